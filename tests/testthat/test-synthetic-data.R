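one_band_config <- function(n = 5, seed = 3, artifacts = artifact_spec(),
                            conc_range = c(1, 3), link = "linear") {
  synthetic_config(
    n_samples = n, grid = c(400, 500, 40),
    constituents = list(constituent_spec(
      "A", conc_range,
      data.frame(center_nm = 450, width_nm = 15, amplitude_per_unit = 1),
      link = link
    )),
    artifacts = artifacts, seed = seed
  )
}

test_that("identical configs and seeds give bit-identical datasets", {
  cfg <- default_grape_config(seed = 9)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$spectra$reflectance, d2$spectra$reflectance)
  expect_identical(d1$references, d2$references)
  d3 <- generate_dataset(default_grape_config(seed = 10))
  expect_false(identical(d1$spectra$reflectance, d3$spectra$reflectance))
})

test_that("artifact-free spectra equal the concentration-scaled Gaussian band", {
  d <- generate_dataset(one_band_config())
  wl <- seq(400, 500, length.out = 40)
  gauss <- exp(-(wl - 450)^2 / (2 * 15^2))
  conc <- d$truth$concentrations[, "A"]
  expect_equal(unname(d$spectra$reflectance), outer(conc, gauss), tolerance = 0)
  expect_equal(unname(d$truth$clean), outer(conc, gauss), tolerance = 0)
})

test_that("observed spectra decompose exactly into clean + stored artifacts", {
  d <- generate_dataset(default_grape_config(seed = 5))
  a <- d$truth$artifacts
  recon <- d$truth$clean * a$multiplier + a$offset + a$baseline + a$noise
  expect_identical(unname(d$spectra$reflectance), recon)
})

test_that("at zero artifacts a linear-link concentration is an affine functional of the spectrum", {
  cfg <- synthetic_config(
    n_samples = 30, grid = c(400, 700, 60),
    constituents = list(
      constituent_spec("A", c(1, 3), data.frame(
        center_nm = 450, width_nm = 15, amplitude_per_unit = 1
      )),
      constituent_spec("B", c(0.5, 2), data.frame(
        center_nm = 600, width_nm = 20, amplitude_per_unit = 0.7
      ))
    ),
    seed = 21, maturity_correlation = 0.4,
    baseline_mean = function(wl) 0.2 + 0.0001 * wl
  )
  d <- generate_dataset(cfg)
  # direct least squares on a handful of spectral columns recovers the
  # concentrations with zero residual (oracle: the linear system itself)
  cols <- seq(1, 60, by = 6)
  for (nm in c("A", "B")) {
    fit <- lm.fit(cbind(1, d$spectra$reflectance[, cols]), d$truth$concentrations[, nm])
    expect_lt(max(abs(fit$residuals)), 1e-8)
  }
})

test_that("the default grape configuration matches the study dimensions", {
  cfg <- default_grape_config()
  expect_identical(cfg$n_samples, 192L)
  expect_identical(cfg$grid[3], 1507)
  expect_identical(cfg$grid[1:2], c(400, 1100))
  expect_setequal(
    vapply(cfg$constituents, `[[`, character(1), "name"),
    indicator_names()
  )
  for (cs in cfg$constituents) {
    expect_true(all(cs$bands$center_nm >= 400 & cs$bands$center_nm <= 1100))
  }
  d <- generate_dataset(cfg)
  expect_identical(dim(d$spectra$reflectance), c(192L, 1507L))
  expect_s3_class(d$references, "reference_table")
})

test_that("invalid configurations are rejected with clear messages", {
  expect_error(
    constituent_spec("A", c(3, 1), data.frame(
      center_nm = 450, width_nm = 15, amplitude_per_unit = 1
    )),
    "low"
  )
  expect_error(
    constituent_spec("A", c(1, 3), data.frame(
      center_nm = 450, width_nm = -1, amplitude_per_unit = 1
    )),
    "width"
  )
  expect_error(
    synthetic_config(
      n_samples = 5, grid = c(400, 500, 40),
      constituents = list(constituent_spec("A", c(1, 3), data.frame(
        center_nm = 900, width_nm = 15, amplitude_per_unit = 1
      )))
    ),
    "outside the grid"
  )
  expect_error(artifact_spec(noise_sd = -0.1), ">= 0")
})

test_that("quadratic link scales bands by the squared concentration", {
  d <- generate_dataset(one_band_config(link = "quadratic", seed = 8))
  wl <- seq(400, 500, length.out = 40)
  gauss <- exp(-(wl - 450)^2 / (2 * 15^2))
  conc <- d$truth$concentrations[, "A"]
  expect_equal(unname(d$spectra$reflectance), outer(conc^2, gauss), tolerance = 0)
})

test_that("synthetic datasets round-trip through the CSV + truth JSON writer", {
  dir <- tempfile()
  d <- generate_dataset(default_grape_config(seed = 2))
  paths <- write_synthetic_dataset(d, dir)
  back <- read_dataset(file.path(dir, "spectra.csv"), file.path(dir, "references.csv"))
  expect_identical(back$spectra$reflectance, vn_dataset(d$spectra, d$references)$spectra$reflectance)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(as.integer(truth$seed), 2L)
  expect_length(truth$constituents, 6)
})
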