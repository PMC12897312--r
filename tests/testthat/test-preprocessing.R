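test_that("SNV standardizes each row and is idempotent", {
  expect_equal(
    transform_spectra(fit_preprocessor("SNV", matrix(0, 1, 3)), matrix(c(1, 2, 3), 1, 3)),
    matrix(c(-1, 0, 1), 1, 3)
  )
  set.seed(1)
  x <- matrix(rnorm(20 * 30, mean = 5), 20, 30)
  fp <- fit_preprocessor("SNV", x)
  z <- transform_spectra(fp, x)
  expect_lt(max(abs(rowMeans(z))), 1e-10)
  expect_lt(max(abs(apply(z, 1, sd) - 1)), 1e-10)
  expect_equal(transform_spectra(fp, z), z, tolerance = 1e-12)
  expect_error(transform_spectra(fp, matrix(2, 2, 30)), "constant")
})

test_that("SNV output is independent of the training set (row-wise method)", {
  set.seed(2)
  x <- matrix(rnorm(60), 6, 10)
  fp1 <- fit_preprocessor("SNV", x[1:3, ])
  fp2 <- fit_preprocessor("SNV", x[4:6, ])
  expect_identical(transform_spectra(fp1, x), transform_spectra(fp2, x))
})

test_that("MSC learns the training mean and inverts planted affine scatter", {
  r <- sin(seq(0, 3, length.out = 25)) + 2
  fp <- fit_preprocessor("MSC", rbind(r, 3 * r))
  expect_equal(fp$learned$reference, 2 * r, ignore_attr = TRUE)

  fp_r <- fit_preprocessor("MSC", rbind(r, r))
  expect_equal(transform_spectra(fp_r, rbind(r))[1, ], r, ignore_attr = TRUE)
  expect_equal(transform_spectra(fp_r, rbind(2 * r + 3))[1, ], r, ignore_attr = TRUE)

  # two observations of one clean spectrum under different (m, o) scatter
  # map to the same corrected spectrum, exactly, at zero noise
  d <- generate_dataset(synthetic_config(
    n_samples = 3, grid = c(400, 500, 25),
    constituents = list(constituent_spec("A", c(1, 3), data.frame(
      center_nm = 450, width_nm = 15, amplitude_per_unit = 1
    ))),
    seed = 4, baseline_mean = function(wl) rep(0.5, length(wl))
  ))
  clean <- d$truth$clean[1, ]
  obs1 <- 1.3 * clean + 0.2
  obs2 <- 0.7 * clean - 0.1
  fp_c <- fit_preprocessor("MSC", rbind(clean, clean))
  out <- transform_spectra(fp_c, rbind(obs1, obs2))
  expect_equal(out[1, ], out[2, ], tolerance = 1e-12)
  expect_equal(out[1, ], clean, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("SNV removes planted multiplicative/additive scatter exactly", {
  set.seed(5)
  clean <- exp(-(seq(400, 500, length.out = 40) - 450)^2 / 450)
  fp <- fit_preprocessor("SNV", rbind(clean))
  out <- transform_spectra(fp, rbind(clean, 1.8 * clean + 0.3, 0.4 * clean - 0.05))
  expect_equal(out[2, ], out[1, ], tolerance = 1e-12)
  expect_equal(out[3, ], out[1, ], tolerance = 1e-12)
})

test_that("SS standardizes with train statistics and flags zero variance", {
  fp <- fit_preprocessor("SS", matrix(c(1, 3), 2, 1))
  expect_equal(fp$learned$mean, 2, ignore_attr = TRUE)
  expect_equal(fp$learned$sd, sqrt(2), ignore_attr = TRUE)

  set.seed(6)
  xtr <- matrix(rnorm(50), 10, 5)
  fp <- fit_preprocessor("SS", xtr)
  z <- transform_spectra(fp, xtr)
  expect_lt(max(abs(colMeans(z))), 1e-10)
  expect_lt(max(abs(apply(z, 2, sd) - 1)), 1e-10)

  xtr[, 3] <- 7
  expect_error(fit_preprocessor("SS", xtr), "3")
})

test_that("DT annihilates polynomials up to its order", {
  wl <- seq(400, 500, length.out = 30)
  quad <- rbind(2 + 0.3 * wl - 0.004 * wl^2)
  fp <- fit_preprocessor(preprocessor_spec("DT", detrend_order = 2), quad, wavelengths = wl)
  expect_lt(max(abs(transform_spectra(fp, quad))), 1e-8)
  cubic <- rbind(quad[1, ] + 1e-6 * (wl - 450)^3)
  expect_gt(max(abs(transform_spectra(fp, cubic))), 1e-3)
})

test_that("SG reproduces polynomials of degree <= polyorder everywhere", {
  wl <- seq(400, 500, length.out = 40)
  quad <- rbind(1 + 0.05 * (wl - 450) + 0.002 * (wl - 450)^2)
  fp <- fit_preprocessor(preprocessor_spec("SG", window = 5, polyorder = 2), quad,
    wavelengths = wl
  )
  expect_equal(transform_spectra(fp, quad), quad, tolerance = 1e-8)
  # and the interior agrees with the reference Savitzky-Golay filter
  skip_if_not_installed("signal")
  set.seed(7)
  noisy <- rbind(quad[1, ] + rnorm(40, 0, 0.05))
  ours <- transform_spectra(fp, noisy)
  ref <- signal::sgolayfilt(noisy[1, ], p = 2, n = 5)
  interior <- 3:38
  expect_equal(ours[1, interior], ref[interior], tolerance = 1e-10)
})

test_that("FD returns the slope in reflectance per nm on a linear ramp", {
  wl <- seq(400, 500, length.out = 26) # 4 nm step
  ramp <- rbind(0.002 * wl + 1)
  fp <- fit_preprocessor(preprocessor_spec("FD", window = 7, polyorder = 2), ramp,
    wavelengths = wl
  )
  out <- transform_spectra(fp, ramp)
  expect_equal(out[1, 4:23], rep(0.002, 20), tolerance = 1e-10)
})

test_that("train-fitted statistics never depend on the test rows", {
  set.seed(8)
  xtr <- matrix(rnorm(200), 10, 20)
  xte <- matrix(rnorm(100), 5, 20)
  for (m in c("SNV", "MSC", "SG", "FD", "DT", "SS")) {
    fp <- fit_preprocessor(m, xtr)
    full <- transform_spectra(fp, xte)
    sub <- transform_spectra(fp, xte[c(3, 1), , drop = FALSE])
    # equality to numerical precision: the row-batched BLAS products in
    # SG/FD/DT round differently for different batch sizes
    expect_equal(sub[1, ], full[3, ], tolerance = 1e-12, label = m)
    expect_equal(sub[2, ], full[1, ], tolerance = 1e-12, label = m)
  }
})

test_that("preprocessor specs validate their parameters", {
  expect_error(preprocessor_spec("SG", window = 10), "odd")
  expect_error(preprocessor_spec("SG", window = 3, polyorder = 3), "exceed")
  expect_error(preprocessor_spec("XX"), "arg")
  fp <- fit_preprocessor("SS", matrix(rnorm(20), 5, 4))
  expect_error(transform_spectra(fp, matrix(0, 2, 3)), "wavelengths")
})
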