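#' Describe a spectrally active constituent
#'
#' One quality indicator with its plausible concentration range and the
#' Gaussian absorption bands through which it expresses itself in the
#' reflectance spectrum. The contribution of constituent k to the clean
#' spectrum of sample i is `link(c_ik) * sum_b amplitude_b *
#' exp(-(lambda - center_b)^2 / (2 width_b^2))`.
#'
#' @param name Indicator name (one of [indicator_names()] or any label).
#' @param concentration_range Length-2 numeric `(low, high)`, low < high,
#'   in the indicator's units.
#' @param bands Data frame or matrix with columns `center_nm`, `width_nm`,
#'   `amplitude_per_unit`; widths must be positive.
#' @param link `"linear"` (band magnitude proportional to concentration) or
#'   `"quadratic"` (proportional to concentration squared).
#' @return A `constituent_spec` list.
#' @export
constituent_spec <- function(name, concentration_range, bands,
                             link = c("linear", "quadratic")) {
  link <- match.arg(link)
  stopifnot(length(concentration_range) == 2)
  if (!(concentration_range[1] < concentration_range[2])) {
    stop("constituent ", name, ": concentration range low must be < high")
  }
  bands <- as.data.frame(bands)
  needed <- c("center_nm", "width_nm", "amplitude_per_unit")
  if (!all(needed %in% names(bands))) {
    stop("bands need columns: ", paste(needed, collapse = ", "))
  }
  if (any(bands$width_nm <= 0)) stop("constituent ", name, ": band widths must be > 0")
  structure(
    list(
      name = name,
      concentration_range = as.numeric(concentration_range),
      bands = bands[needed],
      link = link
    ),
    class = "constituent_spec"
  )
}

#' Describe the measurement artifacts applied to clean spectra
#'
#' The distortions that scatter-correction and baseline preprocessing are
#' designed to remove: per-spectrum log-normal multiplicative scatter,
#' additive offset, a random polynomial baseline, and i.i.d. additive
#' channel noise. All standard deviations must be non-negative; zero turns
#' the corresponding artifact off.
#'
#' @param scatter_multiplier_sd SD of log(m_i): observed = m_i * clean + ...
#' @param scatter_offset_sd SD of the additive offset o_i.
#' @param baseline_poly_coeffs_sd Numeric vector; SDs of the random
#'   polynomial baseline coefficients (constant, linear, ... in scaled
#'   wavelength on \[-1, 1\]).
#' @param noise_sd SD of i.i.d. additive noise per channel.
#' @return An `artifact_spec` list.
#' @export
artifact_spec <- function(scatter_multiplier_sd = 0, scatter_offset_sd = 0,
                          baseline_poly_coeffs_sd = numeric(0), noise_sd = 0) {
  sds <- c(scatter_multiplier_sd, scatter_offset_sd, baseline_poly_coeffs_sd, noise_sd)
  if (any(sds < 0)) stop("artifact standard deviations must all be >= 0")
  structure(
    list(
      scatter_multiplier_sd = scatter_multiplier_sd,
      scatter_offset_sd = scatter_offset_sd,
      baseline_poly_coeffs_sd = as.numeric(baseline_poly_coeffs_sd),
      noise_sd = noise_sd
    ),
    class = "artifact_spec"
  )
}

#' Configure a synthetic Vis-NIR dataset
#'
#' @param n_samples Positive integer number of samples.
#' @param grid Length-3 numeric `(start_nm, end_nm, n_points)` with
#'   start < end and n_points >= 2.
#' @param constituents List of [constituent_spec()] objects.
#' @param artifacts An [artifact_spec()].
#' @param seed Integer RNG seed; the dataset is a deterministic function of
#'   the full config including this seed.
#' @param maturity_correlation Correlation (via a shared latent ripening
#'   factor, Gaussian copula) between constituent concentrations; 0 makes
#'   them independent.
#' @param baseline_mean Either `NULL` (flat zero mean baseline) or a
#'   function of the wavelength vector returning the deterministic mean
#'   baseline added to every clean spectrum.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_samples, grid, constituents,
                             artifacts = artifact_spec(), seed = 1L,
                             maturity_correlation = 0,
                             baseline_mean = NULL) {
  stopifnot(n_samples >= 1, length(grid) == 3)
  if (!(grid[1] < grid[2])) stop("grid start must be < end")
  if (grid[3] < 2) stop("grid needs at least 2 points")
  if (abs(maturity_correlation) > 1) stop("maturity_correlation must lie in [-1, 1]")
  wl <- seq(grid[1], grid[2], length.out = grid[3])
  for (cs in constituents) {
    stopifnot(inherits(cs, "constituent_spec"))
    outside <- cs$bands$center_nm < min(wl) | cs$bands$center_nm > max(wl)
    if (any(outside)) {
      stop(sprintf(
        "constituent %s: band center %.1f nm lies outside the grid [%.1f, %.1f]",
        cs$name, cs$bands$center_nm[which(outside)[1]], min(wl), max(wl)
      ))
    }
  }
  structure(
    list(
      n_samples = as.integer(n_samples),
      grid = as.numeric(grid),
      constituents = constituents,
      artifacts = artifacts,
      seed = as.integer(seed),
      maturity_correlation = maturity_correlation,
      baseline_mean = baseline_mean
    ),
    class = "synthetic_config"
  )
}

#' Default synthetic configuration emulating the grape study data
#'
#' 192 samples on a 1507-point grid over 400-1100 nm, six constituents
#' named after the grape quality indicators, each expressed through
#' Gaussian bands in the 400-1000 nm pigment region and the 800-920 nm
#' absorption region, with ripening-driven correlation between indicators,
#' multiplicative/additive scatter, polynomial baseline drift, and
#' additive channel noise. Band amplitudes are scaled so the per-indicator
#' spectral signal comfortably exceeds the channel noise (signal-to-noise
#' of at least ten).
#'
#' @param seed Integer RNG seed stored in the config.
#' @return A [synthetic_config()].
#' @export
default_grape_config <- function(seed = 1L) {
  band <- function(center, width, amp) {
    data.frame(center_nm = center, width_nm = width, amplitude_per_unit = amp)
  }
  constituents <- list(
    # visible region: pigment change with maturity (chlorophyll break-down)
    constituent_spec("pH", c(2.5, 3.8), rbind(
      band(505, 28, 0.050), band(682, 22, -0.035), band(918, 35, 0.018)
    )),
    constituent_spec("TSS", c(8, 25), rbind(
      band(844, 30, 0.0075), band(912, 26, 0.0055), band(634, 40, 0.0022)
    )),
    constituent_spec("TA", c(3, 16), rbind(
      band(756, 32, -0.009), band(886, 24, 0.011), band(472, 30, 0.005)
    )),
    constituent_spec("RS", c(40, 240), rbind(
      band(864, 28, 0.00062), band(988, 36, 0.00045), band(558, 34, 0.00021)
    )),
    constituent_spec("TPCN", c(0.5, 4.0), rbind(
      band(536, 30, 0.040), band(808, 26, 0.030), band(946, 30, 0.017)
    )),
    constituent_spec("TPCD", c(5, 45), rbind(
      band(438, 26, 0.0035), band(826, 24, 0.0028), band(892, 30, 0.0020)
    ))
  )
  synthetic_config(
    n_samples = 192L,
    grid = c(400, 1100, 1507),
    constituents = constituents,
    artifacts = artifact_spec(
      scatter_multiplier_sd = 0.08,
      scatter_offset_sd = 0.01,
      baseline_poly_coeffs_sd = c(0.01, 0.008, 0.005),
      noise_sd = 0.002
    ),
    seed = seed,
    maturity_correlation = 0.5,
    # broad reflectance envelope: rises through the visible, flat in NIR
    baseline_mean = function(wl) 0.35 + 0.25 * stats::plogis((wl - 650) / 90)
  )
}

link_value <- function(link, conc) {
  switch(link, linear = conc, quadratic = conc^2)
}

#' Generate a synthetic Vis-NIR dataset
#'
#' Draws concentrations (uniform over each constituent's range, optionally
#' correlated through a shared maturity latent factor), builds the clean
#' spectra from the configured Gaussian bands, then applies multiplicative
#' scatter, additive offset, random polynomial baselines, and channel
#' noise. Deterministic for a fixed config (including its seed).
#'
#' @param config A [synthetic_config()].
#' @return A `synthetic_dataset` list with elements `spectra`
#'   ([spectra_matrix()]), `references` (a [reference_table()] keyed by
#'   constituent name), and `truth` (concentrations, band definitions, clean
#'   spectra, and the realized artifacts, so that
#'   `m * clean + offset + baseline + noise` reproduces the observed
#'   spectra exactly).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_samples
  wl <- seq(config$grid[1], config$grid[2], length.out = config$grid[3])
  p <- length(wl)
  k <- length(config$constituents)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  # concentrations via Gaussian copula with a shared maturity factor
  rho <- config$maturity_correlation
  maturity <- stats::rnorm(n)
  conc <- matrix(0, n, k)
  for (j in seq_len(k)) {
    z <- rho * maturity + sqrt(1 - rho^2) * stats::rnorm(n)
    r <- config$constituents[[j]]$concentration_range
    conc[, j] <- r[1] + (r[2] - r[1]) * stats::pnorm(z)
  }
  colnames(conc) <- vapply(config$constituents, `[[`, character(1), "name")

  # clean spectra: mean baseline + concentration-linked Gaussian bands
  base_mean <- if (is.null(config$baseline_mean)) {
    numeric(p)
  } else {
    as.numeric(config$baseline_mean(wl))
  }
  clean <- matrix(rep(base_mean, each = n), n, p)
  for (j in seq_len(k)) {
    cs <- config$constituents[[j]]
    shape <- numeric(p)
    for (b in seq_len(nrow(cs$bands))) {
      shape <- shape + cs$bands$amplitude_per_unit[b] *
        exp(-(wl - cs$bands$center_nm[b])^2 / (2 * cs$bands$width_nm[b]^2))
    }
    clean <- clean + outer(link_value(cs$link, conc[, j]), shape)
  }

  # artifacts
  a <- config$artifacts
  mult <- if (a$scatter_multiplier_sd > 0) exp(stats::rnorm(n, 0, a$scatter_multiplier_sd)) else rep(1, n)
  offs <- if (a$scatter_offset_sd > 0) stats::rnorm(n, 0, a$scatter_offset_sd) else numeric(n)
  nb <- length(a$baseline_poly_coeffs_sd)
  baseline <- matrix(0, n, p)
  base_coef <- matrix(0, n, max(nb, 1))
  if (nb > 0) {
    x01 <- 2 * (wl - min(wl)) / (max(wl) - min(wl)) - 1 # scaled to [-1, 1]
    basis <- outer(x01, 0:(nb - 1), `^`)                # p x nb
    base_coef <- matrix(stats::rnorm(n * nb), n, nb)
    base_coef <- sweep(base_coef, 2, a$baseline_poly_coeffs_sd, `*`)
    baseline <- base_coef %*% t(basis)
  }
  noise <- if (a$noise_sd > 0) matrix(stats::rnorm(n * p, 0, a$noise_sd), n, p) else matrix(0, n, p)

  observed <- clean * mult + offs + baseline + noise

  ids <- sprintf("S%03d", seq_len(n))
  spectra <- spectra_matrix(observed, wl, ids)
  refs <- reference_table(data.frame(sample_id = ids, conc, check.names = FALSE))

  structure(
    list(
      spectra = spectra,
      references = refs,
      truth = list(
        concentrations = conc,
        constituents = config$constituents,
        clean = clean,
        maturity = maturity,
        artifacts = list(
          multiplier = mult, offset = offs,
          baseline = baseline, baseline_coeffs = base_coef, noise = noise
        )
      ),
      config = config
    ),
    class = "synthetic_dataset"
  )
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  print(x$spectra)
  cat(sprintf(
    "  synthetic: %d constituents, seed %d\n",
    length(x$config$constituents), x$config$seed
  ))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Spectra and reference CSVs via [write_dataset()] plus a JSON file with
#' the generating truth (concentrations, band definitions, artifact
#' realizations summary).
#'
#' @param dataset A `synthetic_dataset` from [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- file.path(dir, "spectra.csv")
  rp <- file.path(dir, "references.csv")
  ds <- vn_dataset(dataset$spectra, dataset$references)
  write_dataset(ds, sp, rp)
  truth <- list(
    seed = dataset$config$seed,
    concentrations = as.data.frame(dataset$truth$concentrations),
    constituents = lapply(dataset$truth$constituents, function(cs) {
      list(
        name = cs$name, link = cs$link,
        concentration_range = cs$concentration_range, bands = cs$bands
      )
    }),
    artifacts = dataset$config$artifacts[]
  )
  tp <- file.path(dir, "truth.json")
  jsonlite::write_json(truth, tp, auto_unbox = TRUE, digits = NA)
  invisible(c(sp, rp, tp))
}
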