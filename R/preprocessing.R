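#' Specify a spectral preprocessing method
#'
#' The six operators applied to diffuse-reflectance spectra before
#' calibration, plus `"NONE"`: standard normal variate (`SNV`),
#' multiplicative scatter correction (`MSC`), Savitzky-Golay smoothing
#' (`SG`), Savitzky-Golay first derivative (`FD`), polynomial detrending
#' (`DT`), and column-wise standard scaling (`SS`). SG/FD take an odd
#' `window` greater than `polyorder`; DT takes `detrend_order >= 1`.
#'
#' @param method One of `"NONE"`, `"DT"`, `"FD"`, `"MSC"`, `"SG"`,
#'   `"SNV"`, `"SS"`.
#' @param window Odd integer window length for SG/FD (default 11).
#' @param polyorder Polynomial order for SG/FD (default 2).
#' @param detrend_order Polynomial order for DT (default 2).
#' @return A `preprocessor_spec` list.
#' @export
preprocessor_spec <- function(method = c("NONE", "DT", "FD", "MSC", "SG", "SNV", "SS"),
                              window = 11L, polyorder = 2L, detrend_order = 2L) {
  method <- match.arg(toupper(method[1]), c("NONE", "DT", "FD", "MSC", "SG", "SNV", "SS"))
  if (method %in% c("SG", "FD")) {
    if (window %% 2 == 0) stop("SG/FD window must be odd, got ", window)
    if (window <= polyorder) stop("SG/FD window must exceed polyorder")
  }
  if (method == "DT" && detrend_order < 1) stop("detrend order must be >= 1")
  structure(
    list(
      method = method, window = as.integer(window),
      polyorder = as.integer(polyorder), detrend_order = as.integer(detrend_order)
    ),
    class = "preprocessor_spec"
  )
}

as_reflectance_matrix <- function(x) {
  if (inherits(x, "spectra_matrix")) x$reflectance else as.matrix(x)
}

#' Fit a preprocessor on training spectra
#'
#' Methods that learn from data store training statistics here so the test
#' set is transformed with train-only information: MSC stores the training
#' mean spectrum as its reference; SS stores per-wavelength training means
#' and (n-1) standard deviations. The row-wise methods (SNV, SG, FD, DT)
#' and NONE store nothing.
#'
#' @param spec A [preprocessor_spec()] (or a method name).
#' @param train_spectra Training [spectra_matrix()] or numeric matrix.
#' @param wavelengths Wavelength vector; required for DT/FD on bare
#'   matrices, taken from the spectra_matrix otherwise.
#' @return A `fitted_preprocessor`.
#' @export
fit_preprocessor <- function(spec, train_spectra, wavelengths = NULL) {
  if (is.character(spec)) spec <- preprocessor_spec(spec)
  stopifnot(inherits(spec, "preprocessor_spec"))
  x <- as_reflectance_matrix(train_spectra)
  if (nrow(x) < 1) stop("cannot fit preprocessor on empty training set")
  if (is.null(wavelengths) && inherits(train_spectra, "spectra_matrix")) {
    wavelengths <- as.numeric(train_spectra$grid)
  }
  if (is.null(wavelengths)) wavelengths <- seq_len(ncol(x))
  learned <- NULL
  if (spec$method == "MSC") {
    learned <- list(reference = colMeans(x))
  } else if (spec$method == "SS") {
    mu <- colMeans(x)
    sdv <- apply(x, 2, stats::sd)
    zero <- which(sdv == 0 | !is.finite(sdv))
    if (length(zero)) {
      stop(
        "SS: zero-variance wavelength column(s): ",
        paste(utils::head(zero, 5), collapse = ", ")
      )
    }
    learned <- list(mean = mu, sd = sdv)
  }
  structure(
    list(spec = spec, learned = learned, n_wavelengths = ncol(x), wavelengths = wavelengths),
    class = "fitted_preprocessor"
  )
}

#' Apply a fitted preprocessor
#'
#' All methods preserve the matrix shape. SNV: each row centered by its
#' mean and scaled by its (n-1) standard deviation. MSC: each row
#' regressed on the training reference spectrum (`row ~ a + b * ref`) and
#' corrected to `(row - a) / b`. SG: Savitzky-Golay least-squares
#' smoothing with one-sided truncated windows at the edges. FD: the
#' Savitzky-Golay first derivative divided by the median wavelength step
#' (units: reflectance per nm). DT: per-row subtraction of the fitted
#' polynomial in wavelength. SS: column-wise standardization with the
#' training statistics.
#'
#' @param fp A `fitted_preprocessor` from [fit_preprocessor()].
#' @param spectra [spectra_matrix()] or numeric matrix with the same
#'   wavelength count as the training set.
#' @return Matrix of the same shape (a [spectra_matrix()] in, a
#'   spectra_matrix out).
#' @export
transform_spectra <- function(fp, spectra) {
  stopifnot(inherits(fp, "fitted_preprocessor"))
  is_sm <- inherits(spectra, "spectra_matrix")
  x <- as_reflectance_matrix(spectra)
  if (ncol(x) != fp$n_wavelengths) {
    stop(sprintf(
      "spectra have %d wavelengths but preprocessor was fitted on %d",
      ncol(x), fp$n_wavelengths
    ))
  }
  out <- switch(fp$spec$method,
    NONE = x,
    SNV = transform_snv(x),
    MSC = transform_msc(x, fp$learned$reference),
    SG = sg_filter(x, fp$spec$window, fp$spec$polyorder, deriv = 0L),
    FD = sg_filter(x, fp$spec$window, fp$spec$polyorder, deriv = 1L) /
      stats::median(diff(fp$wavelengths)),
    DT = transform_detrend(x, fp$wavelengths, fp$spec$detrend_order),
    SS = sweep(sweep(x, 2, fp$learned$mean, `-`), 2, fp$learned$sd, `/`)
  )
  dimnames(out) <- dimnames(x)
  if (is_sm) spectra_matrix(out, as.numeric(spectra$grid), spectra$sample_ids) else out
}

transform_snv <- function(x) {
  mu <- rowMeans(x)
  sdv <- apply(x, 1, stats::sd)
  bad <- which(sdv == 0)
  if (length(bad)) {
    stop("SNV: constant spectrum (zero standard deviation) in row ", bad[1])
  }
  (x - mu) / sdv
}

transform_msc <- function(x, ref) {
  refc <- ref - mean(ref)
  denom <- sum(refc^2)
  if (denom == 0) stop("MSC: reference spectrum is constant")
  out <- x
  for (i in seq_len(nrow(x))) {
    row <- x[i, ]
    b <- sum((row - mean(row)) * refc) / denom
    if (abs(b) < 1e-12) {
      stop("MSC: row ", i, " has near-zero slope against the reference")
    }
    a <- mean(row) - b * mean(ref)
    out[i, ] <- (row - a) / b
  }
  out
}

transform_detrend <- function(x, wavelengths, order) {
  # orthonormal polynomial basis incl. intercept; residual of projection
  basis <- cbind(1, stats::poly(wavelengths, degree = order))
  q <- qr.Q(qr(basis))
  x - (x %*% q) %*% t(q)
}

# Savitzky-Golay filtering as a sparse banded linear map. Interior points
# use the full centered window; within half a window of either edge the
# window is truncated to the available one-sided points and the local
# polynomial is refitted there. deriv = 0 smooths, deriv = 1 returns the
# first derivative per index step.
sg_filter <- function(x, window, polyorder, deriv = 0L) {
  p <- ncol(x)
  h <- (window - 1L) %/% 2L
  if (p < polyorder + 1L) stop("too few wavelengths for the SG polynomial order")
  sg_weights <- function(idx, center) {
    # weights of the LS polynomial's value (deriv 0) or first derivative
    # (deriv 1) evaluated at the center position
    a <- outer(idx - center, 0:polyorder, `^`)
    e <- numeric(polyorder + 1L)
    e[deriv + 1L] <- factorial(deriv)
    a %*% solve(crossprod(a), e)
  }
  out <- matrix(0, nrow(x), p)
  w_int <- NULL # interior windows all share one weight vector
  for (j in seq_len(p)) {
    lo <- max(1L, j - h)
    hi <- min(p, j + h)
    # widen a truncated edge window inward until the fit is determined
    while (hi - lo + 1L < polyorder + 1L) {
      if (lo > 1L) lo <- lo - 1L else hi <- hi + 1L
    }
    idx <- lo:hi
    if (lo == j - h && hi == j + h) {
      if (is.null(w_int)) w_int <- sg_weights(idx, j)
      w <- w_int
    } else {
      w <- sg_weights(idx, j)
    }
    out[, j] <- x[, idx, drop = FALSE] %*% w
  }
  out
}
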