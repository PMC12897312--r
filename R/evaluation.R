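#' Compute calibration/prediction metrics
#'
#' The three standard chemometric figures of merit:
#' `R2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`,
#' `RMSE = sqrt(mean((y - yhat)^2))`, and the residual predictive
#' deviation `RPD = SD(y) / RMSE` with the (n-1)-divisor standard
#' deviation. The mean and SD are those of the evaluated set itself.
#' When predictions are exact (RMSE 0) the RPD is reported as `Inf`.
#' R2 is not clamped: worse-than-mean predictors yield negative values.
#'
#' @param y_true Reference values (length >= 2, non-constant).
#' @param y_pred Predictions, same length.
#' @return A `vn_metrics` list: `r2`, `rmse`, `rpd`, `n`.
#' @export
compute_metrics <- function(y_true, y_pred) {
  y_true <- as.numeric(y_true)
  y_pred <- as.numeric(y_pred)
  n <- length(y_true)
  if (length(y_pred) != n) stop("y_true and y_pred lengths differ")
  if (n < 2) stop("need at least 2 samples")
  if (anyNA(y_true) || anyNA(y_pred)) stop("metrics inputs contain NA")
  sst <- sum((y_true - mean(y_true))^2)
  if (sst == 0) stop("constant y_true: R2 and RPD are undefined")
  sse <- sum((y_true - y_pred)^2)
  rmse <- sqrt(sse / n)
  r2 <- 1 - sse / sst
  sdy <- sqrt(sst / (n - 1))
  rpd <- if (rmse == 0) Inf else sdy / rmse
  structure(list(r2 = r2, rmse = rmse, rpd = rpd, n = n), class = "vn_metrics")
}

#' @export
print.vn_metrics <- function(x, ...) {
  cat(sprintf(
    "R2 = %.4f, RMSE = %.4g, RPD = %.3f (n = %d, %s)\n",
    x$r2, x$rmse, x$rpd, x$n, rpd_category(x$rpd)
  ))
  invisible(x)
}

#' Interpret an RPD value
#'
#' RPD above 2 indicates robust predictive performance; values between
#' 1.4 and 2.0 (inclusive) are acceptable for rough prediction; below 1.4
#' is poor.
#'
#' @param rpd Positive RPD value.
#' @return `"robust"`, `"acceptable"`, or `"poor"`.
#' @export
rpd_category <- function(rpd) {
  stopifnot(rpd > 0)
  if (rpd > 2) "robust" else if (rpd >= 1.4) "acceptable" else "poor"
}

#' Partition wavelengths into influence bands by PLS coefficient size
#'
#' Ranks wavelengths by absolute regression coefficient and splits them
#' into the top 25% (high influence), middle 50% (medium), and bottom 25%
#' (low), the banding used to read PLS coefficient plots. Ties at band
#' boundaries place the lower wavelength index into the higher band.
#'
#' @param coefficients Numeric vector of per-wavelength coefficients
#'   (length >= 4).
#' @return A `coefficient_bands` list of index vectors `high`, `medium`,
#'   `low` (each sorted ascending; together a partition of all indices).
#' @export
coefficient_bands <- function(coefficients) {
  n <- length(coefficients)
  if (n < 4) stop("need at least 4 coefficients")
  ord <- order(-abs(coefficients), seq_len(n)) # |coef| desc, index asc on ties
  n_high <- round(0.25 * n)
  n_low <- round(0.25 * n)
  high <- sort(ord[seq_len(n_high)])
  low <- sort(ord[seq(n - n_low + 1L, n)])
  medium <- sort(ord[seq(n_high + 1L, n - n_low)])
  structure(list(high = high, medium = medium, low = low), class = "coefficient_bands")
}
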