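#' Configure SPA wavelength selection
#'
#' @param max_vars Maximum chain length / largest candidate subset size
#'   (default 50, the subset size used for every indicator).
#' @param cv_folds Folds for the RMSECV estimate (default 10).
#' @param mc_runs Monte-Carlo repetitions of the fold assignment
#'   (default 80).
#' @param inner_model Scoring model for candidate subsets: `"MLR"`
#'   (multiple linear regression, the classic SPA choice) or `"PLS1"`.
#' @param force_size If `TRUE`, the chosen subset size is fixed at
#'   `max_vars` (the protocol that reports exactly 50 wavelengths per
#'   indicator) instead of the RMSECV minimum.
#' @param seed Integer seed for the Monte-Carlo fold assignments.
#' @return An `spa_config` list.
#' @export
spa_config <- function(max_vars = 50L, cv_folds = 10L, mc_runs = 80L,
                       inner_model = c("MLR", "PLS1"), force_size = FALSE,
                       seed = 1L) {
  inner_model <- match.arg(inner_model)
  stopifnot(max_vars >= 1, cv_folds >= 2, mc_runs >= 1)
  structure(
    list(
      max_vars = as.integer(max_vars), cv_folds = as.integer(cv_folds),
      mc_runs = as.integer(mc_runs), inner_model = inner_model,
      force_size = isTRUE(force_size), seed = as.integer(seed)
    ),
    class = "spa_config"
  )
}

#' Successive projections chain
#'
#' Builds the SPA variable chain: starting from `start_index`, columns are
#' mean-centered, and at each step every unselected column is projected
#' onto the orthogonal complement of the span of the selected columns; the
#' column with the largest residual norm is appended (ties broken by the
#' lowest index). This greedily grows a subset of minimally collinear
#' variables.
#'
#' @param X Numeric matrix (training spectra, samples x wavelengths).
#' @param start_index 1-based column index starting the chain.
#' @param k Chain length, `1 <= k <= min(nrow(X) - 1, ncol(X))`.
#' @return Integer vector of k column indices, beginning with
#'   `start_index`.
#' @export
spa_chain <- function(X, start_index, k) {
  x <- as_reflectance_matrix(X)
  p <- ncol(x)
  if (start_index < 1 || start_index > p) stop("start_index out of range")
  kmax <- min(nrow(x) - 1L, p)
  if (k < 1 || k > kmax) {
    stop(sprintf("k must lie in [1, %d] for a %d x %d matrix", kmax, nrow(x), p))
  }
  xc <- sweep(x, 2, colMeans(x), `-`)
  chain <- integer(k)
  chain[1] <- as.integer(start_index)
  resid <- xc
  for (step in seq_len(k)) {
    if (step > 1) {
      norms <- sqrt(colSums(resid^2))
      norms[chain[seq_len(step - 1)]] <- -Inf
      if (max(norms) < 1e-12) {
        stop(sprintf(
          "SPA chain rank-exhausted after %d variables (all residual norms < 1e-12)",
          step - 1L
        ))
      }
      chain[step] <- which.max(norms) # lowest index on ties
    }
    # deflate: remove the newly selected direction from every column
    v <- resid[, chain[step]]
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12 && step < k) {
      stop(sprintf(
        "SPA chain rank-exhausted after %d variables (all residual norms < 1e-12)",
        step
      ))
    }
    if (nv > 0) {
      q <- v / nv
      resid <- resid - q %*% crossprod(q, resid)
    }
  }
  chain
}

# longest chain obtainable before rank exhaustion, capped at k
spa_chain_safe <- function(X, start_index, k) {
  res <- tryCatch(spa_chain(X, start_index, k), error = function(e) e)
  if (!inherits(res, "error")) {
    return(res)
  }
  m <- regmatches(
    conditionMessage(res),
    regexec("rank-exhausted after ([0-9]+)", conditionMessage(res))
  )[[1]]
  if (length(m) < 2) stop(res)
  spa_chain(X, start_index, as.integer(m[2]))
}

#' Select feature wavelengths with SPA scored by Monte-Carlo RMSECV
#'
#' Builds the successive-projections chain from the start column (by
#' default the column most correlated with the response), then scores
#' every prefix subset of size m = 1..max_vars by cross-validated RMSE of
#' the inner regression model, averaged over `mc_runs` Monte-Carlo
#' resampled `cv_folds`-fold assignments. The chosen size is the RMSECV
#' minimum (ties to the smaller size), or `max_vars` when `force_size` is
#' set. Subsets whose inner model is singular score `+Inf`.
#'
#' @param Xtrain Training spectra (already preprocessed), matrix or
#'   [spectra_matrix()].
#' @param ytrain Aligned response vector.
#' @param config An [spa_config()].
#' @param start_index Optional explicit start column; default picks the
#'   column with maximal absolute correlation with `ytrain`.
#' @return A `selection_result`: `selected_indices` (the chain prefix of
#'   the chosen size, in selection order), `chosen_size`, `rmsecv_curve`
#'   (one value per candidate size), `coefficient_paths` (inner-model
#'   coefficients per candidate size, full-train refit), `start_index`,
#'   `chain`.
#' @export
select_wavelengths <- function(Xtrain, ytrain, config = spa_config(),
                               start_index = NULL) {
  x <- as_reflectance_matrix(Xtrain)
  y <- as.numeric(ytrain)
  n <- nrow(x)
  p <- ncol(x)
  stopifnot(length(y) == n)
  if (config$cv_folds > n) stop("more CV folds than training samples")
  if (is.null(start_index)) {
    sdx <- apply(x, 2, stats::sd)
    ok <- sdx > 0
    if (!any(ok)) stop("all spectral columns are constant")
    cors <- rep(0, p)
    cors[ok] <- abs(suppressWarnings(stats::cor(x[, ok, drop = FALSE], y)))
    cors[is.na(cors)] <- 0
    start_index <- which.max(cors)
  }
  kmax <- min(config$max_vars, n - 2L, p) # leave rank headroom for CV refits
  chain <- spa_chain_safe(x, start_index, kmax)
  kmax <- length(chain)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  rmse_runs <- matrix(NA_real_, config$mc_runs, kmax)
  for (r in seq_len(config$mc_runs)) {
    folds <- sample(rep(seq_len(config$cv_folds), length.out = n))
    sq_err <- matrix(NA_real_, n, kmax)
    for (f in seq_len(config$cv_folds)) {
      hold <- folds == f
      pred <- prefix_predictions(
        x[!hold, chain, drop = FALSE], y[!hold],
        x[hold, chain, drop = FALSE], config$inner_model
      )
      sq_err[hold, ] <- (pred - y[hold])^2
    }
    rmse_runs[r, ] <- sqrt(colMeans(sq_err))
  }
  rmsecv <- colMeans(rmse_runs)
  chosen <- if (config$force_size) kmax else which.min(rmsecv)

  coef_paths <- matrix(NA_real_, kmax, kmax,
    dimnames = list(size = NULL, variable = as.character(chain))
  )
  for (m in seq_len(kmax)) {
    b <- tryCatch(
      inner_coefficients(x[, chain[seq_len(m)], drop = FALSE], y, config$inner_model),
      error = function(e) rep(NA_real_, m)
    )
    coef_paths[m, seq_len(m)] <- b
  }

  structure(
    list(
      selected_indices = chain[seq_len(chosen)],
      chosen_size = as.integer(chosen),
      rmsecv_curve = rmsecv,
      rmsecv_runs = rmse_runs,
      coefficient_paths = coef_paths,
      start_index = as.integer(start_index),
      chain = chain,
      config = config
    ),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf(
    "<selection_result> %d wavelengths chosen (chain %d, RMSECV %.4g at minimum)\n",
    x$chosen_size, length(x$chain), min(x$rmsecv_curve)
  ))
  invisible(x)
}

# predictions on Xnew for every prefix size of the (ordered) columns of
# Xsub, fitted on (Xsub, y). MLR with intercept via one QR; rank-deficient
# prefixes score +Inf (predictions NA -> caller treats as Inf).
prefix_predictions <- function(Xsub, y, Xnew, inner_model) {
  m <- ncol(Xsub)
  preds <- matrix(NA_real_, nrow(Xnew), m)
  if (inner_model == "MLR") {
    a <- cbind(1, Xsub)
    qr_a <- qr(a)
    r <- qr.R(qr_a)
    qty <- qr.qty(qr_a, y)[seq_len(ncol(a))]
    # columns enter in order, so prefix solutions come from leading blocks
    for (k in seq_len(m)) {
      dk <- abs(diag(r)[seq_len(k + 1)])
      if (any(dk < 1e-10 * max(dk))) {
        preds[, k] <- Inf # singular prefix: infinite error sentinel
        next
      }
      beta <- backsolve(r[seq_len(k + 1), seq_len(k + 1), drop = FALSE], qty[seq_len(k + 1)])
      preds[, k] <- cbind(1, Xnew[, seq_len(k), drop = FALSE]) %*% beta
    }
  } else { # PLS1: full-dimension fit per prefix
    for (k in seq_len(m)) {
      fit <- tryCatch(
        pls1_fit(Xsub[, seq_len(k), drop = FALSE], y, ncomp = min(k, nrow(Xsub) - 1L)),
        error = function(e) NULL
      )
      preds[, k] <- if (is.null(fit)) Inf else pls1_predict(fit, Xnew[, seq_len(k), drop = FALSE])
    }
  }
  preds
}

inner_coefficients <- function(Xsub, y, inner_model) {
  if (inner_model == "MLR") {
    stats::lm.fit(cbind(1, Xsub), y)$coefficients[-1]
  } else {
    fit <- pls1_fit(Xsub, y, ncomp = min(ncol(Xsub), nrow(Xsub) - 1L))
    fit$coefficients
  }
}
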