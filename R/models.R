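# ---- PLS1 (NIPALS, single response, X-deflation) ------------------------

# Core NIPALS fit on raw (uncentered) inputs; centering handled here.
pls1_fit <- function(X, y, ncomp) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  p <- ncol(X)
  if (p == 0) stop("no predictor variables")
  if (stats::sd(y) == 0) stop("response is constant")
  ncomp <- min(ncomp, n - 1L, p)
  xm <- colMeans(X)
  ym <- mean(y)
  Xc <- sweep(X, 2, xm, `-`)
  yc <- y - ym
  W <- matrix(0, p, ncomp)
  P <- matrix(0, p, ncomp)
  Q <- numeric(ncomp)
  Tm <- matrix(0, n, ncomp)
  a <- 0L
  for (comp in seq_len(ncomp)) {
    w <- crossprod(Xc, yc)[, 1]
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break # X no longer covaries with y
    w <- w / nw
    t <- Xc %*% w
    tt <- sum(t^2)
    if (tt < 1e-12) break
    pv <- crossprod(Xc, t)[, 1] / tt
    q <- sum(yc * t) / tt
    Xc <- Xc - t %*% t(pv)
    W[, comp] <- w
    P[, comp] <- pv
    Q[comp] <- q
    Tm[, comp] <- t
    a <- comp
  }
  if (a == 0L) stop("PLS: no usable components (X uncorrelated with y)")
  W <- W[, seq_len(a), drop = FALSE]
  P <- P[, seq_len(a), drop = FALSE]
  Q <- Q[seq_len(a)]
  # B = W (P'W)^-1 q maps centered X to centered y
  R <- W %*% solve(t(P) %*% W)
  coefs_per_comp <- apply(sweep(R, 2, Q, `*`), 1, cumsum) # a x p: coefs for 1..a comps
  if (a == 1L) coefs_per_comp <- matrix(coefs_per_comp, nrow = 1L)
  list(
    ncomp = a, x_mean = xm, y_mean = ym,
    coefficients = coefs_per_comp[a, ],
    coefficients_path = coefs_per_comp, # row k: coefficients using k components
    weights = W, loadings = P, y_loadings = Q
  )
}

pls1_predict <- function(fit, Xnew, ncomp = fit$ncomp) {
  Xnew <- as.matrix(Xnew)
  ncomp <- min(ncomp, fit$ncomp)
  b <- fit$coefficients_path[ncomp, ]
  drop(sweep(Xnew, 2, fit$x_mean, `-`) %*% b) + fit$y_mean
}

#' Train a PLS regression with cross-validated latent dimension
#'
#' Canonical single-response NIPALS partial least squares with deflation
#' of X only. The number of latent variables is chosen by grid search over
#' `1..min(n_train, n_vars)` (bounded by the achievable rank), minimizing
#' `cv_folds`-fold cross-validated RMSE; the winning dimension is refit on
#' the full training set. Per-wavelength regression coefficients on the
#' original scale are exposed for influence-band analysis.
#'
#' @param X Training spectra (matrix or [spectra_matrix()]).
#' @param y Training response vector.
#' @param cv_folds Number of CV folds (default 5).
#' @param ncomp_max Optional cap on the latent-dimension grid.
#' @param ncomp Optional fixed latent dimension; skips the CV search.
#' @param seed Seed for the CV fold shuffle.
#' @return A `trained_model` (algorithm `"PLS"`) with `diagnostics`
#'   holding `ncomp`, `coefficients`, `intercept`, and the CV RMSE curve.
#' @export
train_pls <- function(X, y, cv_folds = 5L, ncomp_max = NULL, ncomp = NULL, seed = 1L) {
  x <- as_reflectance_matrix(X)
  y <- as.numeric(y)
  n <- nrow(x)
  if (n < cv_folds) stop("fewer training samples than CV folds")
  if (stats::sd(y) == 0) stop("response is constant")
  if (ncol(x) == 0) stop("no predictor variables")
  if (!is.null(ncomp)) {
    fit <- pls1_fit(x, y, ncomp = ncomp)
    return(structure(
      list(
        algorithm = "PLS",
        fit = fit,
        diagnostics = list(
          ncomp = fit$ncomp,
          coefficients = fit$coefficients,
          intercept = fit$y_mean - sum(fit$x_mean * fit$coefficients),
          cv_rmse = NULL
        ),
        n_wavelengths = ncol(x)
      ),
      class = "trained_model"
    ))
  }
  amax <- min(n, ncol(x))
  if (!is.null(ncomp_max)) amax <- min(amax, ncomp_max)
  amax <- min(amax, n - ceiling(n / cv_folds) - 1L, ncol(x)) # rank bound inside folds
  amax <- max(amax, 1L)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  folds <- sample(rep(seq_len(cv_folds), length.out = n))
  sq_err <- matrix(NA_real_, n, amax)
  for (f in seq_len(cv_folds)) {
    hold <- folds == f
    fit <- pls1_fit(x[!hold, , drop = FALSE], y[!hold], ncomp = amax)
    for (k in seq_len(amax)) {
      kk <- min(k, fit$ncomp)
      sq_err[hold, k] <- (pls1_predict(fit, x[hold, , drop = FALSE], kk) - y[hold])^2
    }
  }
  cv_rmse <- sqrt(colMeans(sq_err))
  best <- which.min(cv_rmse)
  fit <- pls1_fit(x, y, ncomp = best)
  structure(
    list(
      algorithm = "PLS",
      fit = fit,
      diagnostics = list(
        ncomp = fit$ncomp,
        coefficients = fit$coefficients,
        intercept = fit$y_mean - sum(fit$x_mean * fit$coefficients),
        cv_rmse = cv_rmse
      ),
      n_wavelengths = ncol(x)
    ),
    class = "trained_model"
  )
}

# ---- SVR (randomized grid search over the stated grid) -------------------

svr_grid <- function() {
  expand.grid(
    C = c(0.1, 1, 10, 100),
    gamma = c("scale", "auto", "0.01", "0.1", "1"),
    kernel = c("linear", "rbf", "sigmoid"),
    stringsAsFactors = FALSE
  )
}

resolve_gamma <- function(token, x) {
  switch(token,
    scale = 1 / (ncol(x) * stats::var(as.vector(x))),
    auto = 1 / ncol(x),
    as.numeric(token)
  )
}

#' Train a support vector regression with randomized hyperparameter search
#'
#' Epsilon-SVR over the predefined grid `C in (0.1, 1, 10, 100)`, kernel
#' coefficient gamma in (scale, auto, 0.01, 0.1, 1) - where `scale` means
#' `1/(p * var(X))` and `auto` means `1/p` - and kernel in (linear, rbf,
#' sigmoid). Exactly 10 distinct configurations are sampled from the grid
#' (seeded), each scored by 5-fold cross-validated RMSE; the best is refit
#' on the full training set.
#'
#' @param X Training spectra (matrix or [spectra_matrix()]).
#' @param y Training response vector.
#' @param seed Integer seed controlling the sampled configurations and
#'   fold shuffle.
#' @param n_iter Number of sampled configurations (default 10).
#' @param cv_folds CV folds (default 5).
#' @return A `trained_model` (algorithm `"SVR"`) with `diagnostics`
#'   holding the chosen `C`, `gamma` (token and value), `kernel`, and the
#'   per-candidate CV RMSE table.
#' @export
train_svr <- function(X, y, seed = 1L, n_iter = 10L, cv_folds = 5L) {
  x <- as_reflectance_matrix(X)
  y <- as.numeric(y)
  n <- nrow(x)
  if (n < cv_folds) stop("fewer training samples than CV folds")
  if (stats::sd(y) == 0) stop("response is constant (zero variance)")

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  grid <- svr_grid()
  picks <- grid[sample(nrow(grid), min(n_iter, nrow(grid))), , drop = FALSE]
  folds <- sample(rep(seq_len(cv_folds), length.out = n))

  fit_one <- function(C, gamma_tok, kernel, rows) {
    e1071::svm(
      x = x[rows, , drop = FALSE], y = y[rows],
      type = "eps-regression",
      kernel = if (kernel == "rbf") "radial" else kernel,
      cost = C, gamma = resolve_gamma(gamma_tok, x[rows, , drop = FALSE]),
      scale = FALSE
    )
  }
  picks$cv_rmse <- NA_real_
  for (i in seq_len(nrow(picks))) {
    err2 <- numeric(0)
    ok <- TRUE
    for (f in seq_len(cv_folds)) {
      hold <- folds == f
      m <- tryCatch(
        fit_one(picks$C[i], picks$gamma[i], picks$kernel[i], which(!hold)),
        error = function(e) NULL
      )
      if (is.null(m)) {
        ok <- FALSE
        break
      }
      pr <- stats::predict(m, x[hold, , drop = FALSE])
      err2 <- c(err2, (pr - y[hold])^2)
    }
    picks$cv_rmse[i] <- if (ok) sqrt(mean(err2)) else Inf
  }
  best <- which.min(picks$cv_rmse)
  final <- fit_one(picks$C[best], picks$gamma[best], picks$kernel[best], seq_len(n))
  structure(
    list(
      algorithm = "SVR",
      fit = final,
      diagnostics = list(
        C = picks$C[best],
        gamma = picks$gamma[best],
        gamma_value = resolve_gamma(picks$gamma[best], x),
        kernel = picks$kernel[best],
        search = picks
      ),
      n_wavelengths = ncol(x)
    ),
    class = "trained_model"
  )
}

# ---- shared predict ------------------------------------------------------

#' Predict from a trained model
#'
#' One finite prediction per row. The CNN is evaluated in inference mode
#' (dropout disabled, batch-norm running statistics).
#'
#' @param object A `trained_model` from [train_pls()], [train_svr()], or
#'   [train_cnn()].
#' @param newdata Spectra with the same wavelength count as the training
#'   set.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.trained_model <- function(object, newdata, ...) {
  x <- as_reflectance_matrix(newdata)
  if (ncol(x) != object$n_wavelengths) {
    stop(sprintf(
      "input has %d wavelengths but the model was trained on %d",
      ncol(x), object$n_wavelengths
    ))
  }
  switch(object$algorithm,
    PLS = pls1_predict(object$fit, x),
    SVR = {
      p <- as.numeric(stats::predict(object$fit, x))
      names(p) <- NULL
      p
    },
    CNN = cnn_predict(object$fit, x),
    stop("unknown algorithm: ", object$algorithm)
  )
}

#' @export
print.trained_model <- function(x, ...) {
  extra <- switch(x$algorithm,
    PLS = sprintf("%d latent variables", x$diagnostics$ncomp),
    SVR = sprintf(
      "kernel %s, C %g, gamma %s",
      x$diagnostics$kernel, x$diagnostics$C, x$diagnostics$gamma
    ),
    CNN = sprintf("%d epochs", length(x$fit$history$train_loss))
  )
  cat(sprintf("<trained_model> %s (%s)\n", x$algorithm, extra))
  invisible(x)
}
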