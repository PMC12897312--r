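# One-dimensional CNN for spectral regression, implemented directly on
# base-R matrices: conv(16, k5, s2) -> BN -> ReLU -> maxpool(2, s1) ->
# conv(32, k3, s2) -> BN -> ReLU -> maxpool(2, s1) -> conv(64, k1, s1) ->
# BN -> ReLU -> adaptive max-pool to length 1 -> FC 64 (dropout 0.2) ->
# FC 32 (dropout 0.2) -> FC 1. MSE loss, Adam updates.
#
# Feature maps are stored as (B*L, C) matrices with row index
# (t - 1) * B + b, so convolution becomes an im2col gather followed by one
# matrix product.

#' Feature-map lengths of the spectral CNN
#'
#' Applies the convolution/pooling length formula `floor((L - k)/s) + 1`
#' through the network stages: conv(k5, s2), pool(w2, s1), conv(k3, s2),
#' pool(w2, s1), conv(k1, s1), adaptive pool to 1.
#'
#' @param L Input spectrum length.
#' @return Integer vector of the six stage output lengths.
#' @export
cnn_feature_lengths <- function(L) {
  clen <- function(L, k, s) as.integer((L - k) %/% s + 1L)
  l1 <- clen(L, 5L, 2L)
  l2 <- clen(l1, 2L, 1L)
  l3 <- clen(l2, 3L, 2L)
  l4 <- clen(l3, 2L, 1L)
  l5 <- clen(l4, 1L, 1L)
  c(l1, l2, l3, l4, l5, if (l5 >= 1L) 1L else 0L)
}

cnn_min_length <- function() {
  L <- 8L
  while (any(cnn_feature_lengths(L) < 1L)) L <- L + 1L
  L
}

# ---- layer primitives ----------------------------------------------------

conv_gather_index <- function(B, L_out, stride, j) {
  # rows of the input matrix feeding kernel offset j of every (t, b)
  s <- (0:(L_out - 1L)) * stride + j # input positions, 1-based
  as.vector(outer(seq_len(B), (s - 1L) * B, `+`))
}

conv_forward <- function(x, B, L_in, Wm, bias, k, stride) {
  C_in <- ncol(x)
  L_out <- (L_in - k) %/% stride + 1L
  cols <- matrix(0, B * L_out, C_in * k)
  idx <- vector("list", k)
  for (j in seq_len(k)) {
    idx[[j]] <- conv_gather_index(B, L_out, stride, j)
    for (c in seq_len(C_in)) {
      cols[, (c - 1L) * k + j] <- x[idx[[j]], c]
    }
  }
  y <- cols %*% Wm
  y <- sweep(y, 2, bias, `+`)
  list(y = y, L_out = L_out, cache = list(cols = cols, idx = idx, C_in = C_in, L_in = L_in))
}

conv_backward <- function(dy, cache, Wm, B, k) {
  dW <- crossprod(cache$cols, dy)
  db <- colSums(dy)
  dcols <- dy %*% t(Wm)
  dx <- matrix(0, B * cache$L_in, cache$C_in)
  for (j in seq_len(k)) {
    for (c in seq_len(cache$C_in)) {
      dx[cache$idx[[j]], c] <- dx[cache$idx[[j]], c] + dcols[, (c - 1L) * k + j]
    }
  }
  list(dx = dx, dW = dW, db = db)
}

bn_forward <- function(x, gamma, beta, running, train, momentum = 0.1, eps = 1e-5) {
  if (train) {
    mu <- colMeans(x)
    v <- colMeans(sweep(x, 2, mu, `-`)^2) # biased batch variance
    running$mean <- (1 - momentum) * running$mean + momentum * mu
    n <- nrow(x)
    unbiased <- if (n > 1) v * n / (n - 1) else v
    running$var <- (1 - momentum) * running$var + momentum * unbiased
  } else {
    mu <- running$mean
    v <- running$var
  }
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(x, 2, mu, `-`), 2, inv_sd, `*`)
  y <- sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`)
  list(y = y, running = running, cache = list(xhat = xhat, inv_sd = inv_sd))
}

bn_backward <- function(dy, cache, gamma) {
  n <- nrow(dy)
  dgamma <- colSums(dy * cache$xhat)
  dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2, gamma, `*`)
  dx <- sweep(
    dxhat - matrix(colMeans(dxhat), n, ncol(dy), byrow = TRUE) -
      cache$xhat * matrix(colMeans(dxhat * cache$xhat), n, ncol(dy), byrow = TRUE),
    2, cache$inv_sd, `*`
  )
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

maxpool2_forward <- function(x, B, L_in) {
  L_out <- L_in - 1L
  r1 <- seq_len(B * L_out)            # rows for t = 1..L_out
  r2 <- r1 + B                        # rows for t + 1
  a <- x[r1, , drop = FALSE]
  b <- x[r2, , drop = FALSE]
  take_first <- a >= b
  list(
    y = ifelse(take_first, a, b), L_out = L_out,
    cache = list(take_first = take_first, r1 = r1, r2 = r2, n_in = nrow(x))
  )
}

maxpool2_backward <- function(dy, cache, C) {
  dx <- matrix(0, cache$n_in, C)
  dx[cache$r1, ] <- dx[cache$r1, ] + dy * cache$take_first
  dx[cache$r2, ] <- dx[cache$r2, ] + dy * (!cache$take_first)
  dx
}

global_maxpool_forward <- function(x, B, L_in) {
  C <- ncol(x)
  arr <- array(x, dim = c(B, L_in, C))
  y <- apply(arr, c(1, 3), max)                        # B x C
  amax <- apply(arr, c(1, 3), which.max)               # t index per (b, c)
  list(y = matrix(y, B, C), cache = list(amax = amax, L_in = L_in, n_in = nrow(x)))
}

global_maxpool_backward <- function(dy, cache, B) {
  C <- ncol(dy)
  dx <- matrix(0, cache$n_in, C)
  for (c in seq_len(C)) {
    rows <- (cache$amax[, c] - 1L) * B + seq_len(B)
    dx[cbind(rows, c)] <- dy[, c]
  }
  dx
}

# ---- parameter initialisation and Adam ----------------------------------

he_init <- function(nrow, ncol, fan_in) {
  matrix(stats::rnorm(nrow * ncol, 0, sqrt(2 / fan_in)), nrow, ncol)
}

cnn_init_params <- function() {
  list(
    conv1_W = he_init(1L * 5L, 16L, 1L * 5L), conv1_b = numeric(16),
    bn1_g = rep(1, 16), bn1_b = numeric(16),
    conv2_W = he_init(16L * 3L, 32L, 16L * 3L), conv2_b = numeric(32),
    bn2_g = rep(1, 32), bn2_b = numeric(32),
    conv3_W = he_init(32L * 1L, 64L, 32L * 1L), conv3_b = numeric(64),
    bn3_g = rep(1, 64), bn3_b = numeric(64),
    fc1_W = he_init(64L, 64L, 64L), fc1_b = numeric(64),
    fc2_W = he_init(64L, 32L, 64L), fc2_b = numeric(32),
    fc3_W = he_init(32L, 1L, 32L), fc3_b = numeric(1)
  )
}

cnn_init_running <- function() {
  list(
    bn1 = list(mean = numeric(16), var = rep(1, 16)),
    bn2 = list(mean = numeric(32), var = rep(1, 32)),
    bn3 = list(mean = numeric(64), var = rep(1, 64))
  )
}

adam_step <- function(state, params, grads, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(state = state, params = params)
}

# ---- forward / backward through the whole network ------------------------

cnn_forward <- function(params, running, xb, train, dropout = 0.2) {
  B <- nrow(xb)
  L <- ncol(xb)
  # column-major vectorisation of the B x L batch puts sample index b
  # fastest: row (t - 1) * B + b, the layout the conv gather assumes
  x <- matrix(as.vector(xb), ncol = 1L)
  caches <- list(B = B, L = L)

  cv1 <- conv_forward(x, B, L, params$conv1_W, params$conv1_b, 5L, 2L)
  bn1 <- bn_forward(cv1$y, params$bn1_g, params$bn1_b, running$bn1, train)
  running$bn1 <- bn1$running
  a1 <- pmax(bn1$y, 0)
  mp1 <- maxpool2_forward(a1, B, cv1$L_out)

  cv2 <- conv_forward(mp1$y, B, mp1$L_out, params$conv2_W, params$conv2_b, 3L, 2L)
  bn2 <- bn_forward(cv2$y, params$bn2_g, params$bn2_b, running$bn2, train)
  running$bn2 <- bn2$running
  a2 <- pmax(bn2$y, 0)
  mp2 <- maxpool2_forward(a2, B, cv2$L_out)

  cv3 <- conv_forward(mp2$y, B, mp2$L_out, params$conv3_W, params$conv3_b, 1L, 1L)
  bn3 <- bn_forward(cv3$y, params$bn3_g, params$bn3_b, running$bn3, train)
  running$bn3 <- bn3$running
  a3 <- pmax(bn3$y, 0)
  gp <- global_maxpool_forward(a3, B, cv3$L_out)

  f1 <- gp$y %*% params$fc1_W
  f1 <- sweep(f1, 2, params$fc1_b, `+`)
  h1 <- pmax(f1, 0)
  d1 <- if (train && dropout > 0) {
    matrix(stats::runif(length(h1)) >= dropout, nrow(h1), ncol(h1)) / (1 - dropout)
  } else {
    1
  }
  h1d <- h1 * d1
  f2 <- h1d %*% params$fc2_W
  f2 <- sweep(f2, 2, params$fc2_b, `+`)
  h2 <- pmax(f2, 0)
  d2 <- if (train && dropout > 0) {
    matrix(stats::runif(length(h2)) >= dropout, nrow(h2), ncol(h2)) / (1 - dropout)
  } else {
    1
  }
  h2d <- h2 * d2
  out <- h2d %*% params$fc3_W + params$fc3_b[1]

  list(
    out = drop(out), running = running,
    cache = list(
      B = B, cv1 = cv1, bn1 = bn1$cache, a1 = a1, mp1 = mp1,
      cv2 = cv2, bn2 = bn2$cache, a2 = a2, mp2 = mp2,
      cv3 = cv3, bn3 = bn3$cache, a3 = a3, gp = gp,
      gp_y = gp$y, h1 = h1, d1 = d1, h1d = h1d, h2 = h2, d2 = d2, h2d = h2d,
      bn1_y = bn1$y, bn2_y = bn2$y, bn3_y = bn3$y
    )
  )
}

cnn_backward <- function(params, cache, dout) {
  B <- cache$B
  dout <- matrix(dout, ncol = 1L)
  grads <- list()

  grads$fc3_W <- crossprod(cache$h2d, dout)
  grads$fc3_b <- colSums(dout)
  dh2d <- dout %*% t(params$fc3_W)
  dh2 <- dh2d * cache$d2
  df2 <- dh2 * (cache$h2 > 0)
  grads$fc2_W <- crossprod(cache$h1d, df2)
  grads$fc2_b <- colSums(df2)
  dh1d <- df2 %*% t(params$fc2_W)
  dh1 <- dh1d * cache$d1
  df1 <- dh1 * (cache$h1 > 0)
  grads$fc1_W <- crossprod(cache$gp_y, df1)
  grads$fc1_b <- colSums(df1)
  dgp <- df1 %*% t(params$fc1_W)

  da3 <- global_maxpool_backward(dgp, cache$gp$cache, B)
  dbn3 <- da3 * (cache$bn3_y > 0)
  bb3 <- bn_backward(dbn3, cache$bn3, params$bn3_g)
  grads$bn3_g <- bb3$dgamma
  grads$bn3_b <- bb3$dbeta
  cb3 <- conv_backward(bb3$dx, cache$cv3$cache, params$conv3_W, B, 1L)
  grads$conv3_W <- cb3$dW
  grads$conv3_b <- cb3$db

  da2 <- maxpool2_backward(cb3$dx, cache$mp2$cache, ncol(cb3$dx))
  dbn2 <- da2 * (cache$bn2_y > 0)
  bb2 <- bn_backward(dbn2, cache$bn2, params$bn2_g)
  grads$bn2_g <- bb2$dgamma
  grads$bn2_b <- bb2$dbeta
  cb2 <- conv_backward(bb2$dx, cache$cv2$cache, params$conv2_W, B, 3L)
  grads$conv2_W <- cb2$dW
  grads$conv2_b <- cb2$db

  da1 <- maxpool2_backward(cb2$dx, cache$mp1$cache, ncol(cb2$dx))
  dbn1 <- da1 * (cache$bn1_y > 0)
  bb1 <- bn_backward(dbn1, cache$bn1, params$bn1_g)
  grads$bn1_g <- bb1$dgamma
  grads$bn1_b <- bb1$dbeta
  cb1 <- conv_backward(bb1$dx, cache$cv1$cache, params$conv1_W, B, 5L)
  grads$conv1_W <- cb1$dW
  grads$conv1_b <- cb1$db

  grads
}

cnn_eval <- function(fit, x) {
  xs <- sweep(sweep(x, 2, fit$x_mean, `-`), 2, fit$x_sd, `/`)
  fwd <- cnn_forward(fit$params, fit$running, xs, train = FALSE)
  fwd$out * fit$y_sd + fit$y_mean
}

cnn_predict <- function(fit, x) {
  # batched so prediction memory stays flat for long spectra
  n <- nrow(x)
  out <- numeric(n)
  bs <- 64L
  for (s in seq(1L, n, by = bs)) {
    rows <- s:min(n, s + bs - 1L)
    out[rows] <- cnn_eval(fit, x[rows, , drop = FALSE])
  }
  out
}

#' Train the one-dimensional spectral CNN
#'
#' Three convolutional stages (16, 32, 64 channels with batch
#' normalization, ReLU, and max pooling as printed in the architecture),
#' adaptive max-pooling to a fixed-length feature vector, and a
#' fully-connected head (64 and 32 neurons, dropout 0.2 each) to one
#' output. Inputs are standardized per wavelength and the response is
#' standardized internally using training statistics (predictions are
#' returned on the original scale). Training minimizes mean squared error
#' with Adam. A per-epoch loss history on the calibration set - and on a
#' monitoring set if supplied; it never influences the weights - is
#' recorded on the original response scale.
#'
#' @param X Training spectra (matrix or [spectra_matrix()]); the spectrum
#'   length must be at least 15 so every stage has positive length.
#' @param y Training response vector.
#' @param epochs Training epochs (default 500).
#' @param seed Integer seed (weight init, batch shuffling, dropout).
#' @param lr Initial Adam learning rate (default 1e-3). With
#'   `lr_decay = TRUE` the rate follows a cosine schedule from `lr` to
#'   near zero across the configured epochs, which stops the late-stage
#'   oscillation a constant rate exhibits on small batches.
#' @param lr_decay Apply the cosine learning-rate schedule (default
#'   `TRUE`).
#' @param batch_size Mini-batch size (default 16).
#' @param X_monitor,y_monitor Optional held-out set whose loss is recorded
#'   each epoch for loss-curve plots (monitoring only).
#' @param dropout Dropout probability in the fully-connected head.
#' @return A `trained_model` (algorithm `"CNN"`) whose `fit$history`
#'   holds `train_loss` and (if monitored) `monitor_loss` per epoch.
#' @export
train_cnn <- function(X, y, epochs = 500L, seed = 1L, lr = 1e-3,
                      lr_decay = TRUE, batch_size = 16L,
                      X_monitor = NULL, y_monitor = NULL, dropout = 0.2) {
  x <- as_reflectance_matrix(X)
  y <- as.numeric(y)
  n <- nrow(x)
  L <- ncol(x)
  stopifnot(length(y) == n, epochs >= 1, n >= 2)
  if (any(cnn_feature_lengths(L) < 1L)) {
    stop(sprintf(
      "input length %d is too short for the network; minimum is %d",
      L, cnn_min_length()
    ))
  }
  if (stats::sd(y) == 0) stop("response is constant")
  if (!is.null(X_monitor)) X_monitor <- as_reflectance_matrix(X_monitor)

  x_mean <- colMeans(x)
  x_sd <- apply(x, 2, stats::sd)
  x_sd[x_sd < 1e-12] <- 1
  y_mean <- mean(y)
  y_sd <- stats::sd(y)
  xs <- sweep(sweep(x, 2, x_mean, `-`), 2, x_sd, `/`)
  ys <- (y - y_mean) / y_sd

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  params <- cnn_init_params()
  running <- cnn_init_running()
  zeros_like <- lapply(params, function(p) p * 0)
  adam <- list(t = 0L, m = zeros_like, v = zeros_like)

  train_loss <- numeric(epochs)
  monitor_loss <- if (is.null(X_monitor)) NULL else numeric(epochs)
  fit_view <- function() {
    list(
      params = params, running = running,
      x_mean = x_mean, x_sd = x_sd, y_mean = y_mean, y_sd = y_sd
    )
  }

  for (ep in seq_len(epochs)) {
    lr_ep <- if (lr_decay) lr * 0.5 * (1 + cos(pi * (ep - 1) / epochs)) else lr
    ord <- sample(n)
    for (s in seq(1L, n, by = batch_size)) {
      rows <- ord[s:min(n, s + batch_size - 1L)]
      fwd <- cnn_forward(params, running, xs[rows, , drop = FALSE], train = TRUE, dropout = dropout)
      running <- fwd$running
      resid <- fwd$out - ys[rows]
      dout <- 2 * resid / length(rows) # d(MSE)/d(out)
      grads <- cnn_backward(params, fwd$cache, dout)
      upd <- adam_step(adam, params, grads, lr_ep)
      adam <- upd$state
      params <- upd$params
    }
    fv <- fit_view()
    train_loss[ep] <- mean((cnn_eval(fv, x) - y)^2)
    if (!is.null(X_monitor)) {
      monitor_loss[ep] <- mean((cnn_eval(fv, X_monitor) - y_monitor)^2)
    }
  }

  fit <- fit_view()
  fit$history <- list(train_loss = train_loss, monitor_loss = monitor_loss)
  structure(
    list(
      algorithm = "CNN",
      fit = fit,
      diagnostics = list(
        epochs = epochs, lr = lr, batch_size = batch_size, dropout = dropout,
        history = fit$history, feature_lengths = cnn_feature_lengths(L)
      ),
      n_wavelengths = L
    ),
    class = "trained_model"
  )
}
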