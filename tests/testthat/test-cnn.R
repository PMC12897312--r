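test_that("feature-map lengths follow the conv/pool length formula", {
  # independent application of floor((L - k)/s) + 1 through the stages
  oracle_lengths <- function(L) {
    f <- function(L, k, s) floor((L - k) / s) + 1
    l <- f(L, 5, 2)
    l <- c(l, f(l[1], 2, 1))
    l <- c(l, f(l[2], 3, 2))
    l <- c(l, f(l[3], 2, 1))
    l <- c(l, f(l[4], 1, 1))
    c(l, 1)
  }
  expect_identical(cnn_feature_lengths(1507), as.integer(oracle_lengths(1507)))
  expect_identical(cnn_feature_lengths(1507), c(752L, 751L, 375L, 374L, 374L, 1L))
  expect_identical(cnn_feature_lengths(50), c(23L, 22L, 10L, 9L, 9L, 1L))
})

test_that("a live forward pass produces the predicted stage shapes", {
  for (L in c(50L, 64L)) {
    B <- 3L
    set.seed(1)
    xb <- matrix(rnorm(B * L), B, L)
    params <- vinechem:::cnn_init_params()
    x <- matrix(as.vector(xb), ncol = 1L)
    cv1 <- vinechem:::conv_forward(x, B, L, params$conv1_W, params$conv1_b, 5L, 2L)
    mp1 <- vinechem:::maxpool2_forward(cv1$y, B, cv1$L_out)
    cv2 <- vinechem:::conv_forward(mp1$y, B, mp1$L_out, params$conv2_W, params$conv2_b, 3L, 2L)
    mp2 <- vinechem:::maxpool2_forward(cv2$y, B, cv2$L_out)
    cv3 <- vinechem:::conv_forward(mp2$y, B, mp2$L_out, params$conv3_W, params$conv3_b, 1L, 1L)
    gp <- vinechem:::global_maxpool_forward(cv3$y, B, cv3$L_out)
    expect_identical(
      c(cv1$L_out, mp1$L_out, cv2$L_out, mp2$L_out, cv3$L_out, 1L),
      cnn_feature_lengths(L)
    )
    expect_identical(dim(gp$y), c(B, 64L))
  }
})

test_that("backpropagated gradients match finite differences", {
  set.seed(2)
  B <- 4L
  L <- 20L
  xb <- matrix(rnorm(B * L), B, L)
  yb <- rnorm(B)
  params <- vinechem:::cnn_init_params()
  running <- vinechem:::cnn_init_running()
  loss_of <- function(p) {
    out <- vinechem:::cnn_forward(p, running, xb, train = TRUE, dropout = 0)$out
    mean((out - yb)^2)
  }
  fwd <- vinechem:::cnn_forward(params, running, xb, train = TRUE, dropout = 0)
  grads <- vinechem:::cnn_backward(params, fwd$cache, 2 * (fwd$out - yb) / B)
  eps <- 1e-5
  for (nm in c(
    "conv1_W", "conv1_b", "bn1_g", "bn2_b", "conv2_W", "conv3_W",
    "fc1_W", "fc2_b", "fc3_W", "fc3_b"
  )) {
    idx <- sample(length(params[[nm]]), min(3, length(params[[nm]])))
    for (i in idx) {
      pp <- params
      pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- params
      pm[[nm]][i] <- pm[[nm]][i] - eps
      num <- (loss_of(pp) - loss_of(pm)) / (2 * eps)
      expect_equal(as.numeric(grads[[nm]][i]), num,
        tolerance = 1e-4,
        label = sprintf("grad %s[%d]", nm, i)
      )
    }
  }
})

test_that("inputs shorter than the architecture minimum are rejected", {
  x <- matrix(rnorm(10 * 14), 10, 14)
  expect_error(train_cnn(x, rnorm(10), epochs = 1), "minimum is 15")
  expect_silent({
    m <- train_cnn(matrix(rnorm(10 * 15), 10, 15), rnorm(10), epochs = 1, seed = 1)
  })
})

test_that("the forward pass maps n x L batches to n predictions", {
  set.seed(3)
  x <- matrix(rnorm(12 * 30), 12, 30)
  y <- rnorm(12)
  fit <- train_cnn(x, y, epochs = 3, seed = 1)
  p <- predict(fit, x)
  expect_length(p, 12)
  expect_true(all(is.finite(p)))
  expect_length(predict(fit, x[1, , drop = FALSE]), 1)
  # inference is deterministic (dropout disabled, fixed running stats)
  expect_identical(predict(fit, x), predict(fit, x))
})

test_that("training is reproducible under a fixed seed and records history", {
  set.seed(4)
  x <- matrix(rnorm(20 * 24), 20, 24)
  y <- rnorm(20)
  f1 <- train_cnn(x, y, epochs = 5, seed = 9, X_monitor = x[1:4, ], y_monitor = y[1:4])
  f2 <- train_cnn(x, y, epochs = 5, seed = 9, X_monitor = x[1:4, ], y_monitor = y[1:4])
  expect_identical(f1$fit$params, f2$fit$params)
  expect_identical(f1$fit$history, f2$fit$history)
  expect_length(f1$fit$history$train_loss, 5)
  expect_length(f1$fit$history$monitor_loss, 5)
  expect_true(all(is.finite(f1$fit$history$train_loss)))
})

test_that("training reduces the loss on a learnable signal", {
  set.seed(5)
  n <- 32
  L <- 24
  t_lat <- runif(n)
  x <- outer(t_lat, sin(seq(0, 3, length.out = L)))
  y <- 1 + 2 * t_lat
  fit <- train_cnn(x, y, epochs = 60, seed = 2)
  h <- fit$fit$history$train_loss
  expect_lt(min(h), h[1] / 10)
})
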