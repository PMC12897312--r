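test_that("orthogonal columns are picked in norm order", {
  # centered orthogonal columns with norms 3 > 2 > 1: starting at the
  # norm-2 column, projection leaves the others' norms unchanged
  x <- cbind(
    c(1, -1, 0, 0) * 3 / sqrt(2),
    c(0, 0, 1, -1) * 2 / sqrt(2),
    c(1, 1, -1, -1) * 1 / 2
  )
  expect_identical(spa_chain(x, 2, 2), c(2L, 1L))
  expect_identical(spa_chain(x, 2, 3), c(2L, 1L, 3L))
})

test_that("a chain of length 1 is just the start column", {
  set.seed(1)
  x <- matrix(rnorm(20), 5, 4)
  expect_identical(spa_chain(x, 3, 1), 3L)
})

test_that("collinear columns are avoided, matching the projection oracle", {
  set.seed(2)
  c1 <- rnorm(8)
  c2 <- rnorm(8)
  x <- cbind(c1, c2, c1 + c2, rnorm(8))
  got <- spa_chain(x, 1, 3)
  expect_identical(got, as.integer(oracle_spa_chain(x, 1, 3)))
  # after picking columns 1 and 2 the collinear column 3 has zero
  # residual, so it can never be the third pick
  expect_false(3L %in% got)
})

test_that("chains match the exhaustive projection oracle on random fixtures", {
  set.seed(3)
  for (rep in 1:20) {
    x <- matrix(rnorm(9 * 6), 9, 6)
    start <- sample(6, 1)
    k <- sample(2:5, 1)
    expect_identical(
      spa_chain(x, start, k),
      as.integer(oracle_spa_chain(x, start, k))
    )
  }
})

test_that("maximal residual norms are non-increasing and residuals orthogonal", {
  set.seed(4)
  x <- matrix(rnorm(12 * 8), 12, 8)
  chain <- spa_chain(x, 1, 6)
  # recompute residual norms independently at each step
  norms <- numeric(5)
  for (s in 2:6) {
    r <- oracle_residual(x, chain[1:(s - 1)], chain[s])
    norms[s - 1] <- sqrt(sum(r^2))
  }
  expect_true(all(diff(norms) <= 1e-8))
  # residual of pick s is orthogonal to all previously selected columns
  xc <- sweep(x, 2, colMeans(x), `-`)
  for (s in 2:6) {
    r <- oracle_residual(x, chain[1:(s - 1)], chain[s])
    expect_lt(max(abs(crossprod(xc[, chain[1:(s - 1)], drop = FALSE], r))), 1e-8)
  }
})

test_that("rank exhaustion raises an informative error", {
  set.seed(5)
  b <- matrix(rnorm(12), 6, 2)
  x <- b %*% matrix(rnorm(10), 2, 5) # rank 2
  expect_error(spa_chain(x, 1, 4), "rank-exhausted")
})

test_that("an exact 3-variable linear signal drives RMSECV to zero at size 3", {
  set.seed(6)
  n <- 24
  latent <- matrix(rnorm(n * 3), n, 3)
  # 10 columns spanned by 3 latent factors; y an exact combination
  mix <- matrix(rnorm(30), 3, 10)
  x <- latent %*% mix
  y <- drop(latent %*% c(1, -2, 0.5))
  sel <- select_wavelengths(x, y, spa_config(max_vars = 10, mc_runs = 3, seed = 1))
  expect_identical(sel$chosen_size, 3L)
  expect_lt(sel$rmsecv_curve[3], 1e-8)
  expect_gt(sel$rmsecv_curve[2], 1e-6)
})

test_that("selection is deterministic under a fixed seed", {
  set.seed(7)
  x <- matrix(rnorm(20 * 15), 20, 15)
  y <- rnorm(20)
  cfg <- spa_config(max_vars = 8, mc_runs = 1, seed = 42)
  s1 <- select_wavelengths(x, y, cfg)
  s2 <- select_wavelengths(x, y, cfg)
  expect_identical(s1$selected_indices, s2$selected_indices)
  expect_identical(s1$rmsecv_curve, s2$rmsecv_curve)
  expect_identical(s1$coefficient_paths, s2$coefficient_paths)
})

test_that("force_size fixes the subset size at max_vars", {
  set.seed(8)
  x <- matrix(rnorm(30 * 20), 30, 20)
  y <- rnorm(30)
  sel <- select_wavelengths(x, y, spa_config(max_vars = 7, mc_runs = 2, force_size = TRUE, seed = 1))
  expect_identical(sel$chosen_size, 7L)
  expect_length(sel$selected_indices, 7)
})

test_that("the default start column is the one most correlated with y", {
  set.seed(9)
  x <- matrix(rnorm(40 * 6), 40, 6)
  y <- x[, 4] + rnorm(40, 0, 0.01)
  sel <- select_wavelengths(x, y, spa_config(max_vars = 3, mc_runs = 1, seed = 1))
  expect_identical(sel$start_index, 4L)
  expect_identical(sel$selected_indices[1], 4L)
})

test_that("planted informative bands are recovered from realistic spectra", {
  # 5 Gaussian bands drive y; most selected wavelengths should fall
  # within one band-width of a true center (checked across seeds)
  hits <- 0L
  total <- 0L
  for (seed in 1:5) {
    set.seed(100 + seed)
    p <- 120
    wl <- seq(400, 1000, length.out = p)
    centers <- c(450, 560, 700, 820, 930)
    width <- 25
    n <- 40
    conc <- matrix(runif(n * 5, 1, 3), n, 5)
    x <- matrix(0, n, p)
    for (b in 1:5) x <- x + outer(conc[, b], exp(-(wl - centers[b])^2 / (2 * width^2)))
    x <- x + matrix(rnorm(n * p, 0, 0.005), n, p) # SNR >> 10
    y <- drop(conc %*% c(1, 0.8, -1.2, 0.9, 0.6))
    sel <- select_wavelengths(x, y, spa_config(max_vars = 10, mc_runs = 5, seed = seed))
    d_to_band <- vapply(
      wl[sel$selected_indices],
      function(w) min(abs(w - centers)), numeric(1)
    )
    hits <- hits + sum(d_to_band <= width)
    total <- total + length(d_to_band)
  }
  expect_gte(hits / total, 0.8)
})
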