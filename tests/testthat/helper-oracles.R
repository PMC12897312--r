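# Independent brute-force oracles used to check the package's greedy /
# closed-form implementations. These deliberately recompute everything
# with naive loops and never share code with the implementation.

# medoid by explicit O(n^2) pairwise distance sums
oracle_medoid <- function(x) {
  n <- nrow(x)
  sums <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      sums[i] <- sums[i] + sqrt(sum((x[i, ] - x[j, ])^2))
    }
  }
  which.min(sums)
}

# SPXY selection by direct max-min accretion over the explicit joint
# distance matrix
oracle_spxy <- function(x, y, n_train) {
  n <- nrow(x)
  dx <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) dx[i, j] <- sqrt(sum((x[i, ] - x[j, ])^2))
  }
  dy <- abs(outer(y, y, `-`))
  d <- dx / max(dx) + dy / max(dy)
  best <- -Inf
  pair <- c(NA, NA)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (d[i, j] > best) {
        best <- d[i, j]
        pair <- c(i, j)
      }
    }
  }
  sel <- pair
  while (length(sel) < n_train) {
    cand <- setdiff(seq_len(n), sel)
    mind <- vapply(cand, function(c) min(d[c, sel]), numeric(1))
    sel <- c(sel, cand[which.max(mind)])
  }
  sort(sel)
}

# SPA chain by exhaustive per-candidate projection: at each step, for
# every unselected column, regress it on the selected (centered) columns
# and measure the residual norm directly.
oracle_spa_chain <- function(x, start, k) {
  xc <- sweep(x, 2, colMeans(x), `-`)
  sel <- start
  while (length(sel) < k) {
    cand <- setdiff(seq_len(ncol(xc)), sel)
    a <- xc[, sel, drop = FALSE]
    norms <- vapply(cand, function(j) {
      fit <- stats::lm.fit(a, xc[, j])
      sqrt(sum(fit$residuals^2))
    }, numeric(1))
    sel <- c(sel, cand[which.max(norms)])
  }
  sel
}

# residual of column j after projecting out the span of columns `sel`
# (centered), computed independently via lm.fit
oracle_residual <- function(x, sel, j) {
  xc <- sweep(x, 2, colMeans(x), `-`)
  stats::lm.fit(xc[, sel, drop = FALSE], xc[, j])$residuals
}

# one-constituent noise-free synthetic fixture builders
make_gaussian_fixture <- function(n = 6, p = 40, seed = 1) {
  set.seed(seed)
  wl <- seq(400, 500, length.out = p)
  conc <- runif(n, 1, 3)
  list(
    wl = wl, conc = conc,
    spectra = outer(conc, exp(-(wl - 450)^2 / (2 * 15^2)))
  )
}
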