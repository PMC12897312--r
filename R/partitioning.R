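#' SPXY sample-set partitioning
#'
#' Splits samples into calibration (training) and prediction (test) sets
#' using joint X-Y distances: `d(i,j) = d_x(i,j)/max(d_x) +
#' d_y(i,j)/max(d_y)`, with `d_x` the Euclidean distance between spectra
#' rows and `d_y = |y_i - y_j|`. The pair at maximal joint distance seeds
#' the training set; Kennard-Stone accretion then repeatedly adds the
#' sample whose minimum joint distance to the current training set is
#' maximal, until `round(train_fraction * N)` samples are selected. Ties
#' are broken by the lowest index. Normalizing each distance by its
#' maximum makes the split invariant to rescaling of either X or y.
#'
#' @param X A [spectra_matrix()] or numeric matrix (samples x wavelengths).
#' @param y Numeric response vector (one indicator), same length as rows
#'   of X.
#' @param train_fraction Fraction of samples assigned to training, in
#'   (0, 1]; the conventional 7:3 calibration/prediction ratio is 0.7.
#' @param indicator Optional label recorded in the result.
#' @return A `split_result` list: `train_indices`, `test_indices`
#'   (1-based, disjoint, covering all samples), `train_fraction`,
#'   `indicator`.
#' @export
spxy_split <- function(X, y, train_fraction = 0.7, indicator = NA_character_) {
  x <- as_reflectance_matrix(X)
  y <- as.numeric(y)
  n <- nrow(x)
  if (length(y) != n) stop("y length does not match number of spectra")
  if (anyNA(y) || any(!is.finite(y))) stop("y contains NaN/Inf values")
  if (n < 3) stop("SPXY needs at least 3 samples")
  if (!(train_fraction > 0 && train_fraction <= 1)) {
    stop("train_fraction must lie in (0, 1]")
  }
  n_train <- round(train_fraction * n)
  if (n_train < 2) stop("train_fraction gives fewer than 2 training samples")

  dx <- as.matrix(stats::dist(x))
  dy <- abs(outer(y, y, `-`))
  mx <- max(dx)
  my <- max(dy)
  if (mx == 0) stop("degenerate spectra: all rows identical (max X-distance is 0)")
  if (my == 0) stop("degenerate response: all y values identical (max Y-distance is 0)")
  d <- dx / mx + dy / my

  # seed pair: first (row-major lowest index) pair attaining the maximum
  seed <- which(d == max(d), arr.ind = TRUE)
  seed <- seed[order(seed[, 1], seed[, 2]), , drop = FALSE]
  selected <- sort(unique(as.integer(seed[1, ])))

  # min distance from each sample to the selected set
  mind <- pmin(d[, selected[1]], d[, selected[2]])
  in_set <- logical(n)
  in_set[selected] <- TRUE
  while (sum(in_set) < n_train) {
    cand <- which(!in_set)
    nxt <- cand[which.max(mind[cand])] # which.max takes the lowest index on ties
    in_set[nxt] <- TRUE
    mind <- pmin(mind, d[, nxt])
  }
  train <- which(in_set)
  structure(
    list(
      train_indices = train,
      test_indices = setdiff(seq_len(n), train),
      train_fraction = train_fraction,
      indicator = indicator
    ),
    class = "split_result"
  )
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf(
    "<split_result> %d train / %d test (fraction %.2f%s)\n",
    length(x$train_indices), length(x$test_indices), x$train_fraction,
    if (is.na(x$indicator)) "" else paste0(", indicator ", x$indicator)
  ))
  invisible(x)
}

#' Write a split as a two-column CSV
#'
#' @param split A `split_result`.
#' @param sample_ids Character ids in original row order.
#' @param path Output CSV path (columns `sample_id`, `role`).
#' @return Invisibly, `path`.
#' @export
write_split <- function(split, sample_ids, path) {
  role <- rep("test", length(sample_ids))
  role[split$train_indices] <- "train"
  utils::write.csv(
    data.frame(sample_id = sample_ids, role = role),
    path,
    row.names = FALSE, quote = FALSE
  )
  invisible(path)
}
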