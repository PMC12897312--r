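#' Construct a wavelength grid
#'
#' A wavelength axis in nanometres. Must be strictly increasing with at
#' least two points; this is the column axis of every [spectra_matrix()].
#'
#' @param values Numeric vector of wavelengths (nm).
#' @return A numeric vector of class `wavelength_grid`.
#' @export
wavelength_grid <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2) {
    stop("wavelength grid needs at least 2 points, got ", length(values))
  }
  if (anyNA(values)) stop("wavelength grid contains missing values")
  if (any(diff(values) <= 0)) {
    bad <- which(diff(values) <= 0)[1]
    stop(sprintf(
      "wavelengths must be strictly increasing; violation at position %d (%g >= %g)",
      bad, values[bad], values[bad + 1]
    ))
  }
  structure(values, class = "wavelength_grid")
}

#' Construct a spectra matrix
#'
#' Samples-by-wavelengths reflectance container. Sample ids are unique
#' character labels; the wavelength axis is validated via
#' [wavelength_grid()].
#'
#' @param reflectance Numeric matrix, one row per sample.
#' @param wavelengths Numeric vector of wavelengths (nm), one per column.
#' @param sample_ids Character vector of unique sample identifiers.
#' @return An object of class `spectra_matrix` with elements `reflectance`,
#'   `grid`, `sample_ids`.
#' @export
spectra_matrix <- function(reflectance, wavelengths, sample_ids = NULL) {
  reflectance <- as.matrix(reflectance)
  storage.mode(reflectance) <- "double"
  grid <- wavelength_grid(wavelengths)
  if (ncol(reflectance) != length(grid)) {
    stop(sprintf(
      "reflectance has %d columns but grid has %d wavelengths",
      ncol(reflectance), length(grid)
    ))
  }
  if (anyNA(reflectance)) stop("reflectance contains missing values")
  if (is.null(sample_ids)) sample_ids <- sprintf("S%03d", seq_len(nrow(reflectance)))
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != nrow(reflectance)) {
    stop("sample_ids length does not match row count")
  }
  if (anyDuplicated(sample_ids)) {
    stop(
      "duplicate sample ids: ",
      paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", ")
    )
  }
  dimnames(reflectance) <- list(sample_ids, format_wavelength(as.numeric(grid)))
  structure(
    list(reflectance = reflectance, grid = grid, sample_ids = sample_ids),
    class = "spectra_matrix"
  )
}

#' @export
print.spectra_matrix <- function(x, ...) {
  g <- as.numeric(x$grid)
  cat(sprintf(
    "<spectra_matrix> %d samples x %d wavelengths (%.1f-%.1f nm)\n",
    nrow(x$reflectance), length(g), min(g), max(g)
  ))
  invisible(x)
}

#' @export
dim.spectra_matrix <- function(x) dim(x$reflectance)

# Indicator columns recognised in reference tables, in canonical order.
#' Names of the six grape quality indicators
#'
#' pH (unitless), TSS (degrees Brix), TA (g/L), RS (g/L), TPCN and TPCD
#' (mg gallic-acid equivalents per g, skin and seed phenolics).
#'
#' @return Character vector of indicator column names.
#' @export
indicator_names <- function() c("pH", "TSS", "TA", "RS", "TPCN", "TPCD")

#' Construct a reference table
#'
#' Wet-chemistry reference values for the six quality indicators, keyed by
#' sample id. All values must be finite; every indicator except pH must be
#' non-negative.
#'
#' @param values Data frame with a `sample_id` column plus one numeric
#'   column per indicator. Tables carrying the six standard indicators
#'   (see [indicator_names()]) are ordered canonically and checked for
#'   non-negativity (pH exempt); other indicator columns only need to be
#'   finite.
#' @return A data frame of class `reference_table`.
#' @export
reference_table <- function(values) {
  values <- as.data.frame(values, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(values)) stop("reference table needs a sample_id column")
  ind_cols <- setdiff(names(values), "sample_id")
  if (length(ind_cols) == 0) stop("reference table has no indicator columns")
  values$sample_id <- as.character(values$sample_id)
  if (anyDuplicated(values$sample_id)) stop("duplicate sample ids in reference table")
  for (col in ind_cols) {
    v <- as.numeric(values[[col]])
    if (any(!is.finite(v))) stop("non-finite values in reference column ", col)
    if (col %in% setdiff(indicator_names(), "pH") && any(v < 0)) {
      stop("negative values in reference column ", col)
    }
    values[[col]] <- v
  }
  std <- intersect(indicator_names(), ind_cols)
  values <- values[c("sample_id", std, setdiff(ind_cols, std))]
  rownames(values) <- NULL
  class(values) <- c("reference_table", "data.frame")
  values
}

#' Pair spectra with reference values
#'
#' Validates that spectra and references describe the same samples and
#' reorders both into a canonical id-sorted order so row i of the spectra
#' always matches row i of the references.
#'
#' @param spectra A [spectra_matrix()].
#' @param references A [reference_table()].
#' @return An object of class `vn_dataset` with elements `spectra` and
#'   `references`.
#' @export
vn_dataset <- function(spectra, references) {
  stopifnot(inherits(spectra, "spectra_matrix"))
  if (!inherits(references, "reference_table")) references <- reference_table(references)
  only_spec <- setdiff(spectra$sample_ids, references$sample_id)
  only_ref <- setdiff(references$sample_id, spectra$sample_ids)
  if (length(only_spec) || length(only_ref)) {
    stop(
      "sample ids do not match between spectra and references.",
      if (length(only_spec)) paste0(" Only in spectra: ", paste(only_spec, collapse = ", "), "."),
      if (length(only_ref)) paste0(" Only in references: ", paste(only_ref, collapse = ", "), ".")
    )
  }
  ord <- order(spectra$sample_ids)
  spectra <- spectra_matrix(
    spectra$reflectance[ord, , drop = FALSE],
    as.numeric(spectra$grid),
    spectra$sample_ids[ord]
  )
  references <- references[match(spectra$sample_ids, references$sample_id), , drop = FALSE]
  rownames(references) <- NULL
  class(references) <- c("reference_table", "data.frame")
  structure(list(spectra = spectra, references = references), class = "vn_dataset")
}

#' @export
print.vn_dataset <- function(x, ...) {
  print(x$spectra)
  cat(sprintf("  paired with references for: %s\n", paste(indicator_names(), collapse = ", ")))
  invisible(x)
}

format_wavelength <- function(w) {
  # shortest decimal representation that round-trips a double
  vapply(w, function(x) formatC(x, digits = 17, format = "g"), character(1))
}

#' Write spectra and references as CSV
#'
#' Wide-matrix spectra CSV (first column `sample_id`, remaining headers the
#' wavelengths in nm) and a reference CSV with the fixed indicator columns.
#' Values are printed with 17 significant digits so a write/read round trip
#' reproduces the doubles bit-exactly.
#'
#' @param dataset A [vn_dataset()].
#' @param spectra_path,reference_path Output file paths.
#' @return Invisibly, the two paths.
#' @export
write_dataset <- function(dataset, spectra_path, reference_path) {
  stopifnot(inherits(dataset, "vn_dataset"))
  sp <- dataset$spectra
  header <- c("sample_id", format_wavelength(as.numeric(sp$grid)))
  rows <- vapply(seq_len(nrow(sp$reflectance)), function(i) {
    paste(c(sp$sample_ids[i], format_wavelength(sp$reflectance[i, ])), collapse = ",")
  }, character(1))
  writeLines(c(paste(header, collapse = ","), rows), spectra_path, useBytes = TRUE)

  ref <- dataset$references
  header2 <- c("sample_id", indicator_names())
  rows2 <- vapply(seq_len(nrow(ref)), function(i) {
    paste(
      c(ref$sample_id[i], format_wavelength(unlist(ref[i, indicator_names()]))),
      collapse = ","
    )
  }, character(1))
  writeLines(c(paste(header2, collapse = ","), rows2), reference_path, useBytes = TRUE)
  invisible(c(spectra_path, reference_path))
}

#' Read a paired spectra/reference dataset from CSV
#'
#' Reads the wide-matrix spectra CSV and the reference CSV written by
#' [write_dataset()], validates both, and returns the canonical id-sorted
#' [vn_dataset()]. Errors name any sample ids present in one file but not
#' the other, and reject non-increasing wavelength headers.
#'
#' @param spectra_path,reference_path Input file paths.
#' @return A [vn_dataset()].
#' @export
read_dataset <- function(spectra_path, reference_path) {
  for (p in c(spectra_path, reference_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  sp <- utils::read.csv(spectra_path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(sp)[1] != "sample_id") stop("first spectra column must be sample_id")
  wl <- suppressWarnings(as.numeric(names(sp)[-1]))
  if (anyNA(wl)) {
    stop(
      "non-numeric wavelength headers: ",
      paste(names(sp)[-1][is.na(wl)], collapse = ", ")
    )
  }
  spectra <- spectra_matrix(as.matrix(sp[, -1, drop = FALSE]), wl, sp$sample_id)
  ref <- utils::read.csv(reference_path, check.names = FALSE, stringsAsFactors = FALSE)
  vn_dataset(spectra, reference_table(ref))
}

#' Pick the representative spectrum among replicate measurements
#'
#' Repeated measurements of one sample are reduced to the single spectrum
#' showing the least deviation from the others: the Euclidean-distance
#' medoid, i.e. the row minimizing the sum of Euclidean distances to all
#' other rows. Ties are broken by the lowest row index.
#'
#' @param replicates A [spectra_matrix()] or numeric matrix of replicate
#'   rows.
#' @return Integer row index (1-based) of the representative spectrum.
#' @export
select_representative <- function(replicates) {
  x <- if (inherits(replicates, "spectra_matrix")) replicates$reflectance else as.matrix(replicates)
  n <- nrow(x)
  if (is.null(n) || n < 1) stop("no replicate spectra supplied")
  if (n == 1) return(1L)
  d <- as.matrix(stats::dist(x, method = "euclidean"))
  unname(which.min(rowSums(d))) # which.min returns the first (lowest-index) minimum
}
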