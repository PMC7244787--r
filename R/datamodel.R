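#' Construct and validate a labelled feature dataset
#'
#' The container every stage of the hyper-ensemble operates on: a numeric
#' feature matrix with one row per sample, a binary label vector
#' (1 = minority/positive class, e.g. pathogenic; 0 = majority/negative
#' class), and optional per-sample annotations: cytogenetic band
#' identifiers (for band-aware cross-validation), regulatory-category
#' identifiers (for per-region balanced subsampling), and sample names.
#'
#' @param features numeric matrix, `n_samples x n_features`; no missing
#'   values.
#' @param labels vector coercible to 0/1; any value greater than 0 is
#'   mapped to 1.
#' @param band_ids optional character/factor vector of length `n_samples`.
#' @param category_ids optional character/factor vector of length
#'   `n_samples`.
#' @param sample_ids optional character vector of length `n_samples`.
#' @return An object of class `smurf_dataset`: a list with elements
#'   `features`, `labels`, `band_ids`, `category_ids`, `sample_ids`.
#' @examples
#' d <- smurf_dataset(matrix(rnorm(20), 10, 2), labels = rep(c(1, 0), c(2, 8)))
#' n_positives(d)
#' @export
smurf_dataset <- function(features, labels, band_ids = NULL,
                          category_ids = NULL, sample_ids = NULL) {
  if (!is.matrix(features)) features <- as.matrix(features)
  storage.mode(features) <- "double"
  if (is.null(colnames(features))) {
    colnames(features) <- sprintf("f%d", seq_len(ncol(features)))
  }
  rownames(features) <- NULL
  if (ncol(features) < 1L) {
    stop_data("features: at least one feature column is required")
  }
  if (anyNA(features) || any(!is.finite(features))) {
    stop_data("features: missing or non-finite values are not supported")
  }
  n <- nrow(features)
  labels <- as.numeric(labels)
  if (length(labels) != n) {
    stop_data("labels: length mismatch: ", length(labels), " labels for ",
              n, " samples")
  }
  if (anyNA(labels) || any(labels < 0)) {
    stop_data("labels: values must be non-negative numbers (got NA or < 0)")
  }
  labels <- as.integer(labels > 0)
  check_annot <- function(x, what) {
    if (is.null(x)) return(NULL)
    if (length(x) != n) {
      stop_data(what, ": length mismatch: ", length(x), " values for ",
                n, " samples")
    }
    as.character(x)
  }
  structure(
    list(
      features = features,
      labels = labels,
      band_ids = check_annot(band_ids, "band_ids"),
      category_ids = check_annot(category_ids, "category_ids"),
      sample_ids = check_annot(sample_ids, "sample_ids")
    ),
    class = "smurf_dataset"
  )
}

#' @export
print.smurf_dataset <- function(x, ...) {
  n <- nrow(x$features)
  np <- sum(x$labels)
  cat("smurf_dataset: ", n, " samples x ", ncol(x$features), " features\n",
      sep = "")
  cat("  positives: ", np, ", negatives: ", n - np,
      if (np > 0) paste0("  (", format_imbalance(imbalance_ratio(x)), ")"),
      "\n", sep = "")
  if (!is.null(x$band_ids)) {
    cat("  bands: ", length(unique(x$band_ids)), "\n", sep = "")
  }
  if (!is.null(x$category_ids)) {
    cat("  categories: ", length(unique(x$category_ids)), "\n", sep = "")
  }
  invisible(x)
}

#' @rdname smurf_dataset
#' @param x a `smurf_dataset`.
#' @export
n_positives <- function(x) sum(x$labels == 1L)

#' @rdname smurf_dataset
#' @export
n_negatives <- function(x) sum(x$labels == 0L)

# Parse a whitespace-separated numeric text file into a matrix, with
# 1-based row/column coordinates in error messages.
parse_numeric_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop_data(path, ": empty matrix file")
  rows <- strsplit(trimws(lines), "[[:space:]]+")
  ncols <- lengths(rows)
  if (length(unique(ncols)) != 1L) {
    bad <- which(ncols != ncols[1L])[1L]
    stop_data(path, ": row ", bad, " has ", ncols[bad],
              " columns; expected ", ncols[1L])
  }
  vals <- suppressWarnings(as.numeric(unlist(rows)))
  if (anyNA(vals)) {
    flat <- which(is.na(vals))[1L]
    r <- ((flat - 1L) %/% ncols[1L]) + 1L
    c <- ((flat - 1L) %% ncols[1L]) + 1L
    stop_data(path, ": non-numeric value '", unlist(rows)[flat],
              "' at row ", r, ", column ", c)
  }
  matrix(vals, nrow = length(rows), ncol = ncols[1L], byrow = TRUE)
}

# One numeric per line, aligned with matrix rows.
parse_numeric_column <- function(path, what) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  vals <- suppressWarnings(as.numeric(lines))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1L]
    stop_data(path, ": non-numeric ", what, " '", lines[bad],
              "' at line ", bad)
  }
  vals
}

#' Read a dataset from plain-text matrix and label files
#'
#' The matrix file holds one sample per line as whitespace-separated
#' decimal numbers; the label file holds one numeric label per line,
#' aligned with the matrix rows (any value > 0 is treated as positive).
#' Optional band and fold files follow the same one-value-per-line
#' convention.
#'
#' @param matrix_path path to the feature matrix file.
#' @param labels_path path to the label file.
#' @param band_path optional path to a per-sample band-identifier file
#'   (one token per line; tokens need not be numeric).
#' @param fold_path optional path to a per-sample fold-index file.
#' @return A [smurf_dataset()]; when `fold_path` is given, the fold vector
#'   is attached as attribute `"folds"` (0-based integer fold indices).
#' @export
read_dataset <- function(matrix_path, labels_path, band_path = NULL,
                         fold_path = NULL) {
  for (p in c(matrix_path, labels_path, band_path, fold_path)) {
    if (!file.exists(p)) stop_data("file not found: ", p)
  }
  X <- parse_numeric_matrix(matrix_path)
  y <- parse_numeric_column(labels_path, "label")
  if (length(y) != nrow(X)) {
    stop_data("length mismatch: ", length(y), " labels (", labels_path,
              ") for ", nrow(X), " matrix rows (", matrix_path, ")")
  }
  bands <- NULL
  if (!is.null(band_path)) {
    bands <- trimws(readLines(band_path))
    bands <- bands[nzchar(bands)]
    if (length(bands) != nrow(X)) {
      stop_data("length mismatch: ", length(bands), " band ids for ",
                nrow(X), " matrix rows")
    }
  }
  d <- smurf_dataset(X, y, band_ids = bands)
  if (!is.null(fold_path)) {
    folds <- parse_numeric_column(fold_path, "fold index")
    if (length(folds) != nrow(X)) {
      stop_data("length mismatch: ", length(folds), " fold indices for ",
                nrow(X), " matrix rows")
    }
    attr(d, "folds") <- as.integer(folds)
  }
  d
}

#' Read a dataset from a single TSV file with a header row
#'
#' Columns named `label`, `band`, `category` and `fold` are reserved and
#' peeled off into the corresponding dataset slots; every other column is
#' taken as a numeric feature.
#'
#' @param path path to a tab-separated file with a header row.
#' @return A [smurf_dataset()] (with attribute `"folds"` if a `fold`
#'   column is present).
#' @export
read_dataset_tsv <- function(path) {
  if (!file.exists(path)) stop_data("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!"label" %in% names(df)) {
    stop_data(path, ": required column 'label' not found")
  }
  reserved <- intersect(c("label", "band", "category", "fold"), names(df))
  feat <- df[, setdiff(names(df), reserved), drop = FALSE]
  if (ncol(feat) < 1L) stop_data(path, ": no feature columns")
  X <- as.matrix(feat)
  if (!is.numeric(X)) stop_data(path, ": non-numeric feature column")
  d <- smurf_dataset(X, df$label,
                     band_ids = if ("band" %in% reserved) df$band,
                     category_ids = if ("category" %in% reserved) df$category)
  if ("fold" %in% reserved) attr(d, "folds") <- as.integer(df$fold)
  d
}

#' Write a dataset back to matrix/label (and optional band) files
#'
#' Inverse of [read_dataset()]: values round-trip through the plain-text
#' format.
#'
#' @param dataset a [smurf_dataset()].
#' @param matrix_path,labels_path output paths.
#' @param band_path optional output path for band identifiers.
#' @return Invisibly, `NULL`.
#' @export
write_dataset <- function(dataset, matrix_path, labels_path,
                          band_path = NULL) {
  stopifnot(inherits(dataset, "smurf_dataset"))
  writeLines(apply(dataset$features, 1L, function(r) {
    paste(format(r, digits = 17, scientific = FALSE, trim = TRUE),
          collapse = " ")
  }), matrix_path)
  writeLines(as.character(dataset$labels), labels_path)
  if (!is.null(band_path)) {
    if (is.null(dataset$band_ids)) stop_data("dataset has no band_ids")
    writeLines(dataset$band_ids, band_path)
  }
  invisible(NULL)
}

#' Write prediction scores to a text file
#'
#' One score per line with six decimal digits; round-trips exactly with
#' [read_scores()] at that precision.
#'
#' @param scores numeric vector of scores in `[0, 1]`.
#' @param path output path.
#' @param sample_ids optional sample names; when given, output is
#'   two-column (id, score) tab-separated.
#' @return Invisibly, `NULL`.
#' @export
write_scores <- function(scores, path, sample_ids = NULL) {
  scores <- as.numeric(scores)
  if (length(scores) > 0 &&
      (anyNA(scores) || any(!is.finite(scores)) ||
       any(scores < 0 | scores > 1))) {
    stop_data("scores must be finite values in [0, 1]")
  }
  txt <- sprintf("%.6f", scores)
  if (!is.null(sample_ids)) {
    if (length(sample_ids) != length(scores)) {
      stop_data("sample_ids: length mismatch: ", length(sample_ids),
                " ids for ", length(scores), " scores")
    }
    txt <- paste(sample_ids, txt, sep = "\t")
  }
  writeLines(txt, path)
  invisible(NULL)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(numeric(0))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  last <- vapply(fields, function(f) f[[length(f)]], character(1))
  vals <- suppressWarnings(as.numeric(last))
  if (anyNA(vals)) {
    stop_data(path, ": non-numeric score at line ", which(is.na(vals))[1L])
  }
  vals
}
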