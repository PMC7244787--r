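# Cross-validation fold construction. The band-aware variant keeps all
# variants of a cytogenetic band in a single fold, so genomically nearby
# variants (which share similar features) never straddle the
# training/test boundary.

new_fold_assignment <- function(fold_of, nFolds) {
  structure(list(fold_of = as.integer(fold_of), nFolds = as.integer(nFolds)),
            class = "smurf_folds")
}

#' @export
print.smurf_folds <- function(x, ...) {
  cat("fold assignment: ", length(x$fold_of), " samples in ", x$nFolds,
      " folds (sizes ",
      paste(tabulate(x$fold_of + 1L, x$nFolds), collapse = ", "), ")\n",
      sep = "")
  invisible(x)
}

#' Stratified k-fold assignment
#'
#' Positives and negatives are each shuffled and dealt round-robin, so
#' per-class fold counts differ by at most one — under extreme imbalance
#' this guarantees every fold receives its share of the scarce
#' positives.
#'
#' @param labels 0/1 vector.
#' @param nFolds integer >= 2.
#' @param seed integer RNG seed.
#' @return A fold assignment: list with `fold_of` (0-based fold index
#'   per sample) and `nFolds`.
#' @export
stratified_kfold <- function(labels, nFolds, seed) {
  labels <- as.integer(labels > 0)
  nFolds <- as.integer(nFolds)
  if (nFolds < 2L) stop_config("nFolds must be >= 2")
  if (nFolds > length(labels)) {
    stop_config("nFolds (", nFolds, ") exceeds the number of samples (",
                length(labels), ")")
  }
  fold_of <- integer(length(labels))
  with_seed(seed, {
    for (cls in c(1L, 0L)) {
      idx <- which(labels == cls)
      if (length(idx) == 0L) next
      idx <- sample(idx, length(idx))
      fold_of[idx] <- (seq_along(idx) - 1L) %% nFolds
    }
  })
  new_fold_assignment(fold_of, nFolds)
}

#' Cytogenetic-band-aware k-fold assignment
#'
#' Whole bands are assigned to folds; no band is ever split. Bands are
#' processed in decreasing order of positive count (ties broken by total
#' size, then band id) and each is placed in the fold currently lightest
#' in positives (ties broken by total size, then fold index) — the
#' longest-processing-time heuristic, which keeps the scarce positives
#' as evenly spread as the band structure permits.
#'
#' @param band_ids character vector, band identifier per sample.
#' @param labels 0/1 vector.
#' @param nFolds integer >= 2; must not exceed the number of distinct
#'   bands.
#' @param seed integer; accepted for interface symmetry — the greedy
#'   assignment is fully deterministic.
#' @return A fold assignment as in [stratified_kfold()].
#' @export
band_aware_kfold <- function(band_ids, labels, nFolds, seed = 0L) {
  labels <- as.integer(labels > 0)
  band_ids <- as.character(band_ids)
  if (length(band_ids) != length(labels)) {
    stop_config("band_ids: length mismatch: ", length(band_ids),
                " ids for ", length(labels), " labels")
  }
  nFolds <- as.integer(nFolds)
  if (nFolds < 2L) stop_config("nFolds must be >= 2")
  bands <- unique(band_ids)
  if (length(bands) < nFolds) {
    stop_config("fewer distinct bands (", length(bands),
                ") than folds (", nFolds, ")")
  }
  pos_by_band <- vapply(bands, function(b) sum(labels[band_ids == b]), 0L)
  size_by_band <- vapply(bands, function(b) sum(band_ids == b), 0L)
  ord <- order(-pos_by_band, -size_by_band, bands)

  fold_pos <- numeric(nFolds)
  fold_size <- numeric(nFolds)
  band_fold <- integer(length(bands))
  names(band_fold) <- bands[ord]
  for (b in ord) {
    lightest <- order(fold_pos, fold_size, seq_len(nFolds))[1L]
    band_fold[bands[b]] <- lightest - 1L
    fold_pos[lightest] <- fold_pos[lightest] + pos_by_band[b]
    fold_size[lightest] <- fold_size[lightest] + size_by_band[b]
  }
  new_fold_assignment(band_fold[band_ids], nFolds)
}

#' Per-region balanced subsampling
#'
#' Equalizes the class imbalance across regulatory-region categories:
#' the target ratio `r*` is the smallest negatives-per-positive ratio
#' over the categories; within each category all positives are kept and
#' `floor(r* * n_pos_c)` negatives are drawn uniformly. The returned
#' logical vector marks the retained samples.
#'
#' @param labels 0/1 vector.
#' @param category_ids character vector, category per sample.
#' @param seed integer RNG seed.
#' @return Logical vector, `TRUE` for samples kept in the balanced
#'   subset.
#' @export
region_balanced_subsample <- function(labels, category_ids, seed) {
  labels <- as.integer(labels > 0)
  category_ids <- as.character(category_ids)
  if (length(category_ids) != length(labels)) {
    stop_config("category_ids: length mismatch: ", length(category_ids),
                " ids for ", length(labels), " labels")
  }
  cats <- unique(category_ids)
  n_pos_c <- vapply(cats, function(cc) sum(labels[category_ids == cc]), 0L)
  n_neg_c <- vapply(cats,
                    function(cc) sum(labels[category_ids == cc] == 0L), 0L)
  if (any(n_pos_c == 0L)) {
    stop_config("category with zero positives: ",
                paste(cats[n_pos_c == 0L], collapse = ", "))
  }
  if (any(n_neg_c == 0L)) {
    stop_config("category with zero negatives: ",
                paste(cats[n_neg_c == 0L], collapse = ", "))
  }
  r_star <- min(n_neg_c / n_pos_c)
  mark <- labels == 1L
  with_seed(seed, {
    for (i in seq_along(cats)) {
      neg_idx <- which(category_ids == cats[i] & labels == 0L)
      keep <- floor(r_star * n_pos_c[i])
      if (keep >= length(neg_idx)) {
        mark[neg_idx] <- TRUE
      } else if (keep > 0L) {
        mark[sample(neg_idx, keep)] <- TRUE
      }
    }
  })
  mark
}

#' Read and write per-sample fold files
#'
#' One 0-based integer fold index per line, aligned with the dataset's
#' matrix rows.
#'
#' @param folds a fold assignment (from [stratified_kfold()] or
#'   [band_aware_kfold()]) or a bare integer vector.
#' @param path file path.
#' @return `read_folds` returns an integer vector of fold indices.
#' @export
write_folds <- function(folds, path) {
  v <- if (inherits(folds, "smurf_folds")) folds$fold_of else as.integer(folds)
  writeLines(as.character(v), path)
  invisible(NULL)
}

#' @rdname write_folds
#' @export
read_folds <- function(path) {
  as.integer(parse_numeric_column(path, "fold index"))
}
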