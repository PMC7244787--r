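#' Learning hyper-parameters of the hyper-ensemble
#'
#' The six-tuple controlling training. `nParts` is the number of disjoint
#' parts the majority (negative) class is split into; each part, joined
#' with all positives, trains one forest. `fp` is the SMOTE oversampling
#' factor: `fp` synthetic positives are generated per original positive
#' (`fp = 2` synthesizes two new examples for each positive; `fp = 0`
#' disables oversampling). `ratio` sets the number of negatives retained
#' per part as `ratio` times the total (original + synthetic) positives —
#' `ratio = 2` keeps twice as many negatives as effective positives.
#' `k` is the number of nearest positive neighbours SMOTE interpolates
#' towards. `nTrees` and `mTry` are the per-forest number of trees and
#' the number of features sampled at each split.
#'
#' Defaults are the reference configuration commonly used for
#' pathogenic-variant prioritization: `nParts = 100`, `fp = 2`,
#' `ratio = 3`, `k = 5`, `nTrees = 10`, `mTry = 5`.
#'
#' @param nParts positive integer, number of parts of the partition.
#' @param fp non-negative integer, SMOTE multiplicative factor.
#' @param ratio positive integer, negatives per effective positive.
#' @param k positive integer, SMOTE nearest-neighbour count.
#' @param nTrees positive integer, trees per forest.
#' @param mTry positive integer, features sampled per split node.
#' @return An object of class `smurf_hyperparams`.
#' @examples
#' hyperparams(nParts = 10, fp = 1, ratio = 2)
#' @export
hyperparams <- function(nParts = 100, fp = 2, ratio = 3, k = 5,
                        nTrees = 10, mTry = 5) {
  h <- list(nParts = nParts, fp = fp, ratio = ratio, k = k,
            nTrees = nTrees, mTry = mTry)
  for (nm in names(h)) {
    v <- h[[nm]]
    if (length(v) != 1L || is.na(v) || v != round(v)) {
      stop_config(nm, " must be a single integer value")
    }
    h[[nm]] <- as.integer(v)
  }
  if (h$nParts < 1L) stop_config("nParts must be >= 1")
  if (h$fp < 0L) stop_config("fp must be >= 0")
  if (h$ratio < 1L) stop_config("ratio must be >= 1")
  if (h$k < 1L) stop_config("k must be >= 1")
  if (h$nTrees < 1L) stop_config("nTrees must be >= 1")
  if (h$mTry < 1L) stop_config("mTry must be >= 1")
  structure(h, class = "smurf_hyperparams")
}

#' @export
print.smurf_hyperparams <- function(x, ...) {
  cat("hyper-parameters: ",
      paste(names(x), unlist(x), sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

as_hyperparams <- function(h) {
  if (inherits(h, "smurf_hyperparams")) return(h)
  if (is.list(h)) return(do.call(hyperparams, h))
  stop_config("expected hyper-parameters (see ?hyperparams)")
}

# Feasibility of h for a dataset about to be trained on.
check_feasible <- function(dataset, h) {
  n_neg <- n_negatives(dataset)
  n_pos <- n_positives(dataset)
  if (n_pos < 1L) stop_config("training requires at least 1 positive sample")
  if (n_neg < h$nParts) {
    stop_config("nParts (", h$nParts, ") exceeds the number of negatives (",
                n_neg, ")")
  }
  if (h$fp > 0L && n_pos < 2L) {
    stop_config("SMOTE requires >=2 positives (fp = ", h$fp,
                " with ", n_pos, " positive)")
  }
  if (h$mTry > ncol(dataset$features)) {
    stop_config("mTry (", h$mTry, ") exceeds the number of features (",
                ncol(dataset$features), ")")
  }
  invisible(TRUE)
}
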