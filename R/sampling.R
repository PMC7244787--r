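# Per-part training-set assembly: partition the negatives, SMOTE the
# positives, undersample each part, and concatenate.

#' Partition the negative class into disjoint parts
#'
#' Randomly shuffles the negative sample indices (uniformly, driven by
#' `seed`) and deals them into `nParts` disjoint sets whose sizes differ
#' by at most one. Their union is exactly the set of all negatives, so
#' every negative example is used by exactly one part of the ensemble.
#'
#' @param dataset a [smurf_dataset()].
#' @param nParts positive integer, the number of parts.
#' @param seed integer RNG seed.
#' @return List of `nParts` integer vectors of row indices into the
#'   dataset (each index a negative sample).
#' @export
partition_negatives <- function(dataset, nParts, seed) {
  stopifnot(inherits(dataset, "smurf_dataset"))
  nParts <- as.integer(nParts)
  neg <- which(dataset$labels == 0L)
  if (nParts < 1L) stop_config("nParts must be >= 1")
  if (nParts > length(neg)) {
    stop_config("nParts (", nParts, ") exceeds the number of negatives (",
                length(neg), ")")
  }
  shuffled <- with_seed(seed, sample(neg, length(neg)))
  # sizes differ by <= 1: the first (n mod nParts) parts get one extra
  sizes <- rep(length(neg) %/% nParts, nParts)
  extra <- length(neg) %% nParts
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  split(shuffled, rep(seq_len(nParts), times = sizes))
}

#' SMOTE oversampling of the minority class
#'
#' For each positive example `p`, generates `fp` synthetic examples by
#' linear interpolation `p + u * (q - p)` where `q` is drawn uniformly
#' among the `k` nearest positive neighbours of `p` (Euclidean distance,
#' `p` itself excluded) and `u` is uniform on `[0, 1)`. The neighbour is
#' drawn independently for each synthetic row. When `k >= n_pos` it is
#' clamped to `n_pos - 1`.
#'
#' @param positives numeric matrix of positive examples
#'   (`n_pos x n_features`).
#' @param fp non-negative integer, synthetic examples per positive.
#' @param k positive integer, neighbourhood size.
#' @param seed integer RNG seed.
#' @return Numeric matrix with `fp * n_pos` rows (zero rows when
#'   `fp = 0`).
#' @export
smote_oversample <- function(positives, fp, k, seed) {
  if (!is.matrix(positives)) positives <- as.matrix(positives)
  fp <- as.integer(fp)
  k <- as.integer(k)
  n_pos <- nrow(positives)
  d <- ncol(positives)
  if (fp < 0L) stop_config("fp must be >= 0")
  if (fp == 0L) return(matrix(numeric(0), nrow = 0L, ncol = d))
  if (n_pos < 2L) stop_config("SMOTE requires >=2 positives")
  if (k < 1L) stop_config("k must be >= 1")
  k <- min(k, n_pos - 1L)

  # k nearest positive neighbours of each positive, self excluded
  dm <- as.matrix(stats::dist(positives))
  diag(dm) <- Inf
  nn <- t(apply(dm, 1L, function(row) order(row)[seq_len(k)]))
  nn <- matrix(nn, nrow = n_pos) # guard k = 1 dropping to a vector

  with_seed(seed, {
    synth <- matrix(0, nrow = fp * n_pos, ncol = d)
    row <- 0L
    for (i in seq_len(n_pos)) {
      for (j in seq_len(fp)) {
        q <- nn[i, sample.int(k, 1L)]
        u <- stats::runif(1L)
        row <- row + 1L
        synth[row, ] <- positives[i, ] + u * (positives[q, ] - positives[i, ])
      }
    }
    synth
  })
}

#' Uniform undersampling of a part's negatives
#'
#' Draws `min(target, length(negative_indices))` indices uniformly
#' without replacement. A target larger than the part simply keeps every
#' available negative.
#'
#' @param negative_indices integer vector of candidate row indices.
#' @param target non-negative integer number of negatives to retain.
#' @param seed integer RNG seed.
#' @return Integer vector of retained indices.
#' @export
undersample_negatives <- function(negative_indices, target, seed) {
  target <- as.integer(target)
  if (target < 0L) stop_config("target must be >= 0")
  m <- min(target, length(negative_indices))
  if (m == 0L) return(integer(0))
  if (m == length(negative_indices)) return(negative_indices)
  with_seed(seed, sample(negative_indices, m))
}

#' Assemble one part's balanced training set
#'
#' Concatenates all original positives, `fp * n_pos` SMOTE-synthesized
#' positives, and `ratio * (1 + fp) * n_pos` negatives sampled uniformly
#' from this part's negatives (all of them when the part is smaller than
#' the target). The result is the balanced set one forest trains on.
#'
#' @param dataset a [smurf_dataset()].
#' @param part_negatives integer vector of this part's negative row
#'   indices.
#' @param h a [hyperparams()] object.
#' @param seed master integer seed; the effective seed is derived from
#'   `(seed, part_index)` so parts are independent and schedule-invariant.
#' @param part_index 0-based index of the part.
#' @return An object of class `smurf_part`: list with `X` (matrix), `y`
#'   (0/1 integer vector), `provenance` (factor over `original_positive`,
#'   `synthetic_positive`, `sampled_negative`) and `part_index`.
#' @export
assemble_part <- function(dataset, part_negatives, h, seed, part_index = 0L) {
  stopifnot(inherits(dataset, "smurf_dataset"))
  h <- as_hyperparams(h)
  pos_idx <- which(dataset$labels == 1L)
  n_pos <- length(pos_idx)
  if (n_pos < 1L) stop_config("part assembly requires >=1 positive")
  part_seed <- derive_seed(seed, part_index)
  positives <- dataset$features[pos_idx, , drop = FALSE]
  synth <- smote_oversample(positives, h$fp, h$k, part_seed)
  target_neg <- h$ratio * (1L + h$fp) * n_pos
  keep_neg <- undersample_negatives(part_negatives, target_neg,
                                    derive_seed(part_seed, 1L))
  X <- rbind(positives, synth,
             dataset$features[keep_neg, , drop = FALSE])
  rownames(X) <- NULL
  y <- c(rep(1L, n_pos + nrow(synth)), rep(0L, length(keep_neg)))
  prov <- factor(
    c(rep("original_positive", n_pos),
      rep("synthetic_positive", nrow(synth)),
      rep("sampled_negative", length(keep_neg))),
    levels = c("original_positive", "synthetic_positive", "sampled_negative")
  )
  structure(
    list(X = X, y = y, provenance = prov,
         part_index = as.integer(part_index)),
    class = "smurf_part"
  )
}
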