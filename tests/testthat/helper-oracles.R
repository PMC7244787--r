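# Independent brute-force oracles, deliberately naive so they share no
# code path with the package implementations.

# AUROC by exhaustive positive-negative pair counting.
auroc_brute <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# AUPRC as an explicit loop over distinct descending thresholds.
auprc_brute <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels == 1)
  ap <- 0
  prev_recall <- 0
  for (t in thr) {
    called <- scores >= t
    tp <- sum(called & labels == 1)
    precision <- tp / sum(called)
    recall <- tp / n_pos
    ap <- ap + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  ap
}

# Brute-force k nearest neighbours (Euclidean, self excluded) of row i.
knn_brute <- function(P, i, k) {
  d2 <- colSums((t(P) - P[i, ])^2)
  d2[i] <- Inf
  order(d2)[seq_len(min(k, nrow(P) - 1L))]
}

# Does synthetic row z lie on the segment [p, p + u*(q - p)), u in [0,1),
# for some original positive p and one of its k nearest neighbours q?
on_some_segment <- function(z, P, k, tol = 1e-9) {
  n <- nrow(P)
  for (i in seq_len(n)) {
    p <- P[i, ]
    for (j in knn_brute(P, i, k)) {
      q <- P[j, ]
      dir <- q - p
      nz <- which(abs(dir) > tol)
      u <- if (length(nz) == 0) 0 else (z[nz[1]] - p[nz[1]]) / dir[nz[1]]
      if (u >= -tol && u < 1 + tol &&
          max(abs(z - (p + u * dir))) <= tol * (1 + max(abs(z)))) {
        return(TRUE)
      }
    }
  }
  FALSE
}

# Tiny well-separated dataset for fast ensemble tests.
tiny_dataset <- function(n = 300, n_pos = 20, effect = 3, seed = 42,
                         n_bands = 0, n_categories = 0) {
  generate_synth(synth_spec(n, n_pos, n_features = 6, n_informative = 2,
                            effect_size = effect, n_bands = n_bands,
                            n_categories = n_categories, seed = seed))
}
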