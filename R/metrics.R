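# Ranking metrics. Under extreme imbalance AUPRC is the informative
# metric (and the tuning objective); AUROC is reported alongside it.

check_scored <- function(scores, labels, need_neg = TRUE) {
  if (length(scores) != length(labels)) {
    stop_data("scores and labels differ in length (", length(scores),
              " vs ", length(labels), ")")
  }
  if (length(scores) == 0L) stop_data("empty score vector")
  if (anyNA(scores) || any(!is.finite(scores))) {
    stop_data("scores contain missing or non-finite values")
  }
  labels <- as.integer(labels > 0)
  if (sum(labels) == 0L) stop_data("metric undefined: no positive samples")
  if (need_neg && sum(labels == 0L) == 0L) {
    stop_data("metric undefined: no negative samples")
  }
  labels
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney statistic: the probability that a
#' random positive is scored above a random negative, with ties counted
#' one half. Invariant under any strictly monotone transform of the
#' scores.
#'
#' @param scores numeric score vector (higher = more positive).
#' @param labels 0/1 vector of the same length; both classes must be
#'   present.
#' @return AUROC in `[0, 1]`.
#' @examples
#' auroc(c(0.8, 0.3, 0.5, 0.1), c(1, 1, 0, 0))
#' @export
auroc <- function(scores, labels) {
  labels <- check_scored(scores, labels)
  n_pos <- sum(labels)
  n_neg <- length(labels) - n_pos
  # midranks make the rank-sum identity handle ties exactly
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve
#'
#' Non-interpolated average precision: the sum over distinct descending
#' score thresholds of (increase in recall) x (precision at that
#' threshold). Samples with equal scores form a single tie group
#' processed at one threshold, so the value does not depend on the
#' ordering of tied samples.
#'
#' @inheritParams auroc
#' @return AUPRC in `(0, 1]`.
#' @examples
#' auprc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0))
#' @export
auprc <- function(scores, labels) {
  labels <- check_scored(scores, labels, need_neg = FALSE)
  n_pos <- sum(labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  # last index of each tie group in the sorted order
  group_end <- which(!duplicated(s, fromLast = TRUE))
  tp <- cumsum(y)[group_end]
  n_at <- group_end
  precision <- tp / n_at
  recall <- tp / n_pos
  sum(diff(c(0, recall)) * precision)
}

#' Tabulate ROC or precision-recall curve points
#'
#' One row per distinct score threshold (descending), suitable for
#' dumping to TSV and plotting.
#'
#' @inheritParams auroc
#' @param type `"roc"` for (threshold, fpr, tpr) or `"pr"` for
#'   (threshold, recall, precision).
#' @return A data.frame of curve points.
#' @export
metric_curve <- function(scores, labels, type = c("roc", "pr")) {
  type <- match.arg(type)
  labels <- check_scored(scores, labels)
  n_pos <- sum(labels)
  n_neg <- length(labels) - n_pos
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  group_end <- which(!duplicated(s, fromLast = TRUE))
  tp <- cumsum(y)[group_end]
  fp <- group_end - tp
  if (type == "roc") {
    data.frame(threshold = s[group_end], fpr = fp / n_neg, tpr = tp / n_pos)
  } else {
    data.frame(threshold = s[group_end], recall = tp / n_pos,
               precision = tp / group_end)
  }
}
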