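# ROC curve, AUROC (Mann-Whitney form), and the Youden screening cutoff.

#' ROC staircase and AUROC for real-valued scores
#'
#' AUROC is computed in the Mann-Whitney form: (concordant pairs + half the
#' tied pairs) / (n_pos * n_neg), via ranks. The ROC staircase sweeps the
#' sorted unique scores from high to low, grouping ties, and runs from (0, 0)
#' to (1, 1).
#'
#' @param scores Numeric scores, higher = more likely positive.
#' @param labels 0/1 labels (both classes required).
#' @return List with `roc` (data frame `threshold`, `fpr`, `tpr`) and
#'   `auroc`.
#' @export
roc_auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) hp_stop("scores/labels length mismatch")
  if (anyNA(scores) || anyNA(labels)) hp_stop("scores and labels must be complete")
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    hp_stop("AUROC undefined: only one class present")
  r <- rank(scores)  # midranks handle ties as half-concordant
  auroc <- (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- cumsum(vapply(thr, function(t) sum(labels == 1L & scores == t),
                      numeric(1)))
  fp <- cumsum(vapply(thr, function(t) sum(labels == 0L & scores == t),
                      numeric(1)))
  roc <- data.frame(threshold = c(Inf, thr),
                    fpr = c(0, fp / n_neg),
                    tpr = c(0, tp / n_pos))
  list(roc = roc, auroc = auroc)
}

#' Youden-optimal screening cutoff from an ROC staircase
#'
#' Maximizes Youden's J = TPR - FPR over the ROC thresholds; ties are broken
#' toward the higher threshold (fewer retained pairs).
#'
#' @param roc ROC data frame from [roc_auroc()].
#' @return List with `threshold` and the attained `j`.
#' @export
youden_cutoff <- function(roc) {
  stopifnot(all(c("threshold", "fpr", "tpr") %in% names(roc)))
  j <- roc$tpr - roc$fpr
  best_j <- max(j)
  cand <- roc$threshold[j == best_j]
  list(threshold = max(cand), j = best_j)
}
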