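#' Area under the ROC curve (rank / Mann-Whitney formulation)
#'
#' AUC equals the probability that a random positive outranks a random
#' negative; ties receive half credit via midranks.
#'
#' @param scores numeric class-1 scores
#' @param labels binary 0/1 labels
#' @return AUC in \[0,1\], or `NA` if either class is absent
#' @export
auc_rank <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cohen's kappa for binary predictions
#'
#' Chance-corrected agreement between predicted and true labels.
#'
#' @param pred predicted 0/1 labels
#' @param truth true 0/1 labels
#' @return kappa in \[-1,1\] (`NA` when expected agreement is 1)
#' @export
cohen_kappa <- function(pred, truth) {
  pred <- as.integer(pred); truth <- as.integer(truth)
  n <- length(truth)
  po <- mean(pred == truth)
  pe <- (sum(truth == 1) * sum(pred == 1) +
           sum(truth == 0) * sum(pred == 0)) / n^2
  if (pe >= 1) return(NA_real_)
  (po - pe) / (1 - pe)
}

#' Compare two AUC distributions by a two-sided Mann-Whitney U test
#'
#' @param auc_samples_a,auc_samples_b numeric vectors (length >= 10 each),
#'   e.g. per-split AUCs of two approaches
#' @return two-sided p-value (exact for small tie-free samples, otherwise
#'   the normal approximation with tie correction)
#' @export
compare_approaches <- function(auc_samples_a, auc_samples_b) {
  if (length(auc_samples_a) < 10 || length(auc_samples_b) < 10) {
    stop("need >= 10 values per group for the rank-sum comparison")
  }
  p <- suppressWarnings(wilcox.test(auc_samples_a, auc_samples_b)$p.value)
  if (is.nan(p)) 1 else p    # fully tied samples carry no evidence
}
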