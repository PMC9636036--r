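#' Beta values from read counts with a minimum-depth filter
#'
#' beta = methylated / total where total >= `min_depth`; shallower sites are
#' marked missing (`NA`). Depth exactly at the threshold is retained.
#'
#' @param methylated,total nonnegative integer matrices (CpG x sample) with
#'   identical dimensions; rownames are CpG ids
#' @param min_depth minimum read depth to retain a site (default 10)
#' @return numeric matrix in \[0,1\] with `NA` at filtered entries
#' @export
compute_beta <- function(methylated, total, min_depth = 10) {
  stopifnot(all(dim(methylated) == dim(total)))
  if (any(methylated < 0) || any(total < 0)) stop("counts must be nonnegative")
  bad <- which(methylated > total, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    id <- rownames(methylated)[bad[1, 1]] %||% as.character(bad[1, 1])
    stop("methylated exceeds total at CpG ", id)
  }
  beta <- methylated / total
  beta[total < min_depth] <- NA_real_
  beta[total == 0 & min_depth <= 0] <- NA_real_
  dimnames(beta) <- dimnames(methylated)
  beta
}

#' Fixed-window coverage-weighted smoothing of beta values
#'
#' Replaces each beta by the coverage-weighted mean of values within
#' `window_bp` on the same chromosome (a documented simple stand-in for a
#' local-likelihood smoother). Missing values are excluded; an isolated CpG
#' is returned unchanged; `window_bp = 0` is the identity.
#'
#' @param betas CpG x sample matrix (may contain `NA`)
#' @param positions data.frame with `chrom` and `pos`, rows aligned to
#'   `betas`, positions sorted within chromosome
#' @param window_bp half-window in bp (default 500)
#' @param coverage optional CpG x sample weight matrix (read depth); equal
#'   weights when `NULL`
#' @return smoothed matrix, same shape, values in \[0,1\]
#' @export
smooth_betas <- function(betas, positions, window_bp = 500, coverage = NULL) {
  betas <- as.matrix(betas)
  stopifnot(nrow(betas) == nrow(positions))
  if (window_bp == 0) return(betas)
  out <- betas
  for (chr in unique(positions$chrom)) {
    rows <- which(positions$chrom == chr)
    pos <- positions$pos[rows]
    if (is.unsorted(pos)) stop("positions must be sorted within chromosome")
    lo <- findInterval(pos - window_bp - 0.5, pos) + 1L
    hi <- findInterval(pos + window_bp + 0.5 - 1e-9, pos)
    for (j in seq_len(ncol(betas))) {
      b <- betas[rows, j]
      w <- if (is.null(coverage)) rep(1, length(rows)) else coverage[rows, j]
      w[is.na(b)] <- 0
      bw <- ifelse(is.na(b), 0, b * w)
      cw <- cumsum(c(0, w))
      cbw <- cumsum(c(0, bw))
      sw <- cw[hi + 1L] - cw[lo]
      sbw <- cbw[hi + 1L] - cbw[lo]
      sm <- ifelse(sw > 0, sbw / sw, b)
      sm[is.na(b)] <- NA_real_
      out[rows, j] <- sm
    }
  }
  out
}

subset_methylome <- function(x, idx) {
  x$cpg_ids <- x$cpg_ids[idx]
  x$positions <- x$positions[idx, , drop = FALSE]
  for (f in c("betas", "meth", "total")) {
    if (!is.null(x[[f]])) x[[f]] <- x[[f]][idx, , drop = FALSE]
  }
  if (!is.null(x$class_means)) x$class_means <- x$class_means[idx, , drop = FALSE]
  x
}

#' Impute missing betas with the per-CpG cross-sample mean
#'
#' @param betas matrix with possible `NA`
#' @return matrix without `NA` (rows that are entirely missing stay `NA`)
#' @export
impute_missing <- function(betas) {
  mu <- rowMeans(betas, na.rm = TRUE)
  idx <- which(is.na(betas), arr.ind = TRUE)
  if (nrow(idx)) betas[idx] <- mu[idx[, 1]]
  betas
}

#' Restrict a reference atlas and a bulk methylome to a shared CpG universe
#'
#' Keeps the CpGs investigated on both sides (in the atlas' order), drops
#' sites missing in more than `max_missing` of the samples of either side,
#' and mean-imputes any remaining missing entries.
#'
#' @param atlas a `ReferenceAtlas`
#' @param bulk a `BulkMethylome`
#' @param max_missing maximum tolerated missing fraction per CpG (default 0.2)
#' @return list with the restricted `atlas` and `bulk`, rows aligned
#' @export
intersect_universe <- function(atlas, bulk, max_missing = 0.2) {
  common <- intersect(atlas$cpg_ids, bulk$cpg_ids)
  if (!length(common)) {
    stop(sprintf("empty CpG intersection (atlas %d, bulk %d sites)",
                 length(atlas$cpg_ids), length(bulk$cpg_ids)))
  }
  a_idx <- match(common, atlas$cpg_ids)
  b_idx <- match(common, bulk$cpg_ids)
  miss_a <- rowMeans(is.na(atlas$betas[a_idx, , drop = FALSE]))
  miss_b <- rowMeans(is.na(bulk$betas[b_idx, , drop = FALSE]))
  keep <- miss_a <= max_missing & miss_b <= max_missing
  atlas <- subset_methylome(atlas, a_idx[keep])
  bulk <- subset_methylome(bulk, b_idx[keep])
  atlas$betas <- impute_missing(atlas$betas)
  bulk$betas <- impute_missing(bulk$betas)
  list(atlas = atlas, bulk = bulk)
}

#' Construct a bulk methylome from count matrices
#'
#' Applies the depth filter via [compute_beta()].
#'
#' @param meth,total CpG x sample count matrices with "chrom:pos" rownames
#' @param min_depth depth filter (default 10)
#' @return a `BulkMethylome`
#' @export
bulk_from_counts <- function(meth, total, min_depth = 10) {
  ids <- rownames(meth)
  structure(list(
    cpg_ids = ids, positions = split_cpg_id(ids),
    betas = compute_beta(meth, total, min_depth = min_depth),
    meth = meth, total = total,
    sample_ids = colnames(meth)
  ), class = "BulkMethylome")
}

#' Construct a reference atlas from a beta matrix and class labels
#'
#' @param betas CpG x sample matrix with "chrom:pos" rownames
#' @param class_labels per-sample cell-state class
#' @param meth,total optional count matrices (needed for [call_dmcs()])
#' @return a `ReferenceAtlas`
#' @export
reference_atlas <- function(betas, class_labels, meth = NULL, total = NULL) {
  stopifnot(ncol(betas) == length(class_labels))
  if (length(unique(class_labels)) < 2) stop(">= 2 classes required")
  ids <- rownames(betas)
  structure(list(
    cpg_ids = ids, positions = split_cpg_id(ids),
    betas = betas, meth = meth, total = total,
    sample_ids = colnames(betas) %||% paste0("s", seq_len(ncol(betas))),
    class_labels = class_labels,
    state = class_state(class_labels)
  ), class = "ReferenceAtlas")
}
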