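#' Call differentially methylated CpGs between two reference classes
#'
#' Two-group comparison of methylation proportions from read counts under a
#' beta-binomial model: per group the proportion is estimated from pooled
#' counts (optionally coverage-weighted window smoothing of the pooled
#' proportion when `smoothing` is on); dispersion is estimated per group by
#' method-of-moments across replicates and shrunk toward the local (+-
#' `window_bp`) mean dispersion; the Wald-type statistic divides the effect
#' by a standard error computed at the pooled (null) proportion, and p
#' comes from the normal reference. Sites with zero total coverage in a
#' group are skipped (count recorded in the `skipped` attribute).
#'
#' @param atlas a `ReferenceAtlas` with `meth`/`total` counts
#' @param class_a,class_b class labels (>= 2 replicates each)
#' @param p_threshold significance cutoff for the DMC flag (default 0.001)
#' @param smoothing smooth pooled proportions in a +-`window_bp` window
#'   (default TRUE)
#' @param window_bp half-window for smoothing and dispersion shrinkage
#' @param shrink weight of the local mean in the dispersion shrinkage
#' @param return_all return every tested site instead of only DMCs
#' @return data.frame: `cpg_id`, `mean_a`, `mean_b`, `effect` (a - b),
#'   `stat`, `p`, `dmc`, `direction` (hypo/hyper in class_a); attribute
#'   `skipped` counts zero-coverage sites
#' @export
call_dmcs <- function(atlas, class_a, class_b, p_threshold = 0.001,
                      smoothing = TRUE, window_bp = 500, shrink = 0.5,
                      return_all = FALSE) {
  ia <- which(atlas$class_labels == class_a)
  ib <- which(atlas$class_labels == class_b)
  if (length(ia) < 2 || length(ib) < 2) {
    stop("both classes need >= 2 replicates with count data")
  }
  grp <- function(idx) {
    m <- atlas$meth[, idx, drop = FALSE]
    n <- atlas$total[, idx, drop = FALSE]
    Sm <- rowSums(m); Sn <- rowSums(n)
    phat <- ifelse(Sn > 0, Sm / Sn, NA_real_)
    # method-of-moments dispersion across replicates
    pr <- m / ifelse(n > 0, n, NA)
    pbar <- rowMeans(pr, na.rm = TRUE)
    s2 <- apply(pr, 1, var, na.rm = TRUE)
    inv_n <- rowMeans(ifelse(n > 0, 1 / n, NA), na.rm = TRUE)
    frac <- rowMeans(ifelse(n > 0, (n - 1) / n, NA), na.rm = TRUE)
    pq <- pbar * (1 - pbar)
    phi <- ifelse(pq > 0 & frac > 0, (s2 / pq - inv_n) / frac, 0)
    phi[!is.finite(phi)] <- 0
    phi <- pmin(pmax(phi, 0), 0.9)
    # variance multiplier sum n_i (1 + (n_i - 1) phi) for pooled estimator
    list(Sm = Sm, Sn = Sn, phat = phat, phi = phi, n = n)
  }
  a <- grp(ia); b <- grp(ib)
  keep <- a$Sn > 0 & b$Sn > 0
  skipped <- sum(!keep)

  pos <- atlas$positions
  # local shrinkage of the averaged dispersion
  phi <- (a$phi + b$phi) / 2
  local_phi <- drop(smooth_betas(matrix(phi, ncol = 1), pos,
                                 window_bp = window_bp))
  phi <- (1 - shrink) * phi + shrink * local_phi

  mean_a <- a$phat; mean_b <- b$phat
  if (smoothing) {
    mean_a <- drop(smooth_betas(matrix(mean_a, ncol = 1), pos,
                                window_bp = window_bp,
                                coverage = matrix(a$Sn, ncol = 1)))
    mean_b <- drop(smooth_betas(matrix(mean_b, ncol = 1), pos,
                                window_bp = window_bp,
                                coverage = matrix(b$Sn, ncol = 1)))
  }
  effect <- mean_a - mean_b
  # null (pooled) proportion with a continuity guard for the variance
  p0 <- (a$Sm + b$Sm + 0.5) / (a$Sn + b$Sn + 1)
  vmult <- function(g) {
    rowSums(g$n * (1 + pmax(g$n - 1, 0) * phi)) / pmax(g$Sn, 1)^2
  }
  se <- sqrt(p0 * (1 - p0) * (vmult(a) + vmult(b)))
  stat <- ifelse(se > 0, effect / se, 0)
  p <- 2 * pnorm(-abs(stat))

  res <- data.frame(
    cpg_id = atlas$cpg_ids, mean_a = mean_a, mean_b = mean_b,
    effect = effect, stat = stat, p = p,
    dmc = p < p_threshold,
    direction = ifelse(effect < 0, "hypo-in-a", "hyper-in-a"),
    stringsAsFactors = FALSE
  )[keep, ]
  if (!return_all) res <- res[res$dmc, ]
  attr(res, "skipped") <- skipped
  attr(res, "classes") <- c(class_a, class_b)
  res
}

#' Categorize signature CpGs by differential methylation between class pairs
#'
#' Tests each signature CpG (via the [call_dmcs()] machinery at
#' `p_threshold`) for every class pair in three categories: matched
#' TIIC/PBMC states of the same immune cell type (TIIC-PBMC), pairs of
#' distinct TIIC types (TIIC-TIIC), and pairs of distinct PBMC types
#' (PBMC-PBMC). A CpG counts in a category when significant for at least
#' one of its pairs; categories are not mutually exclusive.
#'
#' @param signature a `SignatureMatrix`
#' @param atlas a `ReferenceAtlas` containing the signature CpGs
#' @param p_threshold DMC cutoff (default 0.001)
#' @param smoothing passed to [call_dmcs()]
#' @return list with `counts` (named integer vector) and `members` (named
#'   list of CpG-id sets)
#' @export
categorize_signature_dmcs <- function(signature, atlas, p_threshold = 0.001,
                                      smoothing = TRUE) {
  idx <- match(signature$cpg_ids, atlas$cpg_ids)
  if (anyNA(idx)) stop("signature CpGs missing from atlas")
  sub <- subset_methylome(atlas, idx)
  present <- unique(sub$class_labels)
  tiic <- present[class_state(present) == "TIIC"]
  pbmc <- present[class_state(present) == "PBMC"]
  pairs <- list(`TIIC-PBMC` = Filter(function(p) all(p %in% present),
                                     matched_state_pairs()),
                `TIIC-TIIC` = if (length(tiic) >= 2)
                  combn(sort(tiic), 2, simplify = FALSE) else list(),
                `PBMC-PBMC` = if (length(pbmc) >= 2)
                  combn(sort(pbmc), 2, simplify = FALSE) else list())
  members <- lapply(pairs, function(pl) {
    hits <- character(0)
    for (p in pl) {
      d <- call_dmcs(sub, p[1], p[2], p_threshold = p_threshold,
                     smoothing = smoothing)
      hits <- union(hits, d$cpg_id)
    }
    hits
  })
  list(counts = vapply(members, length, 1L), members = members)
}
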