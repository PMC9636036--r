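#' Select signature CpG sites and assemble the signature matrix
#'
#' One-vs-rest Welch t test per cell-state class at every CpG on the
#' reference betas, Benjamini-Hochberg adjusted across CpGs within each
#' class. CpGs passing `fdr <= fdr_threshold` and `|mean difference| >=
#' min_delta_beta` are ranked by absolute mean difference and the top
#' `max_per_class` kept. A CpG selected for several classes is attributed
#' to the class with the largest absolute difference. Matrix entries are
#' per-class median (optionally mean) betas at the selected sites.
#'
#' The three reference modes restrict which samples enter: `"TIIC"`
#' excludes PBMC classes, `"PBMC"` excludes TIIC classes, `"TIIC+PBMC"`
#' uses all; stromal classes (epithelial, fibroblast) are always included.
#'
#' @param atlas a `ReferenceAtlas` with per-sample class labels
#' @param mode `"TIIC+PBMC"`, `"TIIC"` or `"PBMC"`
#' @param fdr_threshold BH-adjusted p cutoff (default 0.05)
#' @param min_delta_beta minimum absolute one-vs-rest mean difference
#'   (default 0.2)
#' @param max_per_class per-class cap on selected CpGs (default 200)
#' @param use_mean use the per-class mean instead of the median
#' @param allow_relax when a class yields no passing CpG, keep its 5
#'   best-ranked sub-threshold CpGs instead of erroring
#' @return object of class `SignatureMatrix`: `cpg_ids`, `class_labels`,
#'   `values` (CpG x class), `attribution`, `mode`, `stats`
#' @export
select_signature_cpgs <- function(atlas, mode = c("TIIC+PBMC", "TIIC", "PBMC"),
                                  fdr_threshold = 0.05, min_delta_beta = 0.2,
                                  max_per_class = 200, use_mean = FALSE,
                                  allow_relax = FALSE) {
  mode <- match.arg(mode)
  keep_states <- switch(mode,
    "TIIC+PBMC" = c("TIIC", "PBMC", "stromal"),
    "TIIC" = c("TIIC", "stromal"),
    "PBMC" = c("PBMC", "stromal"))
  sel <- atlas$state %in% keep_states
  betas <- atlas$betas[, sel, drop = FALSE]
  cls <- atlas$class_labels[sel]
  classes <- unique(cls)
  if (length(classes) < 2) stop("need >= 2 classes for mode ", mode)
  for (k in classes) {
    if (sum(cls == k) < 2) {
      stop("class ", k, " has < 2 replicates; variance undefined")
    }
  }

  n_cpg <- nrow(betas)
  per_class <- vector("list", length(classes))
  names(per_class) <- classes
  effect_mat <- matrix(0, n_cpg, length(classes),
                       dimnames = list(rownames(betas), classes))
  for (k in classes) {
    in_k <- cls == k
    n1 <- sum(in_k); n2 <- sum(!in_k)
    if (n1 < 2) stop("class ", k, " has < 2 replicates; variance undefined")
    x1 <- betas[, in_k, drop = FALSE]
    x2 <- betas[, !in_k, drop = FALSE]
    m1 <- rowMeans(x1); m2 <- rowMeans(x2)
    v1 <- apply(x1, 1, var); v2 <- apply(x2, 1, var)
    se2 <- v1 / n1 + v2 / n2
    d <- m1 - m2
    tt <- d / sqrt(pmax(se2, 1e-24))
    df <- pmax(se2^2 / pmax(v1^2 / (n1^2 * (n1 - 1)) +
                              v2^2 / (n2^2 * (n2 - 1)), 1e-300), 1)
    p <- 2 * pt(-abs(tt), df)
    fdr <- p.adjust(p, method = "BH")
    effect_mat[, k] <- d
    pass <- which(fdr <= fdr_threshold & abs(d) >= min_delta_beta)
    if (!length(pass)) {
      if (!allow_relax) {
        stop("no signature CpG passes thresholds for class ", k,
             " (set allow_relax = TRUE to keep its best-ranked sites)")
      }
      warning("class ", k, " retained with sub-threshold CpGs")
      pass <- order(p)[seq_len(min(5, n_cpg))]
    }
    pass <- pass[order(-abs(d[pass]))]
    per_class[[k]] <- head(pass, max_per_class)
  }

  all_idx <- sort(unique(unlist(per_class)))
  # attribution: the class with the largest |effect| among selectors
  attribution <- vapply(all_idx, function(i) {
    selectors <- names(which(vapply(per_class, function(s) i %in% s, TRUE)))
    selectors[which.max(abs(effect_mat[i, selectors]))]
  }, "")
  lost <- setdiff(classes, unique(attribution))
  if (length(lost) && !allow_relax) {
    stop("class(es) lost all CpGs to stronger attributions: ",
         paste(lost, collapse = ", "))
  }

  ids <- rownames(betas)[all_idx]
  centre <- if (use_mean) rowMeans else function(x) apply(x, 1, median)
  values <- vapply(classes, function(k)
    centre(betas[all_idx, cls == k, drop = FALSE]), numeric(length(all_idx)))
  values <- matrix(values, nrow = length(all_idx),
                   dimnames = list(ids, classes))

  structure(list(
    cpg_ids = ids,
    class_labels = classes,
    values = values,
    attribution = setNames(attribution, ids),
    mode = mode,
    effects = effect_mat[all_idx, , drop = FALSE]
  ), class = "SignatureMatrix")
}

#' Extract the mixture matrix for a signature from a bulk methylome
#'
#' Rows are ordered exactly as the signature CpGs; signature CpGs absent
#' from the bulk are dropped from both sides (with a warning giving the
#' count). More than half the signature missing is an error.
#'
#' @param bulk a `BulkMethylome` with betas
#' @param signature a `SignatureMatrix`
#' @return list with `mixture` (CpG x sample matrix) and the (possibly
#'   reduced) `signature`
#' @export
build_mixture_matrix <- function(bulk, signature) {
  present <- signature$cpg_ids %in% bulk$cpg_ids
  if (mean(present) < 0.5) {
    stop(sprintf("signature inapplicable: only %d of %d signature CpGs in bulk",
                 sum(present), length(present)))
  }
  if (!all(present)) {
    warning(sum(!present), " signature CpGs absent from bulk; dropped")
    keep <- which(present)
    signature$cpg_ids <- signature$cpg_ids[keep]
    signature$values <- signature$values[keep, , drop = FALSE]
    signature$attribution <- signature$attribution[keep]
    signature$effects <- signature$effects[keep, , drop = FALSE]
  }
  mixture <- bulk$betas[match(signature$cpg_ids, bulk$cpg_ids), , drop = FALSE]
  list(mixture = mixture, signature = signature)
}
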