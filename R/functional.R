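#' Map CpG sites to nearby regulatory elements and their target genes
#'
#' A CpG maps to a regulatory element (RE) when the distance from the CpG
#' position to the nearest base of the RE interval is at most `window_bp`
#' (0 when inside; the boundary is inclusive, so a gap of exactly
#' `window_bp` maps). Coordinates are 0-based half-open (BED).
#'
#' @param cpg_ids character "chrom:pos" identifiers
#' @param re_map list with `intervals` (data.frame chrom/start/end/re_id)
#'   and `re_targets` (named character re_id -> gene); a `ToyGenome` works
#'   via its `re_intervals`/`re_targets` fields
#' @param window_bp maximum distance in bp (default 1250)
#' @return data.frame: `cpg_id`, `re_id`, `gene`, `distance` (one row per
#'   CpG-RE pair within the window)
#' @export
map_cpgs_to_res <- function(cpg_ids, re_map, window_bp = 1250) {
  intervals <- re_map$intervals %||% re_map$re_intervals
  targets <- re_map$re_targets
  coords <- split_cpg_id(cpg_ids)
  if (anyNA(coords$pos)) stop("malformed CpG ids")
  shared <- intersect(unique(coords$chrom), unique(intervals$chrom))
  if (!length(shared)) {
    stop("no shared chromosome between CpGs (",
         paste(unique(coords$chrom), collapse = ","), ") and REs (",
         paste(unique(intervals$chrom), collapse = ","), ")")
  }
  cpg_gr <- GenomicRanges::GRanges(
    coords$chrom, IRanges::IRanges(coords$pos + 1L, width = 1L))
  re_gr <- GenomicRanges::GRanges(
    intervals$chrom, IRanges::IRanges(intervals$start + 1L, intervals$end))
  hits <- GenomicRanges::findOverlaps(cpg_gr, re_gr, maxgap = window_bp)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  # base-to-base gap in 0-based coordinates: 0 inside the interval,
  # otherwise distance to the nearest interval base
  p <- coords$pos[q]
  st <- intervals$start[s]; en <- intervals$end[s]
  gap <- ifelse(p >= st & p < en, 0L, ifelse(p < st, st - p, p - (en - 1L)))
  keep <- gap <= window_bp
  data.frame(
    cpg_id = cpg_ids[q[keep]],
    re_id = intervals$re_id[s[keep]],
    gene = unname(targets[intervals$re_id[s[keep]]]),
    distance = gap[keep],
    stringsAsFactors = FALSE
  )
}

#' Hypergeometric gene-set enrichment with BH correction
#'
#' Upper-tail hypergeometric test of the overlap between the target genes
#' and each gene set intersected with the background, BH-adjusted across
#' the tested terms. Gene-level deduplication is the caller's concern
#' (each gene counts once).
#'
#' @param target_genes character vector (must be a subset of background)
#' @param background_genes character vector, the gene universe
#' @param gene_sets named list of gene vectors
#' @param restrict_to optional character vector of term ids to test (e.g.
#'   the configured child terms of an immune-response parent term)
#' @return data.frame: term, overlap, term_size, target_size,
#'   background_size, p, adj_p, genes (comma-separated overlap)
#' @export
enrich_go <- function(target_genes, background_genes, gene_sets,
                      restrict_to = NULL) {
  target <- unique(target_genes)
  background <- unique(background_genes)
  bad <- setdiff(target, background)
  if (length(bad)) {
    stop("target genes outside background: ", paste(bad, collapse = ", "))
  }
  if (!length(gene_sets)) stop("gene_sets is empty")
  if (!is.null(restrict_to)) gene_sets <- gene_sets[names(gene_sets) %in% restrict_to]
  N <- length(background); n <- length(target)
  rows <- lapply(names(gene_sets), function(term) {
    term_bg <- intersect(gene_sets[[term]], background)
    K <- length(term_bg)
    ov <- intersect(target, term_bg)
    x <- length(ov)
    p <- if (K == 0) 1 else phyper(x - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, overlap = x, term_size = K, target_size = n,
               background_size = N, p = p,
               genes = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adj_p <- p.adjust(out$p, method = "BH")
  out[order(out$p), c("term", "overlap", "term_size", "target_size",
                      "background_size", "p", "adj_p", "genes")]
}

#' Test hypomethylation of DMCs near REs of marker genes
#'
#' For each marker gene, collects the DMCs lying within `window_bp` of any
#' RE targeting it (the IL12 marker expands to IL12A and IL12B) and runs a
#' paired two-sided t test of the group-A vs group-B mean methylation
#' across those DMCs (paired by CpG). Markers with fewer than `min_dmcs`
#' proximal DMCs are reported untestable rather than erroring.
#'
#' @param dmcs data.frame from [call_dmcs()] between the two states of one
#'   cell type (e.g. TIIC-DC vs PBMC-DC), with `cpg_id`, `mean_a`, `mean_b`
#' @param marker_genes character vector of marker gene symbols
#' @param re_map RE map (see [map_cpgs_to_res()])
#' @param window_bp proximity window (default 1250)
#' @param min_dmcs minimum proximal DMCs to test a marker (default 3)
#' @return data.frame: marker, n_dmcs, mean_diff, statistic, p_value,
#'   direction, testable, reason
#' @export
marker_hypomethylation_test <- function(dmcs, marker_genes, re_map,
                                        window_bp = 1250, min_dmcs = 3) {
  mapping <- if (nrow(dmcs)) {
    map_cpgs_to_res(dmcs$cpg_id, re_map, window_bp = window_bp)
  } else {
    data.frame(cpg_id = character(0), gene = character(0))
  }
  all_targets <- unique(unname((re_map$re_targets)))
  rows <- lapply(marker_genes, function(mk) {
    genes <- if (mk == "IL12") c("IL12A", "IL12B") else mk
    untestable <- function(reason) {
      data.frame(marker = mk, n_dmcs = 0L, mean_diff = NA_real_,
                 statistic = NA_real_, p_value = NA_real_,
                 direction = NA_character_, testable = FALSE,
                 reason = reason, stringsAsFactors = FALSE)
    }
    if (!any(genes %in% all_targets)) {
      return(untestable("marker absent from RE map"))
    }
    ids <- unique(mapping$cpg_id[mapping$gene %in% genes])
    if (length(ids) < min_dmcs) {
      return(untestable(sprintf("only %d proximal DMCs (< %d)",
                                length(ids), min_dmcs)))
    }
    sub <- dmcs[match(ids, dmcs$cpg_id), ]
    tt <- t.test(sub$mean_a, sub$mean_b, paired = TRUE)
    md <- mean(sub$mean_a - sub$mean_b)
    data.frame(marker = mk, n_dmcs = length(ids), mean_diff = md,
               statistic = unname(tt$statistic), p_value = tt$p.value,
               direction = if (md < 0) "hypo-in-a" else "hyper-in-a",
               testable = TRUE, reason = "", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
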