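#' Generate a toy genome with CpGs, regulatory elements and gene sets
#'
#' Lays out `n_cpgs` CpG sites on two chromosomes (~3 kb spacing, so the
#' 1,250 bp regulatory-element windows of neighbouring CpGs never collide),
#' assigns planted roles (class marker, state-DMC, background) by a seeded
#' draw, and places a regulatory element (RE) within 1,250 bp of every
#' planted state-DMC. A quarter of background CpGs receive a decoy RE; the
#' rest lie farther than 1,250 bp from all REs so that enrichment against
#' the plant is testable. REs proximal to state-DMCs target either
#' dendritic-cell activation marker genes or "migration-program" genes;
#' decoy REs target housekeeping genes. Gene sets group these gene families
#' so that the planted enrichment signal is known.
#'
#' @param config a [sim_config()] object
#' @param seed integer seed (default `config$seed`)
#' @return object of class `ToyGenome`: list with `chrom_sizes`,
#'   `cpg_positions` (data.frame chrom/pos, 0-based), `re_intervals`
#'   (data.frame chrom/start/end/re_id, 0-based half-open), `re_targets`
#'   (named character re_id -> gene), `gene_sets` (named list of gene
#'   vectors), and the planted role assignment (`roles`, per CpG).
#' @export
generate_toy_genome <- function(config, seed = config$seed) {
  n_planted <- config$n_classes * config$n_marker_cpgs_per_class +
    config$n_state_dmcs
  if (config$n_cpgs < n_planted) {
    stop(sprintf(
      "config infeasible: %d CpGs cannot host %d planted sites (deficit %d)",
      config$n_cpgs, n_planted, n_planted - config$n_cpgs))
  }
  set.seed(seed)

  n <- config$n_cpgs
  n_chr1 <- ceiling(n / 2)
  chrom <- rep(c("chr1", "chr2"), times = c(n_chr1, n - n_chr1))
  idx_in_chr <- c(seq_len(n_chr1), seq_len(n - n_chr1))
  pos <- as.integer(1000 + (idx_in_chr - 1) * 3000 +
                      sample(0:200, n, replace = TRUE))
  cpg <- data.frame(chrom = chrom, pos = pos, stringsAsFactors = FALSE)
  ids <- cpg_id(chrom, pos)
  chrom_sizes <- tapply(pos, chrom, function(p) max(p) + 2000L)

  # planted roles
  roles <- rep("background", n)
  planted <- sample.int(n, n_planted)
  marker_idx <- planted[seq_len(config$n_classes * config$n_marker_cpgs_per_class)]
  state_idx <- setdiff(planted, marker_idx)
  roles[marker_idx] <- rep(config$class_labels, each = config$n_marker_cpgs_per_class)
  roles[state_idx] <- "state_dmc"

  # one RE per state-DMC; decoys near 25% of background CpGs
  bg_idx <- which(roles == "background")
  decoy_idx <- sort(sample(bg_idx, round(0.25 * length(bg_idx))))
  re_anchor <- c(state_idx, decoy_idx)
  re <- data.frame(
    chrom = cpg$chrom[re_anchor],
    start = cpg$pos[re_anchor] + 250L,
    end = cpg$pos[re_anchor] + 450L,
    re_id = sprintf("RE%05d", seq_along(re_anchor)),
    stringsAsFactors = FALSE
  )

  # targets: DC activation markers on ~40% of state-DMC REs, a migration
  # gene on each remaining state-DMC RE, housekeeping genes on decoys
  n_state <- length(state_idx)
  n_dc <- if (n_state == 0) 0 else max(min(n_state, 8L), round(0.4 * n_state))
  dc_re <- seq_len(n_dc)
  mig_re <- setdiff(seq_len(n_state), dc_re)
  targets <- character(nrow(re))
  targets[dc_re] <- rep_len(dc_marker_genes(), n_dc)
  targets[mig_re] <- sprintf("MIG%03d", seq_along(mig_re))
  decoy_slots <- seq(n_state + 1, length.out = length(decoy_idx))
  targets[decoy_slots] <- sprintf("HK%04d", seq_along(decoy_idx))
  re_targets <- setNames(targets, re$re_id)

  hk_genes <- unique(targets[decoy_slots])
  hk_split <- split(hk_genes, rep_len(1:3, length(hk_genes)))
  gene_sets <- c(
    list(
      immune_cell_migration = sort(unique(targets[mig_re])),
      dendritic_cell_activation = dc_marker_genes()
    ),
    setNames(hk_split, paste0("housekeeping_", seq_along(hk_split)))
  )
  gene_sets <- Filter(length, gene_sets)

  genome <- list(
    chrom_sizes = chrom_sizes,
    cpg_positions = cpg,
    cpg_ids = ids,
    re_intervals = re,
    re_targets = re_targets,
    gene_sets = gene_sets,
    roles = roles,
    marker_idx = marker_idx,
    state_idx = state_idx,
    dc_state_idx = state_idx[dc_re]
  )
  class(genome) <- "ToyGenome"
  genome
}
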