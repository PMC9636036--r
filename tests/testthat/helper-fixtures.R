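# shared synthetic fixtures, built once per test run

small_cfg <- function(seed = 11L, ...) {
  args <- list(n_cpgs = 1200, n_marker_cpgs_per_class = 10,
               n_state_dmcs = 60, seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

.fixtures <- new.env(parent = emptyenv())

# a small complete world: genome, reference atlas, 40-sample bulk cohort
small_world <- function() {
  if (is.null(.fixtures$world)) {
    cfg <- small_cfg()
    genome <- generate_toy_genome(cfg)
    refs <- generate_reference_profiles(genome, cfg)
    cohort <- generate_bulk_cohort(refs$atlas, genome, cfg, 40)
    .fixtures$world <- list(cfg = cfg, genome = genome, atlas = refs$atlas,
                            ref_truth = refs$truth, bulk = cohort$bulk,
                            clinical = cohort$clinical,
                            bulk_truth = cohort$truth)
  }
  .fixtures$world
}

# brute-force AUC: fraction of positive/negative pairs correctly ordered
auc_brute <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg) tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

# brute-force CpG-to-RE mapping under the base-gap definition
map_brute <- function(pos_df, intervals, window_bp) {
  hits <- list()
  for (i in seq_len(nrow(pos_df))) {
    for (j in seq_len(nrow(intervals))) {
      if (pos_df$chrom[i] != intervals$chrom[j]) next
      p <- pos_df$pos[i]
      s <- intervals$start[j]; e <- intervals$end[j]
      gap <- if (p >= s && p < e) 0L else if (p < s) s - p else p - (e - 1L)
      if (gap <= window_bp) hits[[length(hits) + 1]] <- c(i, j, gap)
    }
  }
  if (!length(hits)) return(matrix(numeric(0), ncol = 3))
  do.call(rbind, hits)
}
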