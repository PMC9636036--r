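#!/usr/bin/env Rscript
# Stage 4: interpret the dual-state signature. Signature CpGs are
# categorized by which class pairs they separate (matched TIIC/PBMC states,
# TIIC-TIIC, PBMC-PBMC), the TIIC-PBMC set is mapped to regulatory elements
# within 1,250 bp and tested for gene-set enrichment against the panel-wide
# background, and methylation near REs of dendritic-cell activation markers
# is compared between TIIC-DC and PBMC-DC.

library(methylstate)

out <- "results/analysis"
cfg <- sim_config(seed = 42L)
genome <- generate_toy_genome(cfg)
refs <- generate_reference_profiles(genome, cfg)

cat("signature DMC categories by reference mode:\n")
cat_rows <- list()
for (mode in c("TIIC+PBMC", "TIIC", "PBMC")) {
  sig <- select_signature_cpgs(refs$atlas, mode)
  cats <- categorize_signature_dmcs(sig, refs$atlas)
  cat_rows[[mode]] <- data.frame(mode = mode, t(cats$counts))
  cat(sprintf("  %-10s TIIC-PBMC %3d | TIIC-TIIC %3d | PBMC-PBMC %3d\n",
              mode, cats$counts[["TIIC-PBMC"]], cats$counts[["TIIC-TIIC"]],
              cats$counts[["PBMC-PBMC"]]))
  if (mode == "TIIC+PBMC") state_members <- cats$members[["TIIC-PBMC"]]
}
write.table(do.call(rbind, cat_rows), file.path(out, "dmc_categories.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# enrichment of TIIC-PBMC DMC target genes vs the panel background
mapping <- map_cpgs_to_res(state_members, genome)
background <- unique(map_cpgs_to_res(refs$atlas$cpg_ids, genome)$gene)
enr <- enrich_go(unique(mapping$gene), background, genome$gene_sets)
write.table(enr, file.path(out, "enrichment.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("\ntop enriched gene sets for TIIC-PBMC DMC targets:\n")
print(head(enr[, c("term", "overlap", "term_size", "p", "adj_p")], 3),
      row.names = FALSE)

# DC activation-marker hypomethylation in TIIC-DC vs PBMC-DC
dc <- call_dmcs(refs$atlas, "TIIC-DC", "PBMC-DC")
mt <- marker_hypomethylation_test(
  dc, c("HLA-DRA", "CCR7", "CD40", "CCL22", "IFNG", "IL12", "CD86"), genome)
write.table(mt, file.path(out, "dc_markers.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("\nDC activation-marker regions (negative mean_diff = hypomethylated in TIIC-DC):\n")
print(mt[, c("marker", "n_dmcs", "mean_diff", "p_value", "testable")],
      row.names = FALSE)
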