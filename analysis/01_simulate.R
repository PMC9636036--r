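#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study -- a toy genome with planted
# regulatory structure, sorted-cell reference methylomes for ten cell-state
# classes (four immune types in tumor-infiltrating and blood states, plus
# epithelial cells and fibroblasts), and a 150-patient bulk tumor cohort
# whose recurrence labels depend on the TIIC-CD8T / TIIC-DC / PBMC-DC
# fractions and on clinical covariates.

library(methylstate)

out <- "results/analysis"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(seed = 42L)
genome <- generate_toy_genome(cfg)
refs <- generate_reference_profiles(genome, cfg)
cohort <- generate_bulk_cohort(refs$atlas, genome, cfg, 150)

write_methylome(refs$atlas, file.path(out, "sim"), "atlas")
write_methylome(cohort$bulk, file.path(out, "sim"), "bulk")
write_bed6(genome$re_intervals, file.path(out, "sim", "res.bed"))
write_re_targets(genome$re_targets, file.path(out, "sim", "re_targets.tsv"))
write_gmt(genome$gene_sets, file.path(out, "sim", "gene_sets.gmt"))
write.table(cohort$clinical, file.path(out, "sim", "clinical.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(
  list(true_proportions = as.data.frame(cohort$truth$true_proportions),
       label_model = cohort$truth$label_model),
  file.path(out, "sim", "ground_truth.json"), auto_unbox = TRUE, digits = NA)

cat(sprintf("genome: %d CpGs on %d chromosomes, %d regulatory elements\n",
            length(genome$cpg_ids), length(genome$chrom_sizes),
            nrow(genome$re_intervals)))
cat(sprintf("atlas: %d classes x %d replicates\n",
            cfg$n_classes, cfg$n_replicates))
cat(sprintf("cohort: %d patients, recurrence rate %.2f\n",
            nrow(cohort$clinical), mean(cohort$clinical$recurrence)))
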