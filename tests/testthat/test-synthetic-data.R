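test_that("toy genome honours sizing, determinism and RE geometry", {
  cfg <- sim_config(n_cpgs = 1000, n_marker_cpgs_per_class = 20,
                    n_state_dmcs = 100, seed = 3L)
  g <- generate_toy_genome(cfg)
  expect_length(g$cpg_ids, 1000)
  expect_gte(nrow(g$re_intervals), 100)
  expect_false(any(duplicated(g$cpg_ids)))
  # positions strictly increasing within chromosome
  for (chr in names(g$chrom_sizes)) {
    p <- g$cpg_positions$pos[g$cpg_positions$chrom == chr]
    expect_true(all(diff(p) > 0))
    expect_true(all(p >= 0 & p < g$chrom_sizes[[chr]]))
  }
  expect_true(all(g$re_intervals$start < g$re_intervals$end))

  # determinism: same seed identical, different seed different
  expect_identical(g, generate_toy_genome(cfg))
  expect_false(identical(g$cpg_positions,
                         generate_toy_genome(cfg, seed = 4L)$cpg_positions))

  # infeasible sizing names the deficit
  bad <- sim_config(n_cpgs = 50, n_marker_cpgs_per_class = 20, n_state_dmcs = 0)
  expect_error(generate_toy_genome(bad), "deficit")

  # every state-DMC within 1,250 bp of an RE; most background CpGs beyond
  mapping <- map_cpgs_to_res(g$cpg_ids[g$state_idx], g, window_bp = 1250)
  expect_true(all(g$cpg_ids[g$state_idx] %in% mapping$cpg_id))
  bg <- g$cpg_ids[g$roles == "background"]
  bg_mapped <- unique(map_cpgs_to_res(bg, g, window_bp = 1250)$cpg_id)
  expect_gte(mean(!bg %in% bg_mapped), 0.5)
})

test_that("reference profiles carry the planted class and state effects", {
  w <- small_world()
  cfg <- w$cfg; atlas <- w$atlas; truth <- w$ref_truth
  cm <- atlas$class_means

  # planted markers: focal class differs from every other class by >= delta
  for (k in cfg$class_labels) {
    ids <- truth$planted_class_markers[[k]]
    expect_length(ids, cfg$n_marker_cpgs_per_class)
    gaps <- abs(cm[ids, k] - cm[ids, setdiff(cfg$class_labels, k)])
    expect_true(all(gaps >= cfg$delta_beta_marker - 1e-9))
  }

  # matched-type bookkeeping: four immune-type keys
  expect_named(truth$planted_state_dmcs, c("CD4T", "CD8T", "DC", "MacMono"))
  # state effect between matched classes at planted state-DMCs
  for (pair in matched_state_pairs()) {
    ids <- truth$planted_state_dmcs$DC
    gap <- abs(cm[ids, pair[1]] - cm[ids, pair[2]])
    expect_true(all(gap >= cfg$delta_beta_state - 1e-9))
  }
  # marker sets disjoint from state-DMC set
  state_ids <- truth$planted_state_dmcs$DC
  for (ids in truth$planted_class_markers) {
    expect_length(intersect(ids, state_ids), 0)
  }
  # replicate counts and count-data integrity
  expect_equal(table(atlas$class_labels)[[1]], cfg$n_replicates)
  expect_true(all(atlas$meth <= atlas$total))
})

test_that("bulk cohorts mix linearly with simplex ground truth", {
  w <- small_world()
  W <- w$bulk_truth$true_proportions
  expect_true(all(W >= 0))
  expect_true(all(abs(rowSums(W) - 1) < 1e-12))

  # noiseless limit: bulk betas equal S w exactly
  cfg0 <- small_cfg(seed = 21L, noise_sd = 0)
  g <- generate_toy_genome(cfg0)
  refs <- generate_reference_profiles(g, cfg0)
  b <- generate_bulk_cohort(refs$atlas, g, cfg0, 5)
  recon <- refs$atlas$class_means %*% t(b$truth$true_proportions)
  expect_lt(max(abs(b$bulk$betas - pmin(pmax(recon, 0), 1))), 1e-12)

  # determinism and degenerate-parameter guard
  b2 <- generate_bulk_cohort(refs$atlas, g, cfg0, 5)
  expect_identical(b$bulk$betas, b2$bulk$betas)
  expect_error(generate_bulk_cohort(refs$atlas, g,
    small_cfg(dirichlet_alpha = c(rep(1, 9), 0)), 5), "positive")
  expect_error(generate_bulk_cohort(refs$atlas, g, cfg0, 1), "n_samples")
})

test_that("recurrence labels follow the configured logistic model", {
  # null model: empirical rate matches logistic(intercept)
  cfg <- small_cfg(seed = 31L, label_coefficients = setNames(numeric(0), character(0)),
                   clinical_effects = c(tnm = 0, metastasis = 0, msi = 0),
                   label_intercept = -0.4)
  g <- generate_toy_genome(cfg)
  refs <- generate_reference_profiles(g, cfg)
  b <- generate_bulk_cohort(refs$atlas, g, cfg, 600)
  rate <- mean(b$clinical$recurrence)
  expect_lt(abs(rate - plogis(-0.4)), 3 * sqrt(0.25 / 600) + 0.02)

  # protective TIIC-DC + TIIC-CD8T fractions lower the recurrence frequency
  cfg2 <- small_cfg(seed = 32L,
                    label_coefficients = c("TIIC-DC" = -8, "TIIC-CD8T" = -8),
                    clinical_effects = c(tnm = 0, metastasis = 0, msi = 0))
  g2 <- generate_toy_genome(cfg2)
  refs2 <- generate_reference_profiles(g2, cfg2)
  b2 <- generate_bulk_cohort(refs2$atlas, g2, cfg2, 400)
  frac <- b2$truth$true_proportions[, "TIIC-DC"] +
    b2$truth$true_proportions[, "TIIC-CD8T"]
  hi <- b2$clinical$recurrence[frac > median(frac)]
  lo <- b2$clinical$recurrence[frac <= median(frac)]
  expect_lt(mean(hi), mean(lo))
})
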