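#' Generate sorted-cell reference profiles with planted signal
#'
#' Builds per-class mean beta profiles on the toy genome and draws
#' `n_replicates` noisy replicates per class (emulating sorted cells from
#' multiple donors), plus read counts at negative-binomial coverage.
#' Background CpGs follow a bimodal beta mixture (0.5*Beta(0.5,8) +
#' 0.5*Beta(8,0.5)), the marginal shape typical of bisulfite methylomes.
#' Planted class markers shift one class by `delta_beta_marker` away from
#' all others; planted state-DMCs implement a shared infiltration program:
#' all four TIIC classes shifted by `delta_beta_state` relative to their
#' PBMC counterparts, stromal classes midway. State-DMCs proximal to
#' dendritic-cell marker REs are always hypomethylated in TIICs; the rest
#' are hypomethylated with probability `state_hypo_fraction`.
#'
#' @param genome a [generate_toy_genome()] result
#' @param config a [sim_config()] object
#' @param seed integer seed (default `config$seed + 1`)
#' @return list with `atlas` (a `ReferenceAtlas`) and `truth` (planted
#'   marker/state-DMC bookkeeping)
#' @export
generate_reference_profiles <- function(genome, config,
                                        seed = config$seed + 1L) {
  set.seed(seed)
  n <- config$n_cpgs
  K <- config$n_classes
  labs <- config$class_labels
  dm <- config$delta_beta_marker
  ds <- config$delta_beta_state

  # baseline betas, bimodal
  hi <- rbinom(n, 1, 0.5) == 1
  base <- ifelse(hi, rbeta(n, 8, 0.5), rbeta(n, 0.5, 8))

  class_means <- matrix(rep(base, K), nrow = n, ncol = K,
                        dimnames = list(genome$cpg_ids, labs))

  # truncated draws from the bimodal methylome marginal: planted baselines
  # sit near 0 or 1 like real signature CpGs, leaving headroom for the shift
  rtrunc_beta <- function(n, a, b, lo, hi) {
    qbeta(runif(n, pbeta(lo, a, b), pbeta(hi, a, b)), a, b)
  }

  # class markers: headroom-aware direction, effect >= dm before clipping
  for (k in seq_len(K)) {
    idx <- which(genome$roles == labs[k])
    if (!length(idx)) next
    up <- runif(length(idx)) < 0.5
    b <- ifelse(up, rtrunc_beta(length(idx), 0.5, 8, 0.02, 0.95 - dm),
                rtrunc_beta(length(idx), 8, 0.5, 0.05 + dm, 0.98))
    class_means[idx, ] <- b          # all classes at baseline
    class_means[idx, k] <- b + ifelse(up, dm, -dm)
  }

  # shared state program: TIIC +- ds, stromal +- ds/2, PBMC at baseline
  st <- class_state(labs)
  sidx <- genome$state_idx
  if (length(sidx)) {
    hypo <- runif(length(sidx)) < config$state_hypo_fraction
    hypo[sidx %in% genome$dc_state_idx] <- TRUE
    b <- ifelse(hypo, rtrunc_beta(length(sidx), 8, 0.5, ds + 0.05, 0.98),
                rtrunc_beta(length(sidx), 0.5, 8, 0.02, 0.95 - ds))
    shift <- ifelse(hypo, -ds, ds)
    for (k in seq_len(K)) {
      mult <- switch(st[k], TIIC = 1, stromal = 0.5, PBMC = 0)
      class_means[sidx, k] <- b + mult * shift
    }
    state_direction <- setNames(ifelse(hypo, "hypo-in-TIIC", "hyper-in-TIIC"),
                                genome$cpg_ids[sidx])
  } else {
    state_direction <- character(0)
  }
  class_means <- clip01(class_means)

  # replicates: noisy betas and read counts
  R <- config$n_replicates
  sample_ids <- paste0(rep(labs, each = R), "_rep", rep(seq_len(R), K))
  sample_class <- rep(labs, each = R)
  betas <- matrix(0, n, K * R, dimnames = list(genome$cpg_ids, sample_ids))
  for (j in seq_len(K * R)) {
    betas[, j] <- clip01(class_means[, sample_class[j]] +
                           rnorm(n, 0, config$ref_replicate_sd))
  }
  total <- matrix(rnbinom(n * K * R, mu = config$coverage_mean,
                          size = 1 / config$coverage_dispersion),
                  n, K * R, dimnames = dimnames(betas))
  meth <- matrix(rbinom(n * K * R, as.vector(total), as.vector(betas)),
                 n, K * R, dimnames = dimnames(betas))

  atlas <- structure(list(
    cpg_ids = genome$cpg_ids,
    positions = genome$cpg_positions,
    betas = betas, meth = meth, total = total,
    sample_ids = sample_ids,
    class_labels = sample_class,
    state = class_state(sample_class),
    class_means = class_means
  ), class = "ReferenceAtlas")

  shared_state_ids <- genome$cpg_ids[sidx]
  truth <- list(
    planted_class_markers = lapply(setNames(labs, labs), function(l)
      genome$cpg_ids[genome$roles == l]),
    planted_state_dmcs = lapply(matched_state_pairs(), function(p) shared_state_ids),
    state_direction = state_direction,
    dc_marker_proximal = genome$cpg_ids[genome$dc_state_idx]
  )
  list(atlas = atlas, truth = truth)
}
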