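#' Generate a bulk tumor cohort with known mixing proportions
#'
#' Draws per-sample cell-state proportions from a Dirichlet, mixes the
#' reference class mean profiles linearly (bulk beta = sum_k w_k beta_k +
#' Gaussian noise, clipped to \[0,1\]), draws read counts (negative-binomial
#' coverage, binomial methylated counts), samples clinical covariates and
#' assigns a recurrence label from a logistic model on the true proportions
#' plus centred clinical effects.
#'
#' @param atlas a `ReferenceAtlas` from [generate_reference_profiles()]
#' @param genome the matching `ToyGenome`
#' @param config a [sim_config()] object
#' @param n_samples cohort size (>= 2)
#' @param seed integer seed (default `config$seed + 2`)
#' @return list with `bulk` (a `BulkMethylome`), `clinical` (data.frame) and
#'   `truth` (true proportion matrix, label model, per-sample recurrence
#'   probability)
#' @export
generate_bulk_cohort <- function(atlas, genome, config, n_samples,
                                 seed = config$seed + 2L) {
  if (n_samples < 2) stop("n_samples must be >= 2")
  if (any(config$dirichlet_alpha <= 0)) {
    stop("dirichlet_alpha must be strictly positive")
  }
  set.seed(seed)
  labs <- config$class_labels
  S <- atlas$class_means
  n <- nrow(S)

  W <- rdirichlet(n_samples, config$dirichlet_alpha)
  colnames(W) <- labs
  rownames(W) <- sprintf("sample%03d", seq_len(n_samples))

  clean <- S %*% t(W)                       # CpG x sample, exact mixing
  betas <- clip01(clean + matrix(rnorm(n * n_samples, 0, config$noise_sd),
                                 n, n_samples))
  dimnames(betas) <- list(atlas$cpg_ids, rownames(W))
  total <- matrix(rnbinom(n * n_samples, mu = config$coverage_mean,
                          size = 1 / config$coverage_dispersion),
                  n, n_samples, dimnames = dimnames(betas))
  meth <- matrix(rbinom(n * n_samples, as.vector(total), as.vector(betas)),
                 n, n_samples, dimnames = dimnames(betas))

  bulk <- structure(list(
    cpg_ids = atlas$cpg_ids,
    positions = atlas$positions,
    betas = betas, meth = meth, total = total,
    sample_ids = rownames(W)
  ), class = "BulkMethylome")

  # clinical covariates
  tnm <- sample(1:4, n_samples, replace = TRUE, prob = c(0.2, 0.3, 0.3, 0.2))
  metastasis <- rbinom(n_samples, 1, 0.3)
  msi <- rbinom(n_samples, 1, 0.15)
  side <- sample(c("left", "right"), n_samples, replace = TRUE)
  organ <- sample(c("colon", "rectum"), n_samples, replace = TRUE,
                  prob = c(0.7, 0.3))
  adjuvant <- rbinom(n_samples, 1, 0.5)

  coef <- setNames(numeric(length(labs)), labs)
  coef[names(config$label_coefficients)] <- config$label_coefficients
  ce <- config$clinical_effects
  lp <- config$label_intercept + drop(W %*% coef) +
    ce[["tnm"]] * (tnm - 2.5) +
    ce[["metastasis"]] * (metastasis - 0.3) +
    ce[["msi"]] * (msi - 0.15)
  p_rec <- plogis(lp)
  recurrence <- rbinom(n_samples, 1, p_rec)

  clinical <- data.frame(
    sample_id = rownames(W), recurrence = recurrence, tnm_stage = tnm,
    metastasis = metastasis, msi = msi, tumor_location_side = side,
    tumor_location_organ = organ, adjuvant_therapy = adjuvant,
    stringsAsFactors = FALSE
  )

  truth <- list(
    true_proportions = W,
    label_model = list(intercept = config$label_intercept,
                       coefficients = coef,
                       clinical_effects = ce),
    recurrence_prob = setNames(p_rec, rownames(W))
  )
  stopifnot(all(abs(rowSums(W) - 1) < 1e-12))
  list(bulk = bulk, clinical = clinical, truth = truth)
}
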