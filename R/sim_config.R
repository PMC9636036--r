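#' Default cell-state class labels
#'
#' Ten classes: two stromal (fibroblast, epithelial) plus four immune cell
#' types each observed in two states, tumor-infiltrating (TIIC-) and
#' peripheral-blood-like (PBMC-). Macrophages (tissue) pair with monocytes
#' (blood) as the myeloid type.
#'
#' @return character vector of length 10
#' @export
default_class_labels <- function() {
  c("fibroblast", "epithelial",
    "TIIC-CD4T", "TIIC-CD8T", "TIIC-DC", "TIIC-macrophage",
    "PBMC-CD4T", "PBMC-CD8T", "PBMC-DC", "PBMC-monocyte")
}

#' Compartment state of each cell-state class
#'
#' @param class_labels character vector of class names
#' @return factor-like character vector: "TIIC", "PBMC" or "stromal"
#' @export
class_state <- function(class_labels) {
  ifelse(startsWith(class_labels, "TIIC-"), "TIIC",
    ifelse(startsWith(class_labels, "PBMC-"), "PBMC", "stromal"))
}

#' Matched TIIC/PBMC pairs of the same immune cell type
#'
#' @return named list: immune type -> c(TIIC class, PBMC class)
#' @export
matched_state_pairs <- function() {
  list(
    CD4T = c("TIIC-CD4T", "PBMC-CD4T"),
    CD8T = c("TIIC-CD8T", "PBMC-CD8T"),
    DC = c("TIIC-DC", "PBMC-DC"),
    MacMono = c("TIIC-macrophage", "PBMC-monocyte")
  )
}

#' Dendritic-cell activation/maturation marker genes
#'
#' Seven canonical immunogenic DC markers; IL12 is represented by its two
#' subunit genes IL12A and IL12B.
#'
#' @return character vector of gene symbols
#' @export
dc_marker_genes <- function() {
  c("HLA-DRA", "CCR7", "CD40", "CCL22", "IFNG", "IL12A", "IL12B", "CD86")
}

#' Simulation configuration for the synthetic benchmark
#'
#' Defines the benchmark conditions emulated by the synthetic-data generator:
#' a ten-class cell-state design with planted class-specific marker CpGs and
#' a shared TIIC-vs-PBMC "infiltration program" of state-differential CpGs,
#' Dirichlet bulk mixtures under linear mixing, negative-binomial sequencing
#' coverage with binomial methylated counts, and recurrence labels driven by
#' a logistic model on selected cell-state fractions plus clinical covariates.
#'
#' @param n_classes number of cell-state classes
#' @param class_labels names of the classes (default [default_class_labels()])
#' @param n_cpgs total CpG sites in the toy genome
#' @param n_marker_cpgs_per_class planted class-specific marker CpGs per class
#' @param delta_beta_marker beta-scale effect of a class marker (0, 1]
#' @param n_state_dmcs planted CpGs differing between TIIC and PBMC states
#' @param delta_beta_state beta-scale effect of the state difference (0, 1]
#' @param n_replicates sorted-cell replicates (donors) per reference class
#' @param ref_replicate_sd within-class beta standard deviation across replicates
#' @param coverage_mean,coverage_dispersion negative-binomial coverage model;
#'   variance = mean + dispersion * mean^2
#' @param dirichlet_alpha concentration vector over classes for bulk mixing
#' @param label_coefficients named log-odds weights on true class fractions;
#'   classes not named get weight 0
#' @param label_intercept log-odds intercept of the recurrence model
#' @param clinical_effects named log-odds weights `c(tnm=, metastasis=, msi=)`
#'   applied to centred clinical covariates
#' @param noise_sd additive beta-scale noise on bulk profiles
#' @param state_hypo_fraction fraction of state-DMCs hypomethylated in TIIC
#'   (DC-marker-proximal sites are always hypomethylated in TIIC)
#' @param seed integer seed; all generator functions derive their randomness
#'   from it
#' @return object of class `sim_config` (a validated list)
#' @export
sim_config <- function(n_classes = 10,
                       class_labels = default_class_labels(),
                       n_cpgs = 3000,
                       n_marker_cpgs_per_class = 20,
                       delta_beta_marker = 0.4,
                       n_state_dmcs = 100,
                       delta_beta_state = 0.4,
                       n_replicates = 3,
                       ref_replicate_sd = 0.02,
                       coverage_mean = 30,
                       coverage_dispersion = 0.3,
                       dirichlet_alpha = rep(1, n_classes),
                       label_coefficients = c("TIIC-CD8T" = -12,
                                              "TIIC-DC" = -12,
                                              "PBMC-DC" = 12),
                       label_intercept = 0.8,
                       clinical_effects = c(tnm = 0.4, metastasis = 0.8,
                                            msi = -0.5),
                       noise_sd = 0.02,
                       state_hypo_fraction = 0.7,
                       seed = 1L) {
  stopifnot(n_classes >= 2, length(class_labels) == n_classes)
  if (delta_beta_marker < 0 || delta_beta_marker > 1 ||
      delta_beta_state < 0 || delta_beta_state > 1) {
    stop("effect sizes must lie in [0, 1]")
  }
  if (any(dirichlet_alpha <= 0)) stop("dirichlet_alpha must be strictly positive")
  if (length(dirichlet_alpha) != n_classes) {
    stop("dirichlet_alpha must have one entry per class")
  }
  unknown <- setdiff(names(label_coefficients), class_labels)
  if (length(unknown)) {
    stop("label_coefficients name unknown classes: ", paste(unknown, collapse = ", "))
  }
  cfg <- list(
    n_classes = n_classes, class_labels = class_labels, n_cpgs = n_cpgs,
    n_marker_cpgs_per_class = n_marker_cpgs_per_class,
    delta_beta_marker = delta_beta_marker, n_state_dmcs = n_state_dmcs,
    delta_beta_state = delta_beta_state, n_replicates = n_replicates,
    ref_replicate_sd = ref_replicate_sd, coverage_mean = coverage_mean,
    coverage_dispersion = coverage_dispersion,
    dirichlet_alpha = dirichlet_alpha,
    label_coefficients = label_coefficients,
    label_intercept = label_intercept, clinical_effects = clinical_effects,
    noise_sd = noise_sd, state_hypo_fraction = state_hypo_fraction,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}
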