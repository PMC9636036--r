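# methylstate

Dual-state immune-cell deconvolution of bulk tumor methylomes, and
machine-learning prediction of colorectal cancer recurrence from the
inferred cell-state composition.

## The problem

A bulk tumor methylome is a weighted average of the methylomes of the
cells in the tissue. Standard reference-based deconvolution estimates how
much of each immune cell *type* a tumor contains; this package implements
the stronger decomposition into cell *states*: each immune type —
CD4⁺ T cells, CD8⁺ T cells, dendritic cells (DC),
macrophages/monocytes — is represented twice in the reference, once as
sorted tumor-infiltrating cells (TIIC-) and once as peripheral-blood
mononuclear cells (PBMC-), alongside epithelial and fibroblast stromal
references. The working hypothesis is that the state split carries the
prognostic signal: a tumor whose DC compartment looks tumor-infiltrating
behaves differently from one whose DC content looks like circulating
blood, even at identical total DC abundance.

The model is linear mixing. For signature matrix $S$ (selected CpGs ×
cell-state classes, per-class median beta values) and bulk methylome
column $m$,

$$m = S\,w + \varepsilon,\qquad w \ge 0,\ \textstyle\sum_k w_k = 1,$$

and $w$ is estimated by ν-support-vector regression with a linear kernel
(ν ∈ {0.25, 0.5, 0.75}, best reconstruction RMSE wins, negative
coefficients truncated, renormalized to the simplex), with a
nonnegative-least-squares oracle as an independent check. Recurrence is
then predicted from selected components of $w$ (optionally plus TNM
stage, metastasis, MSI and tumor-location covariates) with extremely
randomized trees under 100-repeat 70/30 Monte Carlo cross-validation,
exhaustively over cell-state combinations; performance is the rank-based
AUC and Cohen's kappa, approaches are compared by Mann–Whitney tests,
and feature importance by response permutation (p-value floor
1/101 ≈ 9.9×10⁻³ at 100 permutations).

For interpretation, the package calls differentially methylated CpGs
(DMCs) between matched TIIC/PBMC states with a beta-binomial Wald test
(method-of-moments dispersion, locally shrunk, optional ±500 bp
smoothing), maps CpGs to regulatory elements within 1,250 bp, runs
hypergeometric gene-set enrichment with Benjamini–Hochberg correction,
and tests hypomethylation of regions regulating seven DC
activation markers (HLA-DRA, CCR7, CD40, CCL22, IFNG, IL12A/B, CD86).

Because sorted-cell reference methylomes and matched patient cohorts of
this kind are restricted clinical data, everything ships with a first-class synthetic-data generator
(toy genome, planted class markers and a shared TIIC/PBMC "infiltration
program", Dirichlet mixtures, negative-binomial coverage,
composition-driven recurrence labels) so that every stage is testable
against known ground truth. See `vignettes/methylstate-methods.Rmd` for
the full model description and design rationale.

## Worked example

```r
library(methylstate)

cfg    <- sim_config(seed = 42)                       # the benchmark conditions
genome <- generate_toy_genome(cfg)
refs   <- generate_reference_profiles(genome, cfg)
cohort <- generate_bulk_cohort(refs$atlas, genome, cfg, n_samples = 150)

uni <- intersect_universe(refs$atlas, cohort$bulk)
sig <- select_signature_cpgs(uni$atlas, "TIIC+PBMC")  # dual-state signature
pr  <- deconvolve_cohort(uni$bulk, sig)

# recovery of the known mixing proportions
W <- cohort$truth$true_proportions[, colnames(pr$proportions)]
round(range(sapply(colnames(W), function(k) cor(pr$proportions[, k], W[, k]))), 3)

# exhaustive 3-class combination search under Monte Carlo CV
splits <- monte_carlo_splits(150, cohort$clinical$recurrence,
                             n_repeats = 100, seed = 7)
combos <- Filter(function(x) length(x) == 3,
                 enumerate_combinations(pr$class_labels))
rep_ <- search_combinations(pr, cohort$clinical, combos, splits = splits,
                            n_trees = 50, seed = 7)
head(rep_$ranking, 3)
```

Output on this machine:

```
[1] 0.990 0.995
                        combination n_classes  mean_auc     sd_auc mean_kappa rank
1         PBMC-DC+TIIC-CD8T+TIIC-DC         3 0.7887605 0.05446277  0.3738271    1
2       PBMC-CD4T+TIIC-CD8T+TIIC-DC         3 0.7678151 0.06697507  0.3899727    2
3 PBMC-DC+TIIC-CD8T+TIIC-macrophage         3 0.7573739 0.06224387  0.3343813    3
```

The per-class correlations say the ν-SVR recovers every true cell-state
fraction almost perfectly at sequencing-level noise. In the ranking, the
`mean_auc` column is the Monte Carlo average AUC of each 3-class model;
combinations built from TIIC-CD8T, TIIC-DC and PBMC-DC — the classes
that drive the simulated recurrence labels — occupy the top rows, and
the dual-state signature is what makes them available at all: rerunning
with `mode = "TIIC"` caps the best mean AUC well below the dual-state
value (the `analysis/03_recurrence.R` driver prints the paired
rank-sum comparison).

The numbered drivers under `analysis/` run the same workflow as a
narrative: `01_simulate.R` (cohort generation), `02_signature_deconvolution.R`
(three reference modes, recovery), `03_recurrence.R` (combination search,
clinical integration, feature importance, cross-cohort transfer),
`04_dmc_functional.R` (DMC categories, enrichment, DC-marker
hypomethylation). Each writes its tables under `results/analysis/`.

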