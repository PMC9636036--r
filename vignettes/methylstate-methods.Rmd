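---
title: "Dual-state immune deconvolution and recurrence prediction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-state immune deconvolution and recurrence prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Bulk tumor methylomes are weighted mixtures of the methylomes of their
constituent cells. `methylstate` models a colorectal tumor as a mixture of
ten *cell-state classes*: two stromal classes (epithelial cells,
fibroblasts) and four immune cell types — CD4^+^ T cells, CD8^+^ T cells,
dendritic cells (DC), and macrophages/monocytes — each present in two
compartment states, tumor-infiltrating (TIIC-) and peripheral-blood-like
(PBMC-). The premise is that the *state* of an immune cell type, not just
its abundance, carries prognostic information: a tumor rich in TIIC-like
DCs and CD8^+^ T cells behaves differently from one whose DC content is
blood-like. The package provides the full chain needed to test this on
data with known ground truth:

1. a synthetic-data generator with planted methylation structure,
2. preprocessing of count-level bisulfite data to beta values,
3. signature CpG selection per reference mode,
4. ν-SVR deconvolution with a nonnegative-least-squares (NNLS) oracle,
5. Monte Carlo cross-validated recurrence prediction over all cell-state
   combinations,
6. beta-binomial differential methylation and regulatory-element (RE)
   enrichment for interpretation.

## The linear-mixing model and deconvolution

For sample $j$ with mixing weights $w \ge 0$, $\sum_k w_k = 1$, the bulk
beta value at CpG $i$ is
$m_{ij} = \sum_k S_{ik} w_{kj} + \varepsilon_{ij}$, where $S$ is the
*signature matrix* (CpG × class representative betas) and $\varepsilon$
collects read-sampling and biological noise. Estimation follows the
CIBERSORT recipe: the signature matrix is standardized by its *global*
mean and standard deviation and the mixture by its own mean/sd. Global
(rather than per-column) standardization matters: z-scoring each class
column separately would rescale classes unequally and destroy the convex
mixing relation, while a single affine transform is absorbed by the SVR
intercept. A raw-beta mode is available (`standardize = FALSE`) since the
exact convention of the original tool is not documented.

For each ν in {0.25, 0.5, 0.75} a linear-kernel ν-SVR (cost 1, `e1071`) is
fitted, negative coefficients are truncated to zero, and the grid point
whose unnormalized reconstruction $Sw$ has lowest RMSE against the
standardized mixture wins; the winner is renormalized to the simplex. An
all-nonpositive solution returns the uniform vector with a `degenerate`
flag so cohort runs always complete. `nnls_oracle()` solves the same
problem by constrained least squares (`pracma::lsqnonneg`) and serves as
an independent check: on noiseless mixtures the two agree to better than
0.02 per entry, and NNLS recovers planted weights to numerical precision.

On pure-column mixtures the SVR places ~2×10⁻⁴ of weight on correlated
columns (the ε-tube makes tiny spreads free); proportions are therefore
asserted to 10⁻³, not machine precision.

## Signature selection

`select_signature_cpgs()` runs a one-vs-rest Welch t test per class at
every CpG, BH-adjusts within class, and keeps CpGs with FDR ≤ 0.05 and
|Δβ| ≥ 0.2, ranked by |Δβ|, at most 200 per class; a CpG claimed by
several classes is attributed to the one with the largest effect, and the
matrix entry is the per-class median (mean by flag). All four thresholds
are arguments because the selection heuristic of the original
`FeatureSelect`-style tool is not published. Reference modes restrict the
samples: `TIIC` drops PBMC classes, `PBMC` drops TIIC classes, stromal
classes stay in every mode (their presence in all three output panels
implies they were always part of the reference).

## Recurrence prediction

Features are inferred proportions of a chosen class subset, optionally
plus clinical covariates (TNM stage encoded ordinal 1–4 for small-n
robustness — one-hot would quadruple the dimension; metastasis, MSI,
tumor side/organ, adjuvant therapy as 0/1). Splitting is 70/30 Monte
Carlo cross-validation, 100 repeats, *stratified* by the recurrence label
(plain random splits on n≈114–150 with ~40% positives regularly produce
one-class test sets); an unstratified mode exists. All combinations are
scored on the *same* split list, so mode and combination comparisons are
paired by construction. AUC uses the rank (Mann–Whitney) formulation with
midrank ties; Cohen's kappa thresholds the class-1 probability at 0.5.

The default classifier is an extremely randomized trees ensemble
implemented in C++ inside the package: one uniformly drawn cut point per
candidate feature per node, best Gini gain wins, no bootstrap, leaves
store class fractions. The exhaustive search (1023 combinations × 100
splits × several generator seeds ≈ 10⁵–10⁶ fits) needs per-fit latency
well under what general-purpose forest packages can offer through their R
interfaces at n ≈ 100; a test verifies that its mean AUC matches ranger's
`extratrees` splitrule on shared splits. `random_forest` (ranger) and
`gradient_boosting` (xgboost) are available as alternative model kinds.
Ensembles default to 50 trees in the search and 100 elsewhere: at n ≤ 150
and p ≤ 14, AUC differences versus much larger ensembles are far below
split-to-split noise, and tree count is an argument everywhere.

Permutation feature importance refits the ensemble on `n_perms = 100`
response permutations with `mtry = 10`; the per-feature p-value
$(1 + \#\{\text{null} \ge \text{obs}\})/(1 + n_{perms})$ has floor
1/101 ≈ 9.9×10⁻³, which a feature dominating every null draw attains
exactly.

## Differential methylation and functional interpretation

`call_dmcs()` compares two classes from read counts under a beta-binomial
model: pooled per-group proportions (optionally coverage-weighted window
smoothing, ±500 bp), method-of-moments dispersion per group shrunk 50%
toward the local (±500 bp) mean, a Wald-type statistic whose standard
error is evaluated at the pooled null proportion (with a 0.5/1 continuity
guard), and a normal reference. This is a deliberate desk-scale
approximation of shrinkage-based beta-binomial testers; its contract is
calibration (empirical type-I ≤ 2× nominal at p = 0.01 on nulls) and
power (≥ 95% at Δ = 0.3, coverage 100, 4v4, p < 0.001), not p-value
identity with any specific tool.

CpGs map to REs when the base-gap is ≤ 1,250 bp, inclusive at the
boundary, on 0-based half-open BED coordinates; the same 1,250 bp window
is used everywhere a CpG-to-RE proximity is needed. Enrichment is an upper-tail hypergeometric test per
gene set with BH correction; the background is the set of genes reachable
from *all* panel CpGs, genes deduplicated before testing. The
DC-activation marker test collects DMCs within the window of REs
targeting each of HLA-DRA, CCR7, CD40, CCL22, IFNG, IL12 (expanded to
IL12A/IL12B) and CD86, and runs a paired two-sided t test of the
per-CpG group means; markers with fewer than three proximal DMCs are
reported untestable rather than failing the run.

## The synthetic generator: what it emulates and what it does not

The generator is first-class, tested code; every downstream claim in the
test suite is made against its ground truth.

* **Genome.** CpGs at ~3 kb spacing on two chromosomes (so 1,250 bp RE
  windows of neighbouring CpGs never collide), one RE planted within
  1,250 bp of every state-DMC, decoy REs near 25% of background CpGs, and
  ≥50% of background CpGs farther than 1,250 bp from any RE so enrichment
  against the plant is testable. State-DMC REs target either DC
  activation markers (~40%) or "migration-program" genes; decoys target
  housekeeping genes. Gene sets group these families.
* **References.** Background betas follow the bimodal mixture
  0.5·Beta(0.5, 8) + 0.5·Beta(8, 0.5), the marginal shape of real
  methylomes. Three replicates per class (per-class donor counts are not
  public knowledge; three is the minimum that leaves a variance estimate)
  with within-class sd 0.02. Class markers shift one class by Δβ = 0.4
  away from all others; planted-site baselines are drawn from the same
  bimodal Beta tails as the background (truncated to leave headroom for
  the shift), because real signature CpGs are near-fully (un)methylated
  in the off-target classes — and read-sampling noise is smallest exactly
  there, which matters for recovery at realistic coverage.
* **The state program is shared.** All four TIIC classes shift together
  at the planted state-DMCs (stromal classes midway, PBMC classes at
  baseline), emulating a common infiltration program. Per-type private
  state-DMCs would be selected by the *single-state* modes' one-vs-rest
  contrast — contradicting the very phenomenon under study — and a fully
  private program would also make the ten columns nearly collinear.
  Sharing keeps the signature identifiable (types are separated by their
  markers, states by the program) while reproducing the qualitative
  contrast: the dual-state signature absorbs essentially all planted
  state-DMCs, single-state signatures almost none. Most state-DMCs
  (70%, and all DC-marker-proximal ones) are hypomethylated on the TIIC
  side, mirroring activation-associated methylation loss.
* **Bulk cohorts.** Weights are symmetric Dirichlet(1) — the uniform
  simplex, the standard deconvolution benchmark prior; coverage is
  negative binomial (mean 30, dispersion 0.3, so the depth<10 filter
  removes a testable fraction); methylated counts are binomial.
* **Labels.** Recurrence is Bernoulli with log-odds
  $0.8 - 12\,w_{\text{TIIC-CD8T}} - 12\,w_{\text{TIIC-DC}} +
  12\,w_{\text{PBMC-DC}}$ plus centred clinical effects (TNM +0.4/stage,
  metastasis +0.8, MSI −0.5), giving ≈40% recurrence. The weights form an
  equal-magnitude *state contrast*: protective tumor-infiltrating DC and
  CD8^+^ content versus deleterious blood-like DC content. This is the
  mechanism the benchmark is about — a label the dual-state deconvolution
  can see and a single-state deconvolution largely cannot; an earlier
  draft with a weaker positive term let the single-state mode keep up,
  so the contrast was made symmetric and frozen.

Not emulated: sequence-level reads, tumor purity/copy-number effects
beyond the stromal classes, correlated CpG blocks beyond the planted
structure, batch effects, missing-not-at-random coverage, and any
cohort-level quantity of real patients. Passing tests therefore
demonstrate correctness of the machinery and qualitative reproduction of
the modeled mechanisms, not clinical performance numbers.

## Numerical choices and degenerate inputs

* Depth filter keeps sites with total ≥ 10 (boundary retained); CpGs
  missing in >20% of either side's samples are dropped at universe
  intersection, the remainder mean-imputed. Filtering precedes smoothing.
* Welch t uses a 10⁻²⁴ variance floor; zero-variance signature columns
  are an error naming the class.
* The beta-binomial dispersion is clamped to [0, 0.9]; zero-coverage
  groups skip the site (counted, never silently dropped).
* Ranking ties break by fewer features, then lexicographically.
* Rank-sum comparisons use exact p for small tie-free samples, the
  tie-corrected normal approximation otherwise; fully tied inputs return
  p = 1.
* All generators and every stochastic stage take explicit integer seeds;
  reruns are byte-identical.
* Permutation nulls re-permute the labels for every Monte Carlo repeat.
  Permuting once and then split-resampling is *not* a calibrated null: in
  a finite cohort the test-set feature–label correlation is the negative
  complement of the training set's, so models that overfit training noise
  score systematically below AUC 0.5 on the held-out part.

## Benchmark problem sizes

The shipped tests and the acceptance script use: 3,000-CpG genomes, ten
classes × 3 replicates, 150-patient cohorts, 100 Monte Carlo repeats (50
for the full 1023-combination sweep), 10 generator seeds for the
two-state-advantage check and 5 for the planted-combination ranking
(scripts use 4 and 3), 10,000 null CpGs for test calibration. These sizes
put every property comfortably in its asymptotic regime while keeping a
full run on one CPU in minutes; all are arguments, none is hard-coded.

## Known limitations

* The ν-SVR solution depends mildly on the standardization convention;
  both conventions are exposed but only the standardized one is tuned.
* The DMC test's normal reference is anti-conservative for extremely low
  coverage (<5 reads/group); such sites are rare under the default
  coverage model but are not specially handled.
* The GO route tests planted gene sets only; no ontology topology,
  CpG-density bias correction, or real GO content ships with the package.
* `enumerate_combinations()` refuses more than 16 classes; the search is
  exponential by design.
* The exhaustive ranking identifies the signal-carrying classes robustly,
  but the *exact minimal* subset does not reliably out-rank its supersets:
  at n ≈ 150, cohort-level spurious feature–label correlations (~n^(-1/2))
  let some of the 127 supersets of a 3-class signal genuinely edge out the
  minimal set within a given cohort, a winner's curse that neither more
  trees nor more Monte Carlo repeats removes. Interpreting a top-10 table
  should therefore focus on which classes recur across its rows, not on
  the single best subset.
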