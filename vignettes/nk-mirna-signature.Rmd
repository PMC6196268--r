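---
title: "Discriminating NK cell subsets by a miRNA signature: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminating NK cell subsets by a miRNA signature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Human natural killer (NK) cells circulate as two major subsets,
CD56^bright^/CD16^−^ (regulatory, less mature) and CD56^dim^/CD16^+^
(cytotoxic, mature), with CD56^bright^/CD16^dim^ cells as a transitional
stage. `nkmir` implements a complete miRNA-profiling workflow for asking
whether a compact set of miRNAs separates the two subsets: microarray
preprocessing, univariate differential expression, a sparse multivariate
classifier with stability selection, Monte-Carlo validation with a
permutation null, ΔΔCt integration of qPCR measurements, and
over-representation analysis of predicted target genes. A synthetic-data
generator reproduces the statistical structure of such a study (paired
donors, two array batches, a detection floor) so that every stage is
testable offline, against known ground truth.

```{r, eval = FALSE}
library(nkmir)
sim  <- generate_microarray(seed = 1)       # paired 10 + 10, 2000 features
norm <- preprocess_chain(sim$matrix, sim$metadata)
de   <- differential_expression(norm, sim$metadata)
sel  <- nested_cv_select(norm, sim$metadata, seed = 2)
val  <- validate_signature(subset_matrix(norm, sel$signature),
                           sim$metadata, seed = 3)
```

## Preprocessing chain

Raw intensities are in arbitrary scanner light units (LU). The chain is
floor → log2 → quantile normalization → batch adjustment → (optional)
median centering, applied in that order:

* **Detection floor** (`floor_threshold()`, default 1 LU): intensities
  below the floor are noise-dominated and replaced by the floor, which
  also guarantees positivity for the log transform.
* **Quantile normalization** (`quantile_normalize()`, via
  `limma::normalizeQuantiles(ties = TRUE)`): every sample is forced onto
  the mean-of-order-statistics reference distribution; ties receive the
  mean of the reference over the tied rank span. A single-sample matrix
  is a warned no-op.
* **Batch adjustment** (`batch_adjust()`): the study design has two
  separately hybridized array batches. We use the simplest adjustment
  consistent with that design — per feature, each batch is shifted so its
  mean equals the feature's grand mean. This removes an additive batch
  offset exactly, preserves within-batch group contrasts exactly, and is
  idempotent. Empirical-Bayes shrinkage (ComBat-style) is deliberately
  not used: with 10 samples per batch and a location-only artifact it
  adds estimation variance without addressing a demonstrated scale
  effect. A batch containing only one phenotype group is refused, since
  the shift would then absorb the group difference (confounded design).
* **Median centering** (`median_center()`): per-feature median
  subtraction, used for heat-map display and bi-clustering, not for
  testing.

Detection calls (`detection_call()`) label a feature detected when it
exceeds θ = 1 LU on the normalized log2 table; "half or more" of a group
means `ceiling(f * n)` samples (exactly ≥ 5 of 10 at the defaults). The
threshold is interpreted on the scale of the matrix it is given, so
linear-scale thresholding is available by passing a linear matrix.

## Univariate signature

Per feature, a two-sample test on log2 intensities (Welch *t* by
default; Mann–Whitney with mid-ranks and exact small-sample enumeration
by flag), Benjamini–Hochberg adjustment by default (Bonferroni by flag),
and the signature rule: *induced* in the dim subset when
p~adj~ ≤ 0.05 and the difference of group medians is ≥ 1 log2 unit
(two-fold), *repressed* when ≤ −1, *unchanged* otherwise. Fold change is
reported as the signed linear fold `sign(Δ)·2^|Δ|`. Features not
detected in at least half the samples of either group are excluded
before testing, and before the multiplicity adjustment. The per-feature
test is not dictated by the upstream analysis software conventions, so
Welch was chosen as the standard microarray default; the donor pairing
is recorded in metadata but the signature criteria are unpaired, so
paired tests are out of scope.

Bi-clustering (`hierarchical_bicluster()`) runs agglomerative clustering
on features and samples independently; the default distance is
1 − Pearson correlation with average linkage (the defaults of the usual
web heat-map tools), with Euclidean/complete available. Items are
pre-sorted lexicographically so ties resolve deterministically, and a
constant matrix under correlation distance is an error that advises the
Euclidean alternative.

## The sparse classifier

The multivariate engine is a linear model fit by minimizing

$$ \frac{1}{n}\lVert y - X\beta - b\rVert_2^2
   + \tau\lVert\beta\rVert_1 + \mu\lVert\beta\rVert_2^2 $$

on labels coded −1 (bright) / +1 (dim), with features z-scored using
training data only and an unpenalized intercept. Square loss is used
throughout (regularized least squares when τ = 0), which keeps the
validation stage's closed-form ridge and the selection stage's penalized
fits in the same family. The ℓ1 weight τ produces exact zeros
(selection); the ℓ2 weight μ stabilizes the fit and lets correlated
discriminative features enter together instead of one arbitrary
representative — the property that makes frequency aggregation
meaningful.

The solver is accelerated proximal gradient (FISTA) with a
soft-threshold proximal step, an exactly computed Lipschitz constant
(spectral norm of the training design; backtracking is unnecessary at
these problem sizes), and a monotone restart, so the objective never
increases. Convergence is declared at a relative objective change below
`tol` (default 1e-6, cap 10⁴ iterations; non-convergence warns and
flags the returned iterate). Prediction is `sign(βᵀx̃ + b)` with the
documented tie rule sign(0) → +1 (dim). Models serialize to JSON.

## Stability selection

`nested_cv_select()` wraps the classifier in two nested loops:

* **Outer loop**: B = 5 stratified Monte-Carlo learning/test splits with
  a 25% test fraction (per-group test count `max(1, round(0.25 n_g))`,
  i.e. 2 + 2 at the study size). Monte-Carlo splits rather than a fixed
  fold partition keep both classes in every test set at these sample
  sizes. A `pair_by_donor` flag keeps each donor's two samples on the
  same side of a split (off by default, since the selection criteria are
  unpaired).
* **Inner loop**: 4-fold stratified CV on each learning set over a grid
  of (τ, μ): 20 geometric τ values from the learning-set critical value
  τ~max~ (empty model) down to τ~max~/100, warm-started, and
  μ ∈ {10⁻³, 10⁻², 10⁻¹} × the spectral scale of the standardized
  learning Gram matrix. The pair minimizing mean inner misclassification
  error wins; **error ties break toward the smallest τ** — the densest,
  correlation-retaining model, matching the argmin-over-ascending-grid
  convention of the established ℓ1ℓ2 selection frameworks — then toward
  the sparser fit, then the smaller μ. Breaking ties toward sparsity
  instead would collapse the signature to the one or two strongest
  features whenever the signal is clean, defeating the purpose of
  stability aggregation over correlated discriminative sets.

The winning pair is refit on the full learning set; its nonzero-weight
features form that split's list and its held-out error is recorded.
Features are ranked by the fraction of the B lists containing them, and
`aggregate_by_frequency()` keeps those at frequency ≥ φ = 0.5 (the
full count-vs-frequency table is retained as the slope diagnostic;
automatic knee detection is not attempted). Identical seeds give
identical splits, lists and signature. Standardization and model choice
use learning data only; a leakage canary test verifies that a feature
encoding held-out labels is not reliably selected.

## Validation

`montecarlo_cv_accuracy()` repeats R stratified random splits, fitting
closed-form ridge (`rls()`) on each learning set. `validate_signature()`
compares the accuracy distribution under the true labels with a
permutation null and summarizes the separation with a two-sided
two-sample Kolmogorov–Smirnov test (exact p when both samples are small
and tie-free, asymptotic otherwise). Defaults: 100 + 100 repetitions,
25% test fraction, μ = 0.1.

Two numerical subtleties are worth recording:

* **The permutation null re-permutes labels at every split.** A single
  permutation shared by all of an arm's splits makes the arm's
  accuracies mutually dependent, and two such arms differ systematically
  — the KS null check then rejects far above its nominal level. Fresh
  permutations per split restore exchangeability and put chance
  performance exactly at 0.5.
* **Fixed null labels show anti-learning.** When labels are fixed but
  independent of the features, cross-validated accuracy sits *below*
  0.5 (≈ 0.4 at n = 20): held-out class means anti-correlate with the
  learning-set noise the model fits. This is a property of
  cross-validation at small n, not a defect; the package's chance
  reference is therefore the per-split permutation arm.
* **KS p-values on accuracy distributions are conservative.** Accuracies
  live on a discrete grid (multiples of 1/4 at the default test size),
  and the asymptotic two-sample p-value under heavy ties over-covers:
  under the null the observed fraction of p ≤ 0.05 is ≈ 0.02–0.03.
  Reported significance is therefore, if anything, understated.

`cross_technology_predict()` applies a microarray-trained model to a
qPCR cohort: Ct tables are converted to −ΔCt per feature (reference-gene
normalized, log2-like), then each feature is z-scored *within the new
cohort* before the sign rule. This removes platform location and scale
without paired calibration samples; it assumes the new cohort is not
strongly class-imbalanced, since the within-cohort mean then encodes
class composition. Zero-variance features in the new cohort are dropped
with a warning and the rule renormalized over the rest.

## qPCR and reporter arithmetic

`delta_delta_ct()` implements relative quantification: replicate Ct
values are averaged on the Ct scale (triplicates in the emulated
design), ΔCt = target − reference (RNU6B for miRNA, GAPDH for mRNA)
within sample, ΔΔCt against a calibrator sample (RQ exactly 1) or the
unweighted mean ΔCt of a calibrator group, RQ = 2^−ΔΔCt^.
Amplification-efficiency correction is out of scope. For dual-reporter
assays, `reporter_relative_activity()` divides per-well firefly/Renilla
ratios by the control-group mean ratio; note that a global gain applied
to all wells cancels through that normalization (the control mean is 1
by construction).

## Enrichment

`hypergeometric_enrichment()` tests over-representation of a signature's
target genes in gene sets (GMT input) against a user-supplied reference
universe: upper-tail hypergeometric P[X ≥ k], Bonferroni correction over
the m sets that reached the minimum overlap of 3 genes (smaller
overlaps are excluded from the results *and* from m), significance at
p~adj~ ≤ 0.05, enrichment ratio (k/n)/(K/N) and score −log10 p~adj~.
The miRNA→gene step goes through `aggregate_targets()`, which pools
externally produced prediction tables and counts supporting tools per
pair; live queries to prediction services are out of scope, as is any
bundled genome reference.

## The synthetic generator

`generate_microarray()` encodes the emulated study design, and its
defaults are the conditions under which the package's recovery claims
are made: 10 paired donors × 2 subsets, 2000 features with log-normal
intensities (baselines uniform on [−2, 8] log2 LU, so a realistic
fraction sits below the 1 LU floor), 15 + 15 features shifted ±1.5 log2
in the dim group (≥ two-fold median differences), 2 features exclusive
to each subset (silent group placed well below the floor), σ = 0.3
measurement noise on the log2 scale, donors split half-and-half across
two batches offset by 0.5 log2, optional Gaussian donor intercepts
(default 0). Planted features are drawn from baselines in [3, 6.5] so
that detection, not luck, decides the filter. Effects are additive on
the log2 scale with homoscedastic Gaussian noise — deliberately simpler
than real arrays (no probe-level artifacts, heavy tails,
intensity-dependent variance or correlated feature blocks), so passing
tests demonstrate the machinery, not robustness to every real-data
pathology. Quantile normalization compresses the planted 1.5 log2 shift
to ≈ 1.4–1.45 observed, which the recovery margins accommodate.

`generate_intermediate_group()` appends a third subset whose
planted-feature means are the convex combination of the parents
(halfway at mixing 0.5), exercising the three-group ANOVA trend test;
`generate_qpcr()` emits triplicate Ct tables whose dim-group Ct is
lowered by the planted log2 difference, with a flat RNU6B reference.

## Problem sizes in the test suite

The shipped tests run the full study scale where the claim depends on
it (20 samples × 2000 features for univariate sensitivity, selection
recall and outer-CV accuracy; 100 + 100 Monte-Carlo repetitions for
validation; 200 repetitions for the null calibration of the KS check)
and desk-scale fixtures (≤ 25-element universes, 4–6 sample designs)
for the exact oracles: ridge closed form, coordinate-descent objective,
combinatorial hypergeometric tails, CDF-enumerated KS statistics, and
hand ΔΔCt arithmetic.

## Known limitations

* The batch model is location-only; multiplicative batch effects are
  out of scope.
* Square loss treats the ±1 labels as regression targets; logistic or
  hinge losses are not provided.
* The GEO series-matrix reader extracts groups and batches best-effort
  from characteristics lines; an explicit metadata table always wins.
* Enrichment results depend entirely on the supplied prediction tables
  and reference universe; counts obtained with live databases shift with
  database versions and are not reproducible offline.
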