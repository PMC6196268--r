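# nkmir

Human natural killer (NK) cells split into two major blood subsets —
regulatory CD56^bright/CD16− cells and cytotoxic CD56^dim/CD16+ cells —
connected by a CD56^bright/CD16^dim transitional stage. `nkmir` is an R
package for discovering and validating miRNA expression signatures that
discriminate such phenotype groups from microarray profiles, built for
transcriptomics analysts who want the whole chain — preprocessing,
univariate statistics, penalized multivariate selection, resampling
validation, qPCR integration and gene-set enrichment — as tested,
seed-reproducible functions rather than a sequence of web tools.

## What it computes

**Preprocessing.** Detection floor at 1 light unit, log2 transform,
quantile normalization, additive two-batch adjustment, optional median
centering; detection calls per group at a threshold θ ("detected in at
least half / in all samples", with shared and subset-exclusive sets).

**Univariate signature.** Per-miRNA Welch *t* (or Mann–Whitney) on log2
intensities with BH (or Bonferroni) adjustment; a miRNA is *induced* in
the dim subset when p_adj ≤ 0.05 and the group-median difference Δ ≥ 1
log2 (two-fold), *repressed* when Δ ≤ −1. Two-way hierarchical
bi-clustering for the heat-map view.

**Multivariate signature.** A sparse linear classifier fit by

```
min_β  (1/n) ‖y − Xβ − b‖²  +  τ‖β‖₁  +  μ‖β‖₂²
```

(labels y ∈ {−1, +1}, features z-scored on training data, FISTA solver
with exact soft-threshold sparsity; `sign(βᵀx + b)` classifies). Nested
cross-validation — B = 5 stratified outer splits, 4-fold inner model
selection over a (τ, μ) grid — yields B selected-feature lists; features
appearing in at least 50% of the lists form the stable aggregated
signature.

**Validation.** Monte-Carlo cross-validated accuracy of a
regularized-least-squares classifier on a reduced signature, compared
against a per-split permutation null via the two-sample
Kolmogorov–Smirnov test; cross-technology prediction of qPCR cohorts
(−ΔCt, per-feature z-scoring within the cohort, sign rule).

**Assay statistics.** ΔΔCt relative quantification (triplicate means,
reference gene, sample or group calibrator, RQ = 2^−ΔΔCt), dual-reporter
firefly/Renilla ratios normalized to controls, Welch/Mann–Whitney tests
and one-way ANOVA with Bonferroni post-tests.

**Enrichment.** Hypergeometric over-representation of the signature's
predicted target genes in GMT gene sets against a user-supplied
reference universe (minimum overlap 3, Bonferroni over the tested sets),
plus pooling of external miRNA→target prediction tables with
per-pair tool support counts.

**Synthetic data.** `generate_microarray()` emulates the study design —
10 paired donors × 2 subsets, 2000 features, two array batches, a 1 LU
detection floor, 30 planted ≥two-fold effects, subset-exclusive miRNAs,
an optional halfway intermediate group, and matched triplicate qPCR
tables — with full ground truth, so every stage is testable offline.

## Worked example

```r
library(nkmir)
sim  <- generate_microarray(seed = 1)          # linear-scale intensities
norm <- preprocess_chain(sim$matrix, sim$metadata)
det  <- detection_call(norm, sim$metadata)
de   <- differential_expression(norm, sim$metadata)
sel  <- nested_cv_select(norm, sim$metadata, seed = 2)
val  <- validate_signature(subset_matrix(norm, sel$signature),
                           sim$metadata, seed = 3)
```

The run prints:

```
Detection at theta = 1 (>= 50% of group samples):
  bright: 1434 detected (>= fraction), 1353 in all samples
  dim: 1441 detected (>= fraction), 1350 in all samples
  shared: 1424; exclusive: bright=10, dim=17

table(de$status):
  induced repressed unchanged
       17        17      1417

Nested-CV selection: B = 5 splits, test fraction 0.25, phi = 0.50
  mean test accuracy: 1.000
  aggregated signature: 58 features
  per-split list sizes: 72, 72, 76, 95, 90

Monte-Carlo CV validation (100 true / 100 permuted splits)
  mean accuracy (true labels): 1.000
  mean accuracy (permuted):    0.472
  KS D = 0.970, p = 0
```

Reading the numbers: about 1430 of 2000 simulated miRNAs are expressed
above the 1 LU floor in each subset, a handful exclusively in one subset
(the planted exclusive miRNAs are among them). The univariate stage
calls 34 miRNAs (17 up, 17 down in the dim subset: the 30 planted
two-fold effects plus the 4 exclusive features). The nested-CV selection
classifies every held-out sample correctly and aggregates a 58-miRNA
stable signature containing all 30 planted effects; restricted to that
signature, the ridge classifier scores 100% Monte-Carlo CV accuracy
versus 47% under the permutation null, a separation the KS test calls
essentially certain (D = 0.97).

`run_pipeline()` chains all stages from one config object and writes the
tables, JSON reports and a run log (seeds, versions, sizes) to a
directory; `read_series_matrix()`, `read_expression_tsv()`, `read_gmt()`
and `read_target_table()` bring in real data.

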