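---
title: "Building prognostic risk groups from thresholded copy number alterations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building prognostic risk groups from thresholded copy number alterations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnarisk)
```

## The modeling problem

GISTIC 2 "all_thresholded_by_genes" matrices give, per gene region and
tumor sample, an integer call *C* ∈ {−2, −1, 0, +1, +2}. The question this
package addresses is whether, and how, those calls stratify patients into
groups with different survival. Two properties of the data shape every
design choice:

* **Sparsity.** A recurrent alteration is typically carried by a few
  percent of a cohort. Two-group survival tests between a handful of
  carriers and hundreds of non-carriers violate the sample-size assumptions
  behind the asymptotic log-rank reference.
* **Discreteness.** The calls are levels, not doses. Rather than fitting a
  linear term in *C*, the pipeline binarizes each gene four ways — soft
  deletions (C ≤ −1), deep deletions (C = −2), soft amplifications
  (C ≥ +1), deep amplifications (C = +2) — and lets the data say which
  depth is informative for a given cohort.

## Screening

Each recurrent gene region (≥ 4 carriers in the tested mode, the
`min_recurrence` knob) is screened by the two-group log-rank statistic with
the carrier indicator as the grouping. Three p-value engines are available:

* `permutation` (default): the conditional permutation null. The observed
  1-df chi-square is compared with its distribution under reassignment of
  the k carrier labels among the n samples, conditioning on k. When
  C(n, k) ≤ `exhaustive_threshold` every carrier subset is enumerated and
  the p-value is exact; otherwise `n_perm` Monte Carlo draws are used with
  the add-one correction p = (1 + #{stat ≥ obs}) / (1 + n_perm), which
  guarantees p > 0 and near-nominal type-I error. The permutation null is
  exact under exchangeability regardless of how unbalanced the groups are,
  which is precisely the sparse-carrier regime where the χ² reference
  fails.
* `asymptotic`: the χ²(1) reference, appropriate for balanced groups and
  useful for fast exploratory passes.
* `cox`: the likelihood-ratio test from the univariate Cox fit.

The univariate Cox fit on the carrier indicator is computed for every gene
regardless of engine, because its coefficient β (log hazard ratio, Efron
tie handling by default) defines both the risk direction and the weights of
the coefficient sums below. Monotone-likelihood fits — all carrier events
preceding all non-carrier events, say — have no interior maximum; they are
flagged and |β| is clamped at `beta_ceiling` (default 10) so downstream
sums stay finite. Screening retains genes at raw p ≤ 0.05 without
multiple-testing correction: that is a deliberate property of the protocol
this package implements (screening feeds a grouped model rather than a
discovery list); a Benjamini–Hochberg `fdr` column is provided for users
who want to filter harder.

Two open choices were resolved as follows. The permutation p-value is
two-sided (the chi-square statistic is direction-free) and the direction is
recovered from the sign of β, which provably agrees with the sign of the
log-rank observed-minus-expected score for the carrier group. And β comes
from the univariate Cox fit on the indicator, the natural companion to a
two-group log-rank screen.

## Risk assignment

For each sample, the screened coefficients of the genes it carries are
summed per direction: Σβ over high-risk genes (β > 0) and Σ|β| over
low-risk genes (β < 0). The absolute value on the low-risk side makes the
two sums directly comparable magnitudes; summing signed negative
coefficients would make any low-risk burden lose every comparison by
construction. Three algorithms convert sums into labels:

* **single-data** — H if Σβ_high > Σβ_low, L if lower, NA on ties
  (including the no-alteration case 0 vs 0). One model per mode: 4 models.
* **MaxSum** — the amplification and deletion sums of the same depth are
  pooled per direction before the comparison: 2 models (soft, deep).
* **Combinations** — the single-data amplification label crossed with the
  deletion label of the same depth, up to 9 groups: 2 models.

Exactly eight models per cohort, always. Ties between floating-point sums
are declared with relative tolerance 1e−9; exact equality of doubles built
from different summation orders is too fragile a tie definition. The NA
label is a literal group label (the *no-risk* group), never a missing
value, and serves as the reference stratum in all Cox fits.

## Evaluation, ranking, selection

Each model is scored by the k-group log-rank test over its occupied groups
(the 2-group case coincides with the screening statistic to numerical
precision, which the test suite asserts at 1e−9). Ranking is by p-value
ascending, but a model is demoted below all others unless its groups are
*distinguishable*: every occupied group holds ≥ `min_group_frac` (default
2%) of the cohort, and the two extreme groups separate at pairwise p ≤
0.05. "Extreme" is operationalized deterministically as the two occupied
groups with the lowest and highest crude hazard (events per unit follow-up
time). Remaining ties break by fewer groups (simpler models first), then by
a fixed model-id order. This operationalization favors MaxSum over
Combinations when both separate equally well — Combinations tends to shave
off small, uninterpretable groups — while still letting Combinations win
when its extra resolution is real.

Cofactor independence is assessed two ways: per-stratum Cox fits of the
risk label within levels of one cofactor (with level-merging maps such as
T3/T4 pooling, and numeric cofactors dichotomized at `age_cut`, default
60), and a joint multivariate Cox fit of label plus all cofactors on
complete cases, with constant or collinear cofactors dropped by a QR rank
check before fitting. Strata with no events in a risk group are reported
as non-estimable rather than with a meaningless diverging coefficient.
Neither analysis modifies the assignments it consumes.

## The synthetic-cohort generator

`simulate_cohort()` emulates the statistical structure the analysis
assumes, not the biology that produces it: sparse binary carrier indicators
driving a proportional-hazards model. Per gene the generator draws a
carrier fraction from Beta(2, 40) (mean ≈ 4.8%, mass concentrated at
2–10%, matching the sparsity of recurrent CNAs), a random sign, and a
`deep_frac` (default 0.3) admixture of ±2 calls among altered cells.
Planted genes get an exact, without-replacement draw of
`round(carrier_frac × n)` carriers bearing their mode's own call, and
contribute additively on the log-hazard scale:
h(t) = h₀ · exp(Σ β·carrier + cofactor effects). Additivity is the natural
generative counterpart of the Σβ scoring rule. Survival is exponential with
h₀ = log(2)/1095 (three-year median, a mid-range solid-tumor figure);
censoring combines exponential dropout (rate 1/2000 per day) with an
administrative horizon of 3650 days, yielding roughly 60–70% observed
events. Default cofactors are sex (no effect), age (+0.01 log-hazard per
year) and a three-level stage (0/0.25/0.5) — present so that stratified and
multivariate analyses have something realistic to adjust for, mild enough
not to dominate the planted genetic signal.

The default planted scenario — 300 samples, 200 gene regions, five
deep-amplification genes at β = 1.5 carried by 8% of samples — plants the
effect exclusively at C = +2, which is how the test suite reproduces the
qualitative finding that deep alterations build the cleaner models: soft
modes see the same carriers but diluted by soft background alterations.

What the generator does *not* emulate: genomic correlation along
chromosomes (each gene is drawn independently, whereas real CNAs come in
long segments of highly correlated genes), subclonal mixtures, mode
misclassification from purity/ploidy estimation error, and informative
censoring. Passing the planted-recovery tests therefore demonstrates that
the statistical machinery is correct and calibrated, not that any
particular clinical cohort will yield a significant model.

## Numerical and protocol choices

* Permutation p-values are computed vectorized (an at-risk incidence matrix
  times a carrier-assignment matrix), so exhaustive enumeration is used
  whenever C(n, k) ≤ 25,000 and Monte Carlo beyond.
* Per-gene Monte Carlo seeds are derived from the pipeline seed and a hash
  of the gene identifier, so results are identical whatever the row order
  of the input matrix.
* The recurrence filter is applied per mode, on the mode's own indicator: a
  gene with ten heterozygous losses but two homozygous deletions must not
  enter deep-deletion screening with two carriers. A global C ≠ 0
  pre-filter is available (`filter_recurrence_global()`) for users who
  prefer filtering once on the raw calls.
* Duplicate gene symbols in a GISTIC file keep the first row; duplicate
  sample columns are an error. Barcodes are truncated to 12 characters
  (TCGA patient level) for CNA/clinical alignment, overridable.
* Validation problem sizes (20 sparse fixtures for the
  exhaustive-vs-Monte-Carlo check, 2,000 null cohorts of n = 200 for
  type-I calibration, n = 1,000 for coefficient recovery, the 300 × 200
  planted scenario end to end) were chosen to make each check sharp at
  desk scale; they run in about a minute total.

## Known limitations

* Screening is univariate: co-occurring alterations in linkage (the rule,
  not the exception, for CNAs in the same cytoband) all enter the Σβ sums,
  so the sums over-count correlated evidence. The grouped assignment is
  robust to this in rank terms but the sums themselves are not
  interpretable as a joint model's linear predictor.
* The raw-p screening threshold reproduces the implemented protocol and
  will admit ~5% of null genes; cohorts with no true signal still produce
  labeled groups driven by false positives. The model-ranking penalty and
  the `fdr` column are the guard rails.
* Monotone-likelihood clamping at |β| = 10 is a pragmatic ceiling: such
  genes carry direction information but their magnitude is not estimable
  from the data.
* Proportional hazards is assumed throughout; no diagnostic for
  non-proportionality is built in.
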