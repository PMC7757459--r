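---
title: "From kinetic spot read-outs to response classification: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From kinetic spot read-outs to response classification: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinaflow)
```

## The measurement and its model

A porous peptide microarray reports tyrosine-kinase activity of a PBMC
lysate as fluorescent phosphorylation signal accumulating while the
reaction mixture is pumped through the membrane — here 60 pump cycles, with
three to four technical replicates per sample and 144 peptide substrate
spots per array. The raw datum is therefore a kinetic curve per spot:
foreground fluorescence and a locally measured background, both indexed by
cycle.

`kinaflow` models this curve as linear in cycle. Background-corrected
intensity for a signal-bearing spot rises with slope proportional to the
spot's latent kinase activity; a trendless spot is pure noise around zero.
Nothing in the downstream analysis depends on the curve family beyond a
monotone accumulation, and a line is the simplest shape consistent with the
positive-trend requirement used for spot QC; saturation kinetics would only
flatten late cycles, which the end-level statistic tolerates by design.

Each curve is collapsed to one number (`quantify_spots()`):

* `end_level` (default) — the median background-corrected intensity over
  the last quarter of cycles. Robust to per-cycle noise and close to an
  end-of-incubation read-out.
* `slope` — the OLS slope times the cycle count, i.e. fitted total
  accumulation.

Which one the original instrument software used is not documented, so both
are provided; all analyses here use `end_level`. The positive-trend test is
a one-sided OLS slope test at `alpha = 0.05` (configurable); on pure-noise
series it flags the nominal 5%, which the test suite checks.

## Quality control and normalization

**Replicates.** A technical replicate is dropped when it no longer
resembles its siblings: Pearson correlation (across peptides) with the mean
of the others below 0.8, or overall median signal more than 3.5 robust
(MAD) z-units from the replicate consensus. Both thresholds are
conventions, configurable and logged; at least one replicate always
survives. Retained replicates are averaged; a (sample, peptide) counts as
trend-detected when a majority of retained replicates show the positive
trend (ties count as detected).

**Peptide filter.** A peptide is excluded when the trend is missing in
strictly more than 75% of samples. The denominator is the samples present
after replicate QC, since the filter runs after those exclusions. On
generator defaults (trendless fraction 0.25) about 105–110 of 144 peptides
survive, comfortably inside the 60–95% band the tests assert.

**Clipping and transforms.** Background subtraction leaves a small
fraction of negative values; all raw signals below 1 are set to 1 before
any transform. Two transforms cover the two cohort phenotypes:

* `log2` for cohorts whose responders differ by an overall activity shift —
  base 2 so that differences read directly as log2 fold changes;
* a variance-stabilizing generalized log (`vsn_transform()`) for cohorts
  where only peptide *ratios* differ:
  `h_s(x) = asinh((x - a_s)/b_s)/ln 2`, with per-sample offset and scale
  calibrated so every sample has the same median and MAD of `h` (the
  across-sample median of each). The median constraint has a closed form
  (medians commute with monotone maps); the scale is found by
  root-finding, and the two-step update converges in a handful of
  iterations (tolerance 1e-8, cap 100). This is a robust median/MAD
  calibration of the glog family, not the maximum-likelihood fit of the
  classical microarray method; it keeps the defining behavior —
  `h(x2) - h(x1) -> log2(x2/x1)` at high intensity — which the tests check
  at `x = 1000(|a| + b)`, where both the scale and the offset terms of the
  asymptotic error (≈ `0.75 a/(x ln 2) + O((b/x)^2)`) are negligible.
  The calibration assumes most peptides do not differ between groups,
  which is why the ratio-shift generator moves equal numbers of peptides
  up and down.

**Sample outliers.** After transform and filter, a sample is flagged when
its robust z on one of the first two PCA scores exceeds 3.5 in absolute
value, or its overall median activity sits below −3.5 robust z (the
low-overall-activity phenotype behind most real exclusions). One guard is
deliberate: when a single criterion would flag more than a quarter of the
samples, it is reading structured variation — a biological class or a
batch — rather than aberrant samples, and is skipped. Without the guard,
a PC dominated by a strong responder effect labels the entire minority
class as "outliers", which is exactly what robust statistics do to the
smaller mode of a bimodal distribution. Two honest limitations follow and
are visible in the bundled analysis scripts: the glog branch rescales each
sample, so a purely attenuated (low-activity) sample is largely invisible
to it afterwards; and batch offsets widen the spread of sample medians, so
a ×0.25 attenuation that is obvious in a homogeneous cohort can fall short
of 3.5 robust z in a batched one (its footprint then shows up as an
inflated fold-change estimate instead).

**Batch correction.** Parametric empirical-Bayes correction of additive
and multiplicative per-batch, per-peptide effects: standardize each
peptide by its (batch-design) grand mean and pooled ML variance, estimate
batch effects on the standardized scale, shrink them toward batch-level
moment-matched priors (normal / inverse-gamma), correct, de-standardize.
A single batch returns the input unchanged. Two numerical choices matter.
The within-batch variance estimator uses the ML (n) denominator,
consistent with the pooled standardization — with the textbook n−1
denominator every pass shrinks the data by n/(n−1) and the correction is
not even approximately idempotent. And degenerate priors (zero
across-peptide spread of the batch-effect estimates) collapse to the
direct estimates rather than dividing 0/0; in that homogeneous limit the
correction equals direct location/scale standardization, removes a pure
offset exactly and is exactly idempotent, which the acceptance tests
assert at 1e-6. On heterogeneous data the EB posterior intentionally
leaves a small shrinkage residual; there the tests assert a ≥10× reduction
of the between/within batch variance ratio instead. No biological
covariate is preserved during correction by default (`preserve` exists but
defaults off) to avoid optimistically aligning the correction with the
labels.

## Differential statistics

Per peptide, a two-sided two-sample t-test of responders versus
non-responders (Welch by default; pooled available for exact replication
of classical analyses), `delta` = responder mean − non-responder mean in
log2 units, Benjamini–Hochberg q-values, and a significance flag at
unadjusted p < 0.05 — the FDR is reported, never used as the primary
filter. A column with no within-group variation (possible when every value
was clipped) resolves by its group means: equal means give p = 1,
different means p = 0. The cohort summary reports the median and SD of
`delta` over all retained peptides and the equivalent percent increase
`100 (2^median − 1)`; "SD" is the spread of per-peptide deltas, the more
conservative of the two readings the phrase admits.

## Classification

PLS-DA via NIPALS PLS1: responders coded +1, non-responders −1, predictors
autoscaled with training-fold statistics only, latent components extracted
by NIPALS, and the regression vector folded back to the original peptide
scale — the model is literally one coefficient per peptide plus an offset,
and the prediction index is their inner product with a profile. An index
strictly greater than 0 predicts a responder; exactly 0 predicts
non-responder (tie rule). All peptides enter the model; there is no
feature selection.

Cross-validation defaults to leave-one-out, which is natural at cohort
sizes of 10–56 and seed-free; k-fold is available. The number of
components is selected per training partition by inner leave-one-out over
{1, 2, 3}, ties resolved toward fewer components; a fixed-component mode
exists for reproducibility studies. Autoscaling inside the fold, and the
inner selection seeing only the training partition, are the leakage
discipline standard in chemometrics; the suite asserts a direct canary —
flipping a held-out sample's label cannot change that sample's own
prediction index.

The correct classification rate gets an exact two-sided Clopper–Pearson
interval, default level 0.90, computed by the beta-quantile identity and
cross-checked against direct inversion of the binomial tails (the two
routes agree to 1e-10; a brute-force oracle covers every (x, n) with
n ≤ 60 in the tests). For 10/10 correct the interval is 74.1%–100%; for
27/29 it is 79.8%–98.8%.

One bias is worth knowing about: under label permutation, leave-one-out
CCR on a balanced cohort sits *below* 0.5 (removing the held-out sample
leaves its class underrepresented in training, tilting predictions toward
the other class). At 5+5 the permuted-label mean CCR is ≈0.39; at 10+10 it
is ≈0.45. The permutation-null checks therefore run at the 10+10 scale,
with a fixed two-component model to keep 200 permutations cheap.

## The synthetic cohorts

The generator (`generate_cohort()`) emulates the statistical structure the
pipeline assumes, with defaults fixed once at the study's conditions: 144
peptides, 60 cycles, 3 replicates, baseline per-peptide log2 activity
N(7.5, 0.8) so end signals land at O(10²–10³) a.u., background 50 ± 5
a.u., per-cycle noise SD 8 a.u., biological sample×peptide noise 0.3 log2
units, replicate noise 0.1, a quarter of peptides trendless. Responder
effects come in two kinds: a global shift of every signal-bearing
peptide's activity (default 0.84 log2 units, the overall-activity
phenotype), or ratio shifts of a quarter of the peptides, half up and half
down, leaving overall activity unchanged (the phenotype the glog branch is
for). Batch offsets are additive in log2; designated outlier samples are
attenuated ×0.25 in raw intensity. Clinical metadata (best overall
response with SD durations, PFS, progression flags) is generated
consistently with the ground-truth label so both labeling schemes
round-trip.

What it does **not** emulate: real PamChip noise (no published
distributional description exists; Gaussian-on-log2 is a stand-in),
saturating kinetics, spatial array artifacts, peptide–peptide correlation
structure, or cohort-specific protocol covariates beyond an optional
attenuation. Passing tests therefore demonstrate the pipeline's internal
correctness and its behavior under the *assumed* noise model, not
performance on real patient data — which is also why the cohort-level
cross-validation CCRs of the original study are checked as properties
(parameter recovery, null calibration) rather than as numbers.

## Labeling conventions

Best overall response: CR or PR → responder; SD counts as clinical benefit
only at ≥90 days (the boundary day itself inclusive); SD shorter than 90
days is non-responder by convention (the source protocol states only the
90-day minimum for benefit); PD → non-responder. The PFS scheme groups
progression within 140 days (inclusive) as non-responder, later or no
progression as responder. Missing inputs yield `undefined`, never an
error; the pipeline excludes and logs such samples.

## Problem sizes and determinism

Unit tests run on reduced cohorts (40 peptides, 20 cycles) where the
property under test does not depend on the full scale; acceptance-level
checks use the full 144×60×3 geometry, 10 seeds for stochastic properties,
200 permutations for the null band, and 5000 draws for interval coverage.
The pipeline is a pure function of (data, configuration): leave-one-out is
seed-free, the generator is seeded, and rerunning a configuration
byte-reproduces the serialized report.

## Interfaces

The package's exported functions are the interface, with the numbered
scripts under `analysis/` as the workflow drivers (simulate → quantify →
normalize/QC → statistics → classification); each stage also writes its
tables (CSV/TSV/JSON) so any step can be rerun or inspected in isolation.
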