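# kinaflow

Blood-based kinase activity profiling as a response biomarker: `kinaflow`
implements the full analysis path from raw peptide-microarray kinetic
read-outs of PBMC lysates to a cross-validated classifier of clinical
benefit under immune-checkpoint inhibition.

The measurement is a porous tyrosine-kinase substrate array (144 peptides)
through which lysate is pumped for 60 cycles while phosphorylation signal
is imaged; each spot yields a kinetic curve per technical replicate. The
package covers, per cohort:

1. **Quantification** — local background subtraction, collapse of each
   curve to an end-level signal, one-sided OLS positive-trend test per spot.
2. **QC** — replicate consistency filtering (correlation and robust-z
   rules), majority-vote trend calls, exclusion of peptides trendless in
   >75% of samples, PCA/low-activity sample-outlier flagging.
3. **Normalization** — clipping of signals below 1, then `log2` (cohorts
   with overall activity shifts) or a median/MAD-calibrated generalized-log
   variance-stabilizing transform `h(x) = asinh((x−a)/b)/ln 2` (cohorts
   with peptide-ratio shifts).
4. **Batch correction** — parametric empirical-Bayes removal of additive
   and multiplicative per-batch effects.
5. **Statistics** — per-peptide two-sample t-tests (Welch or pooled),
   Benjamini–Hochberg FDR, fold-change summaries
   (`pct = 100·(2^median_log2FC − 1)`).
6. **Classification** — PLS-DA (NIPALS PLS1) on all peptides: one
   coefficient per peptide plus an offset; prediction index > 0 predicts a
   responder. Leave-one-out cross-validated correct classification rate
   (CCR) with exact two-sided 90% Clopper–Pearson intervals.
7. **Synthetic cohorts** — a seeded generator producing kinetic curves and
   clinical metadata with the structure above (global-shift and
   ratio-shift responder effects, batches, low-activity outliers), so every
   stage is testable without patient data.

## Worked example

```r
library(kinaflow)

cfg <- synthetic_config(n_responders = 5, n_nonresponders = 5,
                        effect_kind = "global_shift", effect_size = 0.84,
                        seed = 7)
cohort <- generate_cohort(cfg)
res <- run_pipeline(cohort$timecourses, cohort$meta)
res$classification
#> PLS-DA loo cross-validation: CCR 100% (10/10), 90% CI 74%-100%
round(res$fold_changes$median_delta, 2)
#> [1] 0.85
ncol(res$matrix)   # peptides surviving the trend filter, of 144
#> [1] 108
```

The classifier separates the designed 0.84-log2-unit responder shift
perfectly; 10/10 correct leave-one-out predictions give an exact 90%
binomial interval of 74%–100%, the median per-peptide log2 fold change
recovers the designed effect, and 108 of 144 peptides survive the
trendless-peptide filter.

The numbered scripts under `analysis/` run the same stages over three
study-shaped cohorts (discovery and cross-validation, both transform
branches), writing tables under `results/`:

```sh
Rscript analysis/01_simulate.R     # cohorts as CSV
Rscript analysis/02_quantify.R     # per-spot signals + replicate QC
Rscript analysis/03_normalize_qc.R # activity matrices + outliers + batches
Rscript analysis/04_peptide_stats.R
Rscript analysis/05_classify.R
```

`analysis/05_classify.R` prints, e.g.:

```
ctla4_A: CCR 100% (10/10), 90% CI 74%-100% [loo]
```

## Scope

The package starts from quantified spot intensities; image capture and
segmentation, upstream-kinase inference, and pathway enrichment are out of
scope. Cohorts are always analyzed singly, never pooled.
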