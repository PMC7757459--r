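Package: kinaflow
Title: Kinome Peptide-Array Activity Profiling and Response Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for tyrosine-kinase peptide-array activity
    profiling of PBMC lysates: kinetic-curve quantification with local
    background subtraction and positive-trend detection, technical-replicate
    quality control, low-signal clipping with log2 or variance-stabilizing
    (generalized-log) normalization, trendless-peptide filtering, PCA-based
    sample-outlier flagging, parametric empirical-Bayes batch correction,
    per-peptide differential t-statistics with Benjamini-Hochberg FDR, and
    PLS-DA response classification with cross-validated correct-classification
    rates and exact Clopper-Pearson binomial confidence intervals. Includes a
    synthetic-cohort generator emulating the kinetic and clinical structure of
    checkpoint-inhibitor response studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    sva,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
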