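#!/usr/bin/env Rscript
# Per-peptide differential statistics between responders and
# non-responders: two-sided two-sample t-tests, Benjamini-Hochberg FDR,
# and the cohort-level fold-change summary (median log2 fold change, its
# SD, the equivalent percent increase, and the significant fraction).

suppressPackageStartupMessages(library(kinaflow))

out_dir <- "results/stats"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

for (name in c("ctla4_A", "ctla4_B", "pd1_A")) {
  mat <- read_activity_matrix(file.path("results/matrices", paste0(name, "_activity.tsv")))
  meta <- read_sample_meta(file.path("results/data", paste0(name, "_meta.csv")))
  meta <- label_samples(meta, "bor")
  labels <- meta$label[match(rownames(mat), meta$sample_id)]
  stats <- peptide_ttest(mat, labels)
  fc <- summarize_fold_changes(stats)
  write.csv(stats, file.path(out_dir, paste0(name, "_peptide_stats.csv")),
            row.names = FALSE)
  jsonlite::write_json(fc, file.path(out_dir, paste0(name, "_fold_changes.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cat(sprintf("%s: median log2FC %.2f (SD %.2f) = %.0f%% increase; %d%% of peptides significant (FDR %.0f%%)\n",
              name, fc$median_delta, fc$sd_delta, fc$pct_increase,
              round(100 * fc$fraction_significant),
              100 * ifelse(is.na(fc$fdr_at_significant), 0, fc$fdr_at_significant)))
}
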