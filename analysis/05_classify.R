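#!/usr/bin/env Rscript
# Leave-one-out cross-validated PLS-DA per cohort: per-sample prediction
# indices (index > 0 predicts responder), the correct classification rate,
# and its exact 90% Clopper-Pearson interval. Also emits the figure-ready
# heat-map table (columns sorted by correlation with response, per-column
# z-scores).

suppressPackageStartupMessages(library(kinaflow))

out_dir <- "results/classification"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

for (name in c("ctla4_A", "ctla4_B", "pd1_A")) {
  mat <- read_activity_matrix(file.path("results/matrices", paste0(name, "_activity.tsv")))
  meta <- label_samples(read_sample_meta(file.path("results/data", paste0(name, "_meta.csv"))), "bor")
  labels <- meta$label[match(rownames(mat), meta$sample_id)]

  report <- crossvalidate(mat, labels, scheme = "loo", ci_level = 0.90)
  json <- list(cohort = name, ccr = report$ccr, n_correct = report$n_correct,
               n_total = report$n_total, ci_level = report$ci_level,
               ci_lower = report$ci_lower, ci_upper = report$ci_upper,
               cv_scheme = report$cv_scheme, per_sample = report$per_sample)
  jsonlite::write_json(json, file.path(out_dir, paste0(name, "_classification.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  hm <- heatmap_data(mat, labels)
  hm_df <- data.frame(sample_id = rownames(hm$values), hm$values,
                      check.names = FALSE)
  write.table(hm_df, file.path(out_dir, paste0(name, "_heatmap.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)

  cat(sprintf("%s: CCR %.0f%% (%d/%d), 90%% CI %.0f%%-%.0f%% [%s]\n",
              name, 100 * report$ccr, report$n_correct, report$n_total,
              100 * report$ci_lower, 100 * report$ci_upper, report$cv_scheme))
}
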