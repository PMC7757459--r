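#!/usr/bin/env Rscript
# Average retained replicates, drop peptides without a detectable kinetic
# trend in >75% of samples, clip signals below 1, transform (log2 for the
# anti-CTLA-4-like cohorts, glog/VSN for the anti-PD-1-like cohort), flag
# PCA / low-activity outlier samples, and batch-correct where a cohort has
# lysis batches. Writes activity matrices and a QC report per cohort.

suppressPackageStartupMessages(library(kinaflow))

out_dir <- "results/matrices"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
cohorts <- c(ctla4_A = "log2", ctla4_B = "log2", pd1_A = "vsn")

for (name in names(cohorts)) {
  signals <- read.csv(file.path("results/signals", paste0(name, "_signals.csv")))
  meta <- read_sample_meta(file.path("results/data", paste0(name, "_meta.csv")))
  avg <- average_replicates(signals)
  pf <- filter_trendless_peptides(avg$trend_detected)
  clipped <- clip_low(avg$values[, pf$retained, drop = FALSE])
  mat <- if (cohorts[[name]] == "log2")
    log2_transform(activity_matrix(clipped, "raw"))
  else vsn_transform(activity_matrix(clipped, "raw"))

  fl <- flag_outlier_samples(mat)
  if (length(fl$flagged)) {
    keep <- !(rownames(mat) %in% fl$flagged)
    mat <- activity_matrix(unclass(mat)[keep, , drop = FALSE],
                           attr(mat, "transform_tag"), attr(mat, "provenance"))
  }
  meta <- meta[match(rownames(mat), meta$sample_id), ]

  if (length(unique(meta$batch_id)) >= 2 && all(table(meta$batch_id) >= 2))
    mat <- combat_correct(mat, meta$batch_id)

  write_activity_matrix(mat, file.path(out_dir, paste0(name, "_activity.tsv")))
  qc <- list(cohort = name, transform = cohorts[[name]],
             n_samples = nrow(mat), n_peptides = ncol(mat),
             peptides_excluded = pf$excluded,
             samples_flagged = fl$flagged, flag_reasons = as.list(fl$reasons),
             pca_explained = pca_scores(mat, k = 2)$explained)
  jsonlite::write_json(qc, file.path(out_dir, paste0(name, "_qc.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cat(sprintf("%s [%s]: %d peptides retained (of 144), outliers removed: %s\n",
              name, cohorts[[name]], ncol(mat),
              if (length(fl$flagged)) paste(fl$flagged, collapse = ",") else "none"))
}
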