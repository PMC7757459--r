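#!/usr/bin/env Rscript
# Simulate the three study-shaped cohorts used throughout the analysis:
#   ctla4_A: anti-CTLA-4-like discovery cohort, 5 responders + 5
#            non-responders, global activity shift of 0.84 log2 units.
#   ctla4_B: anti-CTLA-4-like cross-validation cohort, 9+9, weaker shift
#            (0.40 log2 units), two lysis batches and one low-activity
#            outlier sample.
#   pd1_A:   anti-PD-1-like discovery cohort, 14+15, peptide-ratio shifts
#            (a quarter of peptides moved, half up / half down).
# Writes long-format time-course and metadata CSVs under results/data/.

suppressPackageStartupMessages(library(kinaflow))

out_dir <- "results/data"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

configs <- list(
  ctla4_A = synthetic_config(5, 5, effect_kind = "global_shift",
                             effect_size = 0.84, seed = 101),
  ctla4_B = synthetic_config(9, 9, effect_kind = "global_shift",
                             effect_size = 0.40, seed = 102,
                             batch_assignment = c("L1", "L2"),
                             batch_offsets = c(L1 = 0, L2 = 0.8),
                             n_outlier_samples = 1),
  pd1_A = synthetic_config(14, 15, effect_kind = "ratio_shift",
                           effect_size = 0.84, affected_fraction = 0.25,
                           seed = 103)
)

for (name in names(configs)) {
  co <- generate_cohort(configs[[name]])
  write_timecourses(co$timecourses, file.path(out_dir, paste0(name, "_timecourses.csv")))
  write_sample_meta(co$meta, file.path(out_dir, paste0(name, "_meta.csv")))
  tt <- truth_table(co$meta)
  write.csv(tt, file.path(out_dir, paste0(name, "_truth.csv")), row.names = FALSE)
  cat(sprintf("%s: %d samples (%d responders), %d spot curves, outliers: %s\n",
              name, nrow(tt), sum(tt$label == "responder"),
              nrow(co$timecourses) / configs[[name]]$n_cycles,
              if (any(tt$is_outlier)) paste(tt$sample_id[tt$is_outlier], collapse = ",")
              else "none"))
}
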