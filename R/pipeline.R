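#' Heat-map-ready data following the figure conventions
#'
#' Rows (samples) are sorted by response group (non-responders first);
#' columns (peptides) are sorted ascending by the Pearson correlation of
#' their values with the response indicator (responder = 1, non-responder =
#' 0), so the most non-responder-associated peptides sit leftmost and a
#' column equal to the indicator lands rightmost. Values are scaled per
#' column to zero mean and unit variance; zero-variance columns emit zeros
#' and correlation 0, keeping their original relative order.
#'
#' @param mat `activity_matrix`.
#' @param labels sample labels, defined for every row.
#' @return list with `values` (reordered z-scored matrix), `row_order`,
#'   `col_order`, `correlations` (named, in emitted column order).
#' @export
heatmap_data <- function(mat, labels) {
  v <- unclass(mat)
  bad <- !(labels %in% c("responder", "nonresponder"))
  if (any(bad))
    stop("undefined labels for sample(s): ",
         paste(rownames(v)[bad], collapse = ", "))
  y <- as.numeric(labels == "responder")
  cors <- apply(v, 2, function(col) {
    if (sd(col) == 0 || sd(y) == 0) 0 else cor(col, y)
  })
  col_order <- order(cors)                       # stable: ties keep input order
  row_order <- order(factor(labels, c("nonresponder", "responder")))
  z <- apply(v, 2, function(col) {
    s <- sd(col)
    if (s == 0) rep(0, length(col)) else (col - mean(col)) / s
  })
  rownames(z) <- rownames(v)
  out <- z[row_order, col_order, drop = FALSE]
  list(values = out, row_order = rownames(v)[row_order],
       col_order = colnames(v)[col_order],
       correlations = cors[col_order])
}

#' Run the full per-cohort analysis pipeline
#'
#' Orders the stages as: spot quantification -> replicate QC -> replicate
#' averaging -> trendless-peptide filter -> clip -> transform (log2 for
#' anti-CTLA-4-tagged cohorts, glog/VSN for anti-PD-1-tagged, overridable)
#' -> PCA outlier removal -> batch correction -> per-peptide statistics ->
#' cross-validated PLS-DA -> heat-map data. Cohorts are processed singly,
#' never pooled. Every removal decision (replicate, sample, peptide) is
#' logged with its reason.
#'
#' @param timecourses long time-course `data.frame` (see
#'   [read_timecourses()]).
#' @param meta metadata `data.frame`; a `label` column is derived via
#'   `label_scheme` when absent.
#' @param transform `"auto"` (keyed to the therapy tag), `"log2"` or
#'   `"vsn"`.
#' @param statistic spot summary statistic, see [quantify_spots()].
#' @param label_scheme labeling scheme when labels must be derived.
#' @param variance_mode t-test flavor, see [peptide_ttest()].
#' @param cv_scheme,n_components,component_candidates,ci_level passed to
#'   [crossvalidate()].
#' @param outlier_removal logical; remove PCA/low-activity outliers
#'   (default TRUE, needs >= 4 samples).
#' @return list with `matrix` (final `activity_matrix`), `qc` (replicate /
#'   sample / peptide exclusions and PCA variance fractions), `stats`,
#'   `fold_changes`, `classification`, `heatmap`, `log`.
#' @export
run_pipeline <- function(timecourses, meta,
                         transform = c("auto", "log2", "vsn"),
                         statistic = "end_level",
                         label_scheme = "bor",
                         variance_mode = "welch",
                         cv_scheme = "loo", n_components = NULL,
                         component_candidates = 1:3, ci_level = 0.90,
                         outlier_removal = TRUE) {
  transform <- match.arg(transform)
  log <- character()
  if (!"label" %in% names(meta)) meta <- label_samples(meta, label_scheme)
  undef <- meta$sample_id[meta$label == "undefined"]
  if (length(undef)) {
    log <- c(log, sprintf("sample %s: removed (undefined response label)", undef))
    meta <- meta[!meta$sample_id %in% undef, ]
  }
  timecourses <- timecourses[timecourses$sample_id %in% meta$sample_id, ]

  signals <- quantify_spots(timecourses, statistic = statistic)
  rqc <- apply_replicate_qc(signals)
  log <- c(log, rqc$log)
  avg <- average_replicates(rqc$signals)

  pf <- filter_trendless_peptides(avg$trend_detected)
  if (length(pf$excluded))
    log <- c(log, sprintf("peptide %s: excluded (trendless in >75%% of samples)",
                          pf$excluded))
  raw <- avg$values[, pf$retained, drop = FALSE]

  meta <- meta[match(rownames(raw), meta$sample_id), ]
  if (transform == "auto")
    transform <- if (any(meta$therapy == "anti-PD-1")) "vsn" else "log2"
  clipped <- clip_low(raw)
  mat <- if (transform == "log2")
    log2_transform(activity_matrix(clipped, "raw"))
  else vsn_transform(activity_matrix(clipped, "raw"))
  log <- c(log, sprintf("transform: %s", transform))

  pca_info <- NULL
  flagged <- character()
  if (outlier_removal && nrow(mat) >= 4) {
    fl <- flag_outlier_samples(mat)
    flagged <- fl$flagged
    if (length(flagged)) {
      log <- c(log, sprintf("sample %s: removed (%s)", flagged,
                            fl$reasons[flagged]))
      keep <- !(rownames(mat) %in% flagged)
      mat <- am_annotate(mat, values = unclass(mat)[keep, , drop = FALSE],
                         note = sprintf("removed %d outlier sample(s)",
                                        sum(!keep)))
      meta <- meta[keep, ]
    }
  }
  pca_info <- pca_scores(mat, k = min(2, nrow(mat) - 1, ncol(mat)))

  batches <- meta$batch_id
  if (length(unique(batches)) >= 2 && all(table(batches) >= 2)) {
    mat <- combat_correct(mat, batches)
    log <- c(log, sprintf("batch correction over %d batches",
                          length(unique(batches))))
  } else {
    log <- c(log, "batch correction skipped (single batch)")
  }

  stats <- peptide_ttest(mat, meta$label, variance_mode = variance_mode)
  fc <- summarize_fold_changes(stats)
  report <- crossvalidate(mat, meta$label, scheme = cv_scheme,
                          n_components = n_components,
                          component_candidates = component_candidates,
                          ci_level = ci_level)
  hm <- heatmap_data(mat, meta$label)

  list(matrix = mat,
       qc = list(replicate_log = rqc$log,
                 peptides_excluded = pf$excluded,
                 peptide_report = pf$report,
                 samples_flagged = flagged,
                 pca_explained = unname(pca_info$explained)),
       stats = stats, fold_changes = fc,
       classification = report, heatmap = hm, log = log)
}

#' Serialize a pipeline result to JSON (plus TSV/CSV sidecars)
#'
#' @param result output of [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_report <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(matrix = file.path(dir, "activity_matrix.tsv"),
             stats = file.path(dir, "peptide_stats.csv"),
             report = file.path(dir, "report.json"),
             heatmap = file.path(dir, "heatmap.tsv"))
  write_activity_matrix(result$matrix, paths[["matrix"]])
  fwrite(result$stats, paths[["stats"]])
  cl <- result$classification
  json <- list(ccr = cl$ccr, n_correct = cl$n_correct, n_total = cl$n_total,
               ci_level = cl$ci_level, ci_lower = cl$ci_lower,
               ci_upper = cl$ci_upper, cv_scheme = cl$cv_scheme,
               per_sample = cl$per_sample,
               fold_changes = result$fold_changes,
               qc = list(samples_flagged = result$qc$samples_flagged,
                         peptides_excluded = result$qc$peptides_excluded,
                         pca_explained = result$qc$pca_explained),
               log = result$log)
  jsonlite::write_json(json, paths[["report"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  hm <- data.frame(sample_id = rownames(result$heatmap$values),
                   result$heatmap$values, check.names = FALSE)
  write.table(hm, paths[["heatmap"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}
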