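#' Local background subtraction
#'
#' @param foreground,background numeric vectors of equal length.
#' @return elementwise `foreground - background`; negatives are preserved
#'   here (clipping is a normalization-stage decision).
#' @export
subtract_background <- function(foreground, background) {
  if (length(foreground) != length(background))
    stop("foreground and background differ in length")
  foreground - background
}

#' Positive-trend detection on a kinetic series
#'
#' Ordinary least-squares regression of the background-corrected intensity
#' on the cycle index; a spot is signal-positive when the slope is positive
#' and its one-sided p-value falls below `alpha`. Degenerate fits (zero
#' residual variance) resolve by the sign of the slope: exact positive ramps
#' get p = 0, exactly constant or decreasing noise-free series get p = 1.
#'
#' @param corrected background-corrected intensity series (length >= 3).
#' @param cycles cycle indices; defaults to `seq_along(corrected)`.
#' @param alpha one-sided significance level (default 0.05).
#' @return list with `slope`, `trend_p`, `trend_positive`.
#' @export
detect_positive_trend <- function(corrected, cycles = seq_along(corrected),
                                  alpha = 0.05) {
  n <- length(corrected)
  if (n < 3) stop("trend detection needs at least 3 cycles")
  if (length(cycles) != n) stop("cycles and series differ in length")
  x <- cycles - mean(cycles)
  sxx <- sum(x^2)
  slope <- sum(x * corrected) / sxx
  resid <- corrected - mean(corrected) - slope * x
  rss <- sum(resid^2)
  df <- n - 2
  if (rss <= .Machine$double.eps * sum(corrected^2) || rss == 0) {
    p <- if (slope > 0) 0 else 1
  } else {
    se <- sqrt(rss / df / sxx)
    p <- pt(slope / se, df = df, lower.tail = FALSE)
  }
  list(slope = slope, trend_p = p,
       trend_positive = (slope > 0 && p < alpha))
}

#' Quantify every spot of a time-course table
#'
#' Collapses each (sample, peptide, replicate) kinetic curve to one
#' background-corrected signal and attaches the trend test. Two signal
#' statistics are offered, since a kinetic curve admits more than one
#' one-number summary: `end_level` (default) is the median corrected
#' intensity over the last quarter of cycles — a robust end-of-incubation
#' read-out; `slope` is the OLS slope times the number of cycles, i.e. the
#' fitted total accumulation.
#'
#' @param tc validated time-course `data.frame`.
#' @param statistic `"end_level"` or `"slope"`.
#' @param alpha trend-test level, see [detect_positive_trend()].
#' @return `data.frame` with columns `sample_id`, `peptide_id`,
#'   `replicate_id`, `signal`, `trend_positive`, `trend_p`.
#' @export
quantify_spots <- function(tc, statistic = c("end_level", "slope"),
                           alpha = 0.05) {
  statistic <- match.arg(statistic)
  tc <- validate_timecourses(tc)
  dt <- as.data.table(tc)
  dt[, corrected := foreground - background]
  eps <- .Machine$double.eps
  out <- dt[, {
    n <- .N
    if (n < 3) stop("spot (", sample_id[1], ", ", peptide_id[1], ", ",
                    replicate_id[1], ") has fewer than 3 cycles")
    x <- cycle - mean(cycle)
    sxx <- sum(x^2)
    slope <- sum(x * corrected) / sxx
    rss <- sum((corrected - mean(corrected) - slope * x)^2)
    p <- if (rss <= eps * sum(corrected^2) || rss == 0) {
      if (slope > 0) 0 else 1
    } else pt(slope / sqrt(rss / (n - 2) / sxx), df = n - 2,
              lower.tail = FALSE)
    sig <- if (statistic == "end_level")
      median(corrected[cycle > 0.75 * max(cycle)])
    else slope * n
    list(signal = sig, trend_positive = (slope > 0 && p < alpha),
         trend_p = p)
  }, by = .(sample_id, peptide_id, replicate_id)]
  setDF(out)
}

#' Technical-replicate quality control for one sample
#'
#' A replicate is dropped when its Pearson correlation across peptides with
#' the mean of the remaining replicates falls below `min_cor`, or when its
#' overall median signal sits more than `max_median_z` robust (MAD-based)
#' z-units from the median of the replicate medians. A replicate whose
#' signal vector is constant (correlation undefined) fails the correlation
#' rule. At least one replicate is always retained: if all fail, the
#' best-correlated one is kept and flagged.
#'
#' @param sig_matrix replicates x peptides numeric matrix (rownames =
#'   replicate ids) of one sample's signals.
#' @param min_cor correlation threshold (default 0.8).
#' @param max_median_z robust z threshold on replicate medians (default 3.5).
#' @return list with `retained` (replicate ids), `dropped`, `reasons`
#'   (named character), `flagged` (TRUE when the keep-one fallback fired).
#' @export
qc_replicates <- function(sig_matrix, min_cor = 0.8, max_median_z = 3.5) {
  if (!is.matrix(sig_matrix)) sig_matrix <- as.matrix(sig_matrix)
  n_rep <- nrow(sig_matrix)
  if (n_rep < 2)
    return(list(retained = rownames(sig_matrix), dropped = character(),
                reasons = character(), flagged = FALSE))
  ids <- rownames(sig_matrix)
  if (is.null(ids)) ids <- as.character(seq_len(n_rep))
  cors <- vapply(seq_len(n_rep), function(r) {
    ref <- colMeans(sig_matrix[-r, , drop = FALSE])
    if (sd(sig_matrix[r, ]) == 0 || sd(ref) == 0) return(-Inf)
    cor(sig_matrix[r, ], ref)
  }, numeric(1))
  meds <- apply(sig_matrix, 1, median)
  center <- median(meds)
  scale <- mad(meds)
  med_z <- if (scale == 0) ifelse(meds == center, 0, Inf)
           else abs(meds - center) / scale
  fail_cor <- cors < min_cor
  fail_med <- med_z > max_median_z
  fail <- fail_cor | fail_med
  reasons <- character()
  for (r in which(fail)) {
    why <- c(if (fail_cor[r]) sprintf("correlation %.3f < %.2f", cors[r], min_cor),
             if (fail_med[r]) sprintf("median robust z %.1f > %.1f", med_z[r], max_median_z))
    reasons[ids[r]] <- paste(why, collapse = "; ")
  }
  flagged <- FALSE
  if (all(fail)) {
    keep <- which.max(cors)
    fail[keep] <- FALSE
    flagged <- TRUE
    reasons[ids[keep]] <- paste0("retained despite QC failure (fallback): ",
                                 reasons[ids[keep]])
  }
  list(retained = ids[!fail], dropped = ids[fail & !is.na(fail)],
       reasons = reasons, flagged = flagged)
}

#' Apply replicate QC across a whole cohort of spot signals
#'
#' @param signals output of [quantify_spots()].
#' @param min_cor,max_median_z see [qc_replicates()].
#' @return list with `signals` (filtered `data.frame`) and `log` (character,
#'   one line per dropped or flagged replicate).
#' @export
apply_replicate_qc <- function(signals, min_cor = 0.8, max_median_z = 3.5) {
  log <- character()
  keep <- rep(TRUE, nrow(signals))
  for (s in unique(signals$sample_id)) {
    sub <- signals[signals$sample_id == s, ]
    wide <- tapply(sub$signal, list(sub$replicate_id, sub$peptide_id), mean)
    res <- qc_replicates(wide, min_cor = min_cor, max_median_z = max_median_z)
    if (length(res$dropped)) {
      keep[signals$sample_id == s &
             signals$replicate_id %in% res$dropped] <- FALSE
      log <- c(log, sprintf("sample %s: dropped replicate %s (%s)", s,
                            res$dropped, res$reasons[res$dropped]))
    }
    if (res$flagged)
      log <- c(log, sprintf("sample %s: all replicates failed QC; %s", s,
                            res$reasons[res$retained]))
  }
  list(signals = signals[keep, ], log = log)
}

#' Average retained replicates into per-(sample, peptide) signals
#'
#' Arithmetic mean of retained replicate signals. A (sample, peptide) pair
#' counts as trend-detected when a majority of its retained replicates are
#' trend-positive; ties count as detected.
#'
#' @param signals filtered output of [quantify_spots()].
#' @return list with `values` (samples x peptides raw signal matrix) and
#'   `trend_detected` (logical matrix of the same shape).
#' @export
average_replicates <- function(signals) {
  samples <- unique(signals$sample_id)
  peptides <- unique(signals$peptide_id)
  mean_mat <- tapply(signals$signal,
                     list(factor(signals$sample_id, samples),
                          factor(signals$peptide_id, peptides)), mean)
  trend_frac <- tapply(as.numeric(signals$trend_positive),
                       list(factor(signals$sample_id, samples),
                            factor(signals$peptide_id, peptides)), mean)
  if (anyNA(mean_mat))
    stop("every (sample, peptide) pair needs at least one retained replicate")
  list(values = mean_mat, trend_detected = trend_frac >= 0.5)
}
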