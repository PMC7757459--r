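#' Per-peptide two-sample t-tests between responders and non-responders
#'
#' For every peptide, a two-sided two-sample t-test of responders versus
#' non-responders on the transformed activity values. `delta` is the
#' responder mean minus the non-responder mean in log2 units. Welch's
#' unequal-variance form is the default; the pooled-variance form is
#' available for exact replication of classical analyses.
#'
#' @param mat `activity_matrix` (samples x peptides, transformed).
#' @param labels character vector (`"responder"`/`"nonresponder"`), one per
#'   sample, in row order of `mat`.
#' @param variance_mode `"welch"` (default) or `"pooled"`.
#' @param alpha significance threshold on the unadjusted p-value (default
#'   0.05, reported FDR never used as the primary filter).
#' @return `data.frame` with columns `peptide_id`, `delta`, `t_stat`,
#'   `p_value`, `q_value` (Benjamini-Hochberg), `significant`.
#' @export
peptide_ttest <- function(mat, labels, variance_mode = c("welch", "pooled"),
                          alpha = 0.05) {
  variance_mode <- match.arg(variance_mode)
  v <- unclass(mat)
  if (length(labels) != nrow(v))
    stop("labels must match the number of samples")
  is_r <- labels == "responder"
  is_n <- labels == "nonresponder"
  if (sum(is_r) < 2 || sum(is_n) < 2)
    stop("each group needs at least 2 samples for the t-test")
  res <- apply(v, 2, function(x) {
    delta <- mean(x[is_r]) - mean(x[is_n])
    if (sd(x[is_r]) == 0 && sd(x[is_n]) == 0) {
      # degenerate column (e.g. fully clipped): no within-group variation
      if (delta == 0) return(c(delta = 0, t_stat = 0, p_value = 1))
      return(c(delta = delta, t_stat = sign(delta) * Inf, p_value = 0))
    }
    tt <- t.test(x[is_r], x[is_n], var.equal = (variance_mode == "pooled"))
    c(delta = delta, t_stat = unname(tt$statistic), p_value = tt$p.value)
  })
  out <- data.frame(peptide_id = colnames(v), t(res),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$q_value <- bh_adjust(out$p_value)
  out$significant <- out$p_value < alpha
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin, validated wrapper over the standard step-up procedure: sorted
#' ascending, `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1, mapped back
#' to input order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted q-values in input order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Summarize per-peptide fold changes
#'
#' @param stats output of [peptide_ttest()].
#' @return list with `median_delta` and `sd_delta` (log2 units over all
#'   retained peptides), `pct_increase` (`100 * (2^median_delta - 1)`),
#'   `fraction_significant` (unadjusted p < threshold), and
#'   `fdr_at_significant` (mean q-value within the significant set, `NA`
#'   when empty).
#' @export
summarize_fold_changes <- function(stats) {
  if (nrow(stats) < 1) stop("no peptide rows to summarize")
  med <- median(stats$delta)
  sig <- stats$significant
  list(median_delta = med,
       sd_delta = sd(stats$delta),
       pct_increase = 100 * (2 ^ med - 1),
       fraction_significant = mean(sig),
       fdr_at_significant = if (any(sig)) mean(stats$q_value[sig]) else NA_real_)
}
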