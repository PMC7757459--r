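utils::globalVariables(c("corrected", "foreground", "background", "cycle",
                         "sample_id", "peptide_id", "replicate_id", ".",
                         ".N"))

#' Clip low raw signals
#'
#' Background-corrected raw signals below 1 (including the small fraction of
#' negative values produced by background subtraction) are set to 1, so the
#' subsequent log2 transform is defined and bounded below by zero.
#' Idempotent by construction.
#'
#' @param x numeric vector or matrix of raw signals.
#' @return `x` with every value < 1 replaced by 1.
#' @export
clip_low <- function(x) {
  x[x < 1] <- 1
  x
}

#' Log2 transform of clipped raw signals
#'
#' @param mat `activity_matrix` (or plain matrix) of clipped raw signals,
#'   all values >= 1.
#' @return `activity_matrix` tagged `log2`.
#' @export
log2_transform <- function(mat) {
  v <- unclass(mat)
  if (any(v < 1))
    stop("log2_transform expects clipped signals (all >= 1); clip first")
  out <- log2(v)
  activity_matrix(out, transform_tag = "log2",
                  provenance = c(attr(mat, "provenance"), "log2 transform"))
}

#' Fit per-sample generalized-log (arsinh) normalization parameters
#'
#' Variance-stabilizing transform `h_s(x) = asinh((x - a_s) / b_s) / ln 2`
#' with one offset `a_s` and one scale `b_s > 0` per sample, calibrated so
#' that (i) each sample's median of `h` equals the across-sample median of
#' medians and (ii) each sample's MAD of `h` equals the across-sample median
#' MAD. Because `asinh` is monotone, the median constraint is solved in
#' closed form given `b_s`; the MAD constraint is solved by bisection on
#' `log b_s`. Targets and parameters are iterated to convergence (parameter
#' change < `tol`). At high intensity `h` approaches `log2`, so differences
#' of `h` read as log2 fold changes.
#'
#' @param raw samples x peptides matrix of (clipped) raw signals.
#' @param tol convergence tolerance on parameter change (default 1e-8).
#' @param max_iter iteration cap (default 100).
#' @return list with numeric vectors `a` and `b` (named by sample).
#' @export
fit_vsn <- function(raw, tol = 1e-8, max_iter = 100) {
  v <- unclass(raw)
  if (nrow(v) < 2 || ncol(v) < 2)
    stop("glog normalization needs at least 2 samples and 2 peptides")
  spread <- apply(v, 1, mad)
  if (any(spread == 0)) {
    bad <- rownames(v)[which(spread == 0)[1]]
    stop("sample ", bad, " has zero spread; cannot calibrate glog scale")
  }
  a <- rep(0, nrow(v))
  b <- spread
  h <- function(x, a, b) asinh((x - a) / b) / log(2)
  for (iter in seq_len(max_iter)) {
    ht <- t(vapply(seq_len(nrow(v)), function(s) h(v[s, ], a[s], b[s]),
                   numeric(ncol(v))))
    med_target <- median(apply(ht, 1, median))
    mad_target <- median(apply(ht, 1, mad))
    u <- sinh(med_target * log(2))
    a_new <- numeric(nrow(v))
    b_new <- numeric(nrow(v))
    for (s in seq_len(nrow(v))) {
      med_x <- median(v[s, ])
      mad_s <- function(logb) {
        bb <- exp(logb)
        aa <- med_x - bb * u
        mad(h(v[s, ], aa, bb)) - mad_target
      }
      lo <- log(b[s]) - 20; hi <- log(b[s]) + 20
      # MAD of h is monotone decreasing in b
      root <- uniroot(mad_s, c(lo, hi), tol = 1e-12)$root
      b_new[s] <- exp(root)
      a_new[s] <- med_x - b_new[s] * u
    }
    delta <- max(abs(a_new - a) / (1 + abs(a)), abs(b_new - b) / (1 + b))
    a <- a_new; b <- b_new
    if (delta < tol) break
  }
  names(a) <- names(b) <- rownames(v)
  list(a = a, b = b)
}

#' Apply fitted generalized-log parameters
#'
#' @param raw samples x peptides matrix of raw signals.
#' @param params output of [fit_vsn()].
#' @return `activity_matrix` tagged `vsn` (log2-based generalized log).
#' @export
apply_vsn <- function(raw, params) {
  v <- unclass(raw)
  if (!all(rownames(v) %in% names(params$a)))
    stop("glog parameters missing for some samples")
  out <- t(vapply(rownames(v), function(s)
    asinh((v[s, ] - params$a[s]) / params$b[s]) / log(2),
    numeric(ncol(v))))
  rownames(out) <- rownames(v)
  colnames(out) <- colnames(v)
  activity_matrix(out, transform_tag = "vsn",
                  provenance = c(attr(raw, "provenance"),
                                 "glog (arsinh) variance-stabilizing normalization"))
}

#' Fit-and-apply convenience wrapper
#' @inheritParams fit_vsn
#' @return `activity_matrix` tagged `vsn`.
#' @export
vsn_transform <- function(raw, tol = 1e-8, max_iter = 100) {
  apply_vsn(raw, fit_vsn(raw, tol = tol, max_iter = max_iter))
}

#' Trendless-peptide exclusion rule
#'
#' A peptide is excluded when a kinetic trend could not be detected in
#' strictly more than 75% of the samples (exactly 75% is retained).
#'
#' @param trend_detected samples x peptides logical matrix from
#'   [average_replicates()].
#' @param max_trendless_fraction exclusion threshold (default 0.75, strict
#'   inequality).
#' @return list with `retained` (peptide ids), `excluded`, and `report`
#'   (`data.frame` of per-peptide trendless fractions and flags).
#' @export
filter_trendless_peptides <- function(trend_detected,
                                      max_trendless_fraction = 0.75) {
  n_samples <- nrow(trend_detected)
  frac <- colMeans(!trend_detected)
  excluded <- frac > max_trendless_fraction
  report <- data.frame(peptide_id = colnames(trend_detected),
                       trendless_fraction = unname(frac),
                       excluded = unname(excluded),
                       stringsAsFactors = FALSE)
  list(retained = colnames(trend_detected)[!excluded],
       excluded = colnames(trend_detected)[excluded],
       report = report)
}
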