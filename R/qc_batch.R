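#' PCA scores of an activity matrix
#'
#' Columns (peptides) are centered internally; scores are the projections on
#' the top-k right-singular directions.
#'
#' @param mat `activity_matrix` or numeric samples x peptides matrix.
#' @param k number of components.
#' @return list with `scores` (samples x k), `explained` (variance
#'   fractions, non-increasing), `loadings` (peptides x k).
#' @export
pca_scores <- function(mat, k = 2) {
  v <- unclass(mat)
  kmax <- min(nrow(v) - 1, ncol(v))
  if (k < 1 || k > kmax)
    stop("k must be between 1 and min(n_samples - 1, n_peptides) = ", kmax)
  pc <- prcomp(v, center = TRUE, scale. = FALSE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       explained = expl[seq_len(k)],
       loadings = pc$rotation[, seq_len(k), drop = FALSE])
}

robust_z <- function(x) {
  center <- median(x)
  scale <- mad(x)
  if (scale == 0) return(ifelse(x == center, 0, Inf * sign(x - center)))
  (x - center) / scale
}

#' Flag outlier samples by PCA scores and overall activity
#'
#' A sample is flagged when its robust (MAD-based) z-score on any of the
#' first `k` principal components exceeds `z_threshold` in absolute value,
#' or when the robust z of its overall median activity falls below
#' `-z_threshold` — the low-overall-kinase-activity phenotype that accounts
#' for most real-world sample exclusions.
#'
#' Outliers are by definition few: when a single criterion would flag more
#' than `max_flag_fraction` of the samples, it is reading structured
#' variation (a biological group or a batch) rather than aberrant samples,
#' and that criterion is skipped. Robust statistics would otherwise label
#' the minority mode of a bimodal score distribution as outliers wholesale.
#'
#' @param mat `activity_matrix` (transformed, filtered).
#' @param k number of leading components inspected (default 2).
#' @param z_threshold robust z cut-off (default 3.5).
#' @param max_flag_fraction per-criterion breakdown guard (default 0.25).
#' @return list with `flagged` (sample ids) and `reasons` (named character).
#' @export
flag_outlier_samples <- function(mat, k = 2, z_threshold = 3.5,
                                 max_flag_fraction = 0.25) {
  v <- unclass(mat)
  if (nrow(v) < 4) stop("outlier flagging needs at least 4 samples")
  k <- min(k, nrow(v) - 1, ncol(v))
  pcs <- pca_scores(v, k = k)$scores
  cap <- max_flag_fraction * nrow(v)
  reasons <- character()
  add <- function(reasons, hits, fmt, z) {
    if (length(hits) == 0 || length(hits) > cap) return(reasons)
    for (i in hits) {
      s <- rownames(v)[i]
      msg <- sprintf(fmt, z[i])
      reasons[s] <- if (is.na(reasons[s])) msg
                    else paste(reasons[s], msg, sep = "; ")
    }
    reasons
  }
  for (j in seq_len(ncol(pcs))) {
    z <- robust_z(pcs[, j])
    reasons <- add(reasons, which(abs(z) > z_threshold),
                   sprintf("PC%d robust z %%.1f", j), z)
  }
  zmed <- robust_z(apply(v, 1, median))
  reasons <- add(reasons, which(zmed < -z_threshold),
                 "low overall activity (median robust z %.1f)", zmed)
  list(flagged = if (length(reasons)) names(reasons) else character(0),
       reasons = reasons)
}

# Iterative posterior solve for one batch's EB batch-effect estimates.
# Degenerate priors (zero across-peptide spread) collapse to the direct
# estimates, which is the exact homogeneous-batch-effect limit.
eb_solve <- function(z_batch, gamma_hat, delta_hat, conv = 1e-12,
                     max_iter = 5000) {
  n_b <- ncol(z_batch)
  gamma_bar <- mean(gamma_hat)
  t2 <- var(gamma_hat)
  m <- mean(delta_hat)
  s2 <- var(delta_hat)
  if (!is.finite(t2) || t2 < 1e-14) {
    # additive effects homogeneous: posterior is the common value
    gamma_star <- rep(gamma_bar, length(gamma_hat))
    delta_star <- if (!is.finite(s2) || s2 < 1e-14) delta_hat else {
      a <- (2 * s2 + m^2) / s2
      b <- (m * s2 + m^3) / s2
      (b + 0.5 * rowSums((z_batch - gamma_star)^2)) / (n_b / 2 + a - 1)
    }
    return(list(gamma_star = gamma_star, delta_star = delta_star))
  }
  if (!is.finite(s2) || s2 < 1e-14) {
    # multiplicative effects homogeneous: no shrinkage needed on delta
    delta_star <- delta_hat
    gamma_star <- (n_b * t2 * gamma_hat + delta_star * gamma_bar) /
      (n_b * t2 + delta_star)
    return(list(gamma_star = gamma_star, delta_star = delta_star))
  }
  a <- (2 * s2 + m^2) / s2
  b <- (m * s2 + m^3) / s2
  gamma_star <- gamma_hat
  delta_star <- delta_hat
  for (it in seq_len(max_iter)) {
    gamma_new <- (n_b * t2 * gamma_hat + delta_star * gamma_bar) /
      (n_b * t2 + delta_star)
    sse <- rowSums((z_batch - gamma_new)^2)
    delta_new <- (b + 0.5 * sse) / (n_b / 2 + a - 1)
    change <- max(abs(gamma_new - gamma_star), abs(delta_new - delta_star))
    gamma_star <- gamma_new
    delta_star <- delta_new
    if (change < conv) break
  }
  list(gamma_star = gamma_star, delta_star = delta_star)
}

#' Parametric empirical-Bayes batch correction
#'
#' Removes additive and multiplicative per-batch, per-peptide effects by the
#' parametric empirical-Bayes scheme: peptides are standardized by their
#' grand mean (batch-size weighted) and pooled variance; per-batch effects
#' estimated on the standardized data are shrunk toward batch-level priors
#' (normal for additive, inverse-gamma for multiplicative, moment-matched),
#' and the corrected matrix is de-standardized. With a single batch the
#' matrix is returned unchanged (no correction necessary). No biological
#' covariates are included by default; `preserve` accepts a factor (e.g. the
#' response label) to be protected during standardization, default off to
#' avoid optimistic bias.
#'
#' @param mat `activity_matrix`, samples x peptides.
#' @param batch character/factor of batch labels, one per sample.
#' @param preserve optional factor of biological groups to protect.
#' @param conv convergence tolerance of the EB posterior iteration.
#' @return corrected `activity_matrix` (same transform tag).
#' @export
combat_correct <- function(mat, batch, preserve = NULL, conv = 1e-12) {
  v <- unclass(mat)
  batch <- as.character(batch)
  if (length(batch) != nrow(v))
    stop("batch labels must match the number of samples")
  tabs <- table(batch)
  if (length(tabs) < 2)
    return(am_annotate(mat, note = "single batch: no correction applied"))
  if (any(tabs < 2))
    stop("batch ", names(tabs)[tabs < 2][1],
         " has fewer than 2 samples; cannot estimate batch effects")

  g <- t(v)                       # peptides x samples
  batches <- names(tabs)
  n <- ncol(g)
  design <- sapply(batches, function(b) as.numeric(batch == b))
  if (!is.null(preserve)) {
    bio <- stats::model.matrix(~ factor(preserve))[, -1, drop = FALSE]
    design_full <- cbind(design, bio)
  } else design_full <- design
  beta <- t(solve(crossprod(design_full), t(g %*% design_full)))
  batch_beta <- beta[, seq_along(batches), drop = FALSE]
  grand <- as.vector(batch_beta %*% (as.numeric(tabs[batches]) / n))
  fitted <- beta %*% t(design_full)
  var_pooled <- rowSums((g - fitted)^2) / n  # ML variance (divide by n)
  if (any(var_pooled == 0))
    stop("peptide ", rownames(g)[which(var_pooled == 0)[1]],
         " has zero pooled variance; cannot standardize")
  stand_mean <- matrix(grand, nrow(g), n)
  if (!is.null(preserve))
    stand_mean <- stand_mean + beta[, -seq_along(batches), drop = FALSE] %*%
      t(design_full[, -seq_along(batches), drop = FALSE])
  z <- (g - stand_mean) / sqrt(var_pooled)

  corrected_z <- z
  for (b in batches) {
    cols <- which(batch == b)
    zb <- z[, cols, drop = FALSE]
    gamma_hat <- rowMeans(zb)
    # ML (n-denominator) variance, consistent with the pooled standardization;
    # makes correction of homogeneous batch effects exactly idempotent
    delta_hat <- rowSums((zb - gamma_hat)^2) / length(cols)
    post <- eb_solve(zb, gamma_hat, delta_hat, conv = conv)
    corrected_z[, cols] <- (zb - post$gamma_star) / sqrt(post$delta_star)
  }
  out <- t(corrected_z * sqrt(var_pooled) + stand_mean)
  dimnames(out) <- dimnames(v)
  am_annotate(mat, values = out,
              note = sprintf("empirical-Bayes batch correction over %d batches",
                             length(batches)))
}
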