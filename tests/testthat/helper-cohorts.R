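# Shared fixture builders. Small configs keep unit tests fast; acceptance
# tests use the full study-scale defaults.

small_config <- function(n_r = 4, n_n = 4, seed = 1, ...) {
  synthetic_config(n_r, n_n, n_peptides = 40, n_cycles = 20, seed = seed, ...)
}

# transformed activity matrix straight from a cohort, no outlier removal
cohort_matrix <- function(config, transform = "log2") {
  co <- generate_cohort(config)
  sig <- apply_replicate_qc(quantify_spots(co$timecourses))$signals
  avg <- average_replicates(sig)
  pf <- filter_trendless_peptides(avg$trend_detected)
  clipped <- clip_low(avg$values[, pf$retained, drop = FALSE])
  mat <- if (transform == "log2")
    log2_transform(activity_matrix(clipped, "raw"))
  else vsn_transform(activity_matrix(clipped, "raw"))
  list(mat = mat, labels = co$meta$label, meta = co$meta,
       truth = truth_table(co$meta))
}

random_label_matrix <- function(n, p, seed) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("S%02d", 1:n), sprintf("P%03d", 1:p)))
  labels <- rep(c("responder", "nonresponder"), length.out = n)
  list(x = x, labels = labels)
}

# independent brute-force step-up oracle for the BH procedure
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  if (m > 1) for (i in (m - 1):1) q[i] <- min(q[i], q[i + 1])
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# independent binomial-tail root-finding oracle for Clopper-Pearson
cp_oracle <- function(x, n, level = 0.90) {
  a <- (1 - level) / 2
  lower <- if (x == 0) 0 else
    uniroot(function(p) pbinom(x - 1, n, p, lower.tail = FALSE) - a,
            c(1e-12, 1 - 1e-12), tol = 1e-15)$root
  upper <- if (x == n) 1 else
    uniroot(function(p) pbinom(x, n, p) - a,
            c(1e-12, 1 - 1e-12), tol = 1e-15)$root
  c(lower, upper)
}
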