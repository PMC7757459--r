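#' Configuration for a synthetic kinome cohort
#'
#' Builds the parameter set for [generate_cohort()]. Defaults emulate the
#' study conditions the pipeline is designed for: 144 tyrosine-kinase
#' substrate peptides, 60 pump cycles per kinetic read-out, three technical
#' replicates, a quarter of peptides without detectable kinetic trend, and a
#' responder effect of 0.84 log2 units for the global-shift (anti-CTLA-4-like)
#' regime.
#'
#' Two responder-effect regimes are supported. `global_shift` raises the
#' latent log2 activity of every signal-bearing peptide in responders by
#' `effect_size` (the overall-activity phenotype of anti-CTLA-4-like
#' cohorts). `ratio_shift` perturbs only `affected_fraction` of peptides,
#' half up and half down by `effect_size`, leaving overall activity
#' unchanged (the peptide-ratio phenotype of anti-PD-1-like cohorts, and the
#' regime under which the non-differential-majority assumption of
#' variance-stabilizing normalization holds).
#'
#' @param n_responders,n_nonresponders group sizes.
#' @param n_peptides number of array peptides (default 144).
#' @param n_replicates technical replicates per sample, 3 or 4.
#' @param n_cycles pump cycles per kinetic curve (default 60).
#' @param effect_kind `"global_shift"` or `"ratio_shift"`.
#' @param effect_size responder effect in log2 units.
#' @param affected_fraction fraction of peptides carrying the ratio-shift
#'   effect (ignored for `global_shift`).
#' @param trendless_fraction fraction of peptides with no kinetic trend
#'   (latent activity zero; their background-corrected signal is pure noise).
#' @param noise_sd_log2 biological sample-by-peptide noise, log2 units.
#' @param replicate_sd_log2 technical replicate noise, log2 units.
#' @param background_mean,background_sd local-background level and spread,
#'   arbitrary fluorescence units.
#' @param cycle_noise_sd per-cycle read-out noise, arbitrary units.
#' @param baseline_mean_log2,baseline_sd_log2 distribution of per-peptide
#'   baseline log2 activities (end signals land at O(10^2-10^3) a.u.).
#' @param batch_assignment character vector of batch labels, recycled over
#'   samples in order; default a single batch `"B1"`.
#' @param batch_offsets named numeric vector of additive log2 offsets per
#'   batch label; default zero.
#' @param n_outlier_samples number of samples attenuated x0.25 in raw
#'   intensity (the low-overall-activity outlier phenotype).
#' @param seed integer seed; identical config + seed gives bit-identical
#'   cohorts.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_responders, n_nonresponders,
                             n_peptides = 144L, n_replicates = 3L,
                             n_cycles = 60L,
                             effect_kind = c("global_shift", "ratio_shift"),
                             effect_size = 0.84,
                             affected_fraction = 0.25,
                             trendless_fraction = 0.25,
                             noise_sd_log2 = 0.3,
                             replicate_sd_log2 = 0.1,
                             background_mean = 50, background_sd = 5,
                             cycle_noise_sd = 8,
                             baseline_mean_log2 = 7.5,
                             baseline_sd_log2 = 0.8,
                             batch_assignment = "B1",
                             batch_offsets = NULL,
                             n_outlier_samples = 0L,
                             seed = 1L) {
  effect_kind <- match.arg(effect_kind)
  stopifnot(n_responders >= 0, n_nonresponders >= 0,
            n_peptides >= 1, n_replicates %in% c(3L, 4L),
            n_cycles >= 2,
            affected_fraction >= 0, affected_fraction <= 1,
            trendless_fraction >= 0, trendless_fraction <= 1,
            noise_sd_log2 >= 0, replicate_sd_log2 >= 0,
            n_outlier_samples >= 0)
  if (n_responders + n_nonresponders == 0)
    stop("cohort must contain at least one sample")
  cfg <- list(n_responders = as.integer(n_responders),
              n_nonresponders = as.integer(n_nonresponders),
              n_peptides = as.integer(n_peptides),
              n_replicates = as.integer(n_replicates),
              n_cycles = as.integer(n_cycles),
              effect_kind = effect_kind, effect_size = effect_size,
              affected_fraction = affected_fraction,
              trendless_fraction = trendless_fraction,
              noise_sd_log2 = noise_sd_log2,
              replicate_sd_log2 = replicate_sd_log2,
              background_mean = background_mean,
              background_sd = background_sd,
              cycle_noise_sd = cycle_noise_sd,
              baseline_mean_log2 = baseline_mean_log2,
              baseline_sd_log2 = baseline_sd_log2,
              batch_assignment = as.character(batch_assignment),
              batch_offsets = batch_offsets,
              n_outlier_samples = as.integer(n_outlier_samples),
              seed = as.integer(seed))
  class(cfg) <- "synthetic_config"
  cfg
}

#' Generate a synthetic cohort of kinetic spot read-outs plus metadata
#'
#' The kinetic model is linear in cycle: for a spot with raw latent
#' amplitude A (A = 2^latent log2 activity, or 0 for trendless peptides),
#' `foreground(c) = background_level + A * c / n_cycles + cycle noise`,
#' with the locally measured `background` an independent positive noise
#' series around `background_mean`. Background subtraction therefore yields
#' a positively trending corrected curve for signal-bearing spots and pure
#' (occasionally negative) noise for trendless ones.
#'
#' Latent log2 activity for sample s, peptide p:
#' baseline_p + responder effect + batch offset(b(s)) + biological noise,
#' plus replicate noise per technical replicate. Designated outlier samples
#' are attenuated x0.25 in raw amplitude last, mimicking samples with low
#' overall kinase activity.
#'
#' @param config a [synthetic_config()].
#' @return list with `timecourses` (long `data.frame` as accepted by
#'   [validate_timecourses()]) and `meta` (metadata `data.frame` with the
#'   ground-truth `label` column and an attached truth table, see
#'   [truth_table()]).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n_s <- config$n_responders + config$n_nonresponders
  sample_ids <- sprintf("S%02d", seq_len(n_s))
  labels <- rep(c("responder", "nonresponder"),
                c(config$n_responders, config$n_nonresponders))
  peptide_ids <- sprintf("P%03d", seq_len(config$n_peptides))
  batches <- rep_len(config$batch_assignment, n_s)
  offsets <- config$batch_offsets
  batch_shift <- if (is.null(offsets)) rep(0, n_s) else {
    miss <- setdiff(unique(batches), names(offsets))
    if (length(miss)) stop("no batch offset given for batch ", miss[1])
    unname(offsets[batches])
  }

  n_trendless <- round(config$trendless_fraction * config$n_peptides)
  trendless <- rep(FALSE, config$n_peptides)
  if (n_trendless > 0)
    trendless[sample.int(config$n_peptides, n_trendless)] <- TRUE

  baseline <- rnorm(config$n_peptides, config$baseline_mean_log2,
                    config$baseline_sd_log2)

  # per-peptide responder effect (log2 units)
  effect <- rep(0, config$n_peptides)
  if (config$effect_kind == "global_shift") {
    effect[] <- config$effect_size
  } else {
    candidates <- which(!trendless)
    n_aff <- round(config$affected_fraction * config$n_peptides)
    n_aff <- min(n_aff, length(candidates))
    if (n_aff > 0) {
      aff <- sample(candidates, n_aff)
      up <- aff[seq_len(ceiling(n_aff / 2))]
      down <- setdiff(aff, up)
      effect[up] <- config$effect_size
      effect[down] <- -config$effect_size
    }
  }

  outlier <- rep(FALSE, n_s)
  if (config$n_outlier_samples > 0)
    outlier[sample.int(n_s, min(config$n_outlier_samples, n_s))] <- TRUE

  # latent log2 activity, sample x peptide, then replicate copies
  lat <- outer(ifelse(labels == "responder", 1, 0), effect) +
    matrix(baseline, n_s, config$n_peptides, byrow = TRUE) +
    batch_shift +
    matrix(rnorm(n_s * config$n_peptides, 0, config$noise_sd_log2),
           n_s, config$n_peptides)

  n_rep <- config$n_replicates
  n_cyc <- config$n_cycles
  idx <- expand.grid(cycle = seq_len(n_cyc), replicate_id = seq_len(n_rep),
                     peptide = seq_len(config$n_peptides),
                     sample = seq_len(n_s))
  n_spots <- n_s * config$n_peptides * n_rep
  rep_noise <- rnorm(n_spots, 0, config$replicate_sd_log2)
  spot <- (idx$sample - 1L) * config$n_peptides * n_rep +
    (idx$peptide - 1L) * n_rep + idx$replicate_id
  lat_spot <- lat[cbind(idx$sample, idx$peptide)] + rep_noise[spot]
  amplitude <- ifelse(trendless[idx$peptide], 0, 2 ^ lat_spot)
  amplitude <- amplitude * ifelse(outlier[idx$sample], 0.25, 1)

  n_rows <- nrow(idx)
  bg_level <- pmax(rnorm(n_rows, config$background_mean, config$background_sd), 0)
  foreground <- bg_level + amplitude * idx$cycle / n_cyc +
    rnorm(n_rows, 0, config$cycle_noise_sd)
  background <- pmax(rnorm(n_rows, config$background_mean, config$background_sd), 0)

  tc <- data.frame(sample_id = sample_ids[idx$sample],
                   peptide_id = peptide_ids[idx$peptide],
                   replicate_id = idx$replicate_id,
                   cycle = idx$cycle,
                   foreground = foreground,
                   background = background,
                   stringsAsFactors = FALSE)

  therapy <- if (config$effect_kind == "global_shift") "anti-CTLA-4" else "anti-PD-1"
  responder <- labels == "responder"
  bor <- ifelse(responder,
                c("CR", "PR", "SD")[1 + (seq_len(n_s) %% 3)], "PD")
  sd_dur <- ifelse(bor == "SD", 90 + (seq_len(n_s) * 13) %% 200, NA_real_)
  pfs <- ifelse(responder, 150 + (seq_len(n_s) * 17) %% 400,
                30 + (seq_len(n_s) * 11) %% 100)
  meta <- data.frame(sample_id = sample_ids,
                     cohort_id = "SYN",
                     batch_id = batches,
                     therapy = therapy,
                     anticoagulant = "heparin",
                     bor = bor,
                     sd_duration_days = sd_dur,
                     pfs_days = pfs,
                     progressed = !responder,
                     label = labels,
                     stringsAsFactors = FALSE)
  truth <- data.frame(sample_id = sample_ids, label = labels,
                      batch = batches, is_outlier = outlier,
                      stringsAsFactors = FALSE)
  attr(meta, "truth") <- truth
  list(timecourses = tc, meta = meta)
}

#' Ground-truth table of a generated cohort
#'
#' Exposes the generator's per-sample truth (label, batch, outlier flag) for
#' test assertions. This table is never consumed by the analysis path.
#'
#' @param meta the `meta` element returned by [generate_cohort()].
#' @return `data.frame` with columns `sample_id`, `label`, `batch`,
#'   `is_outlier`.
#' @export
truth_table <- function(meta) {
  truth <- attr(meta, "truth")
  if (is.null(truth))
    stop("metadata does not carry generator ground truth; ",
         "was it produced by generate_cohort()?")
  truth
}
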