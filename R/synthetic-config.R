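#' Configuration for the synthetic cohort generators
#'
#' One config object drives the three generators ([generate_eeg()],
#' [generate_asv_table()], [generate_ffq()]), so the planted High/Low
#' structure is consistent across the EEG, microbiome and diet views of the
#' same simulated cohort. Defaults mirror the study conditions the pipeline
#' targets: a 31-child cohort split 11 High / 20 Low, 19-channel 10-20 EEG
#' at 512 Hz, and ASV tables deep enough for rarefaction to 21,000 reads.
#'
#' @param n_subjects_per_group Named integer vector `c(high = , low = )` of
#'   EEG subjects per intake group (a scalar is recycled to both groups).
#' @param seed Integer seed; identical seeds reproduce identical outputs
#'   bit for bit.
#' @param fs Sampling rate, Hz (> 60 so the 30 Hz beta edge is representable).
#' @param n_channels Number of EEG channels (19, the 10-20 montage).
#' @param duration Recording duration per condition, seconds.
#' @param coupling_high,coupling_low Shared-signal fraction per band within
#'   each group, in `[0, 1]`; the knob that plants larger inter-ROI
#'   dependence in the high group when `coupling_high > coupling_low`.
#' @param n_samples,n_samples_high Total microbiome/FFQ cohort size and how
#'   many of them are High-intake (defaults 31 and 11).
#' @param n_asvs Number of ASVs in the synthetic table.
#' @param cooccur_strength_high,cooccur_strength_low Probability in
#'   `[0, 1]` that an ASV's presence tracks its sample's latent community
#'   state, per group; drives presence-absence co-occurrence.
#' @param depth Reads per sample in the generated table.
#' @param min_depth Rarefaction target the table must support (default
#'   21000).
#' @param intake_mean_high,intake_mean_low,intake_sd Planted monthly protein
#'   intake levels and spread, grams/month.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_subjects_per_group = c(high = 11, low = 20),
                             seed = 1,
                             fs = 512,
                             n_channels = 19,
                             duration = 60,
                             coupling_high = 0.8,
                             coupling_low = 0.1,
                             n_samples = 31,
                             n_samples_high = 11,
                             n_asvs = 80,
                             cooccur_strength_high = 0.9,
                             cooccur_strength_low = 0.1,
                             depth = 25000,
                             min_depth = 21000,
                             intake_mean_high = 407.48,
                             intake_mean_low = 211.94,
                             intake_sd = 40) {
  if (length(n_subjects_per_group) == 1L) {
    n_subjects_per_group <- c(high = n_subjects_per_group,
                              low = n_subjects_per_group)
  }
  if (is.null(names(n_subjects_per_group))) {
    names(n_subjects_per_group) <- c("high", "low")
  }
  cfg <- list(
    n_subjects_per_group = n_subjects_per_group, seed = as.integer(seed),
    fs = fs, n_channels = n_channels, duration = duration,
    coupling_high = coupling_high, coupling_low = coupling_low,
    n_samples = n_samples, n_samples_high = n_samples_high,
    n_asvs = n_asvs,
    cooccur_strength_high = cooccur_strength_high,
    cooccur_strength_low = cooccur_strength_low,
    depth = depth, min_depth = min_depth,
    intake_mean_high = intake_mean_high,
    intake_mean_low = intake_mean_low,
    intake_sd = intake_sd
  )
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  assert_scalar_number(cfg$fs, "fs", positive = TRUE)
  assert_scalar_number(cfg$duration, "duration", positive = TRUE)
  if (cfg$fs <= 2 * 30) {
    gbm_abort("`fs` must exceed twice the 30 Hz beta edge.",
              "gbm_invalid_config")
  }
  for (nm in c("coupling_high", "coupling_low",
               "cooccur_strength_high", "cooccur_strength_low")) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || v < 0 || v > 1) {
      gbm_abort(sprintf("`%s` must lie in [0, 1].", nm), "gbm_invalid_config")
    }
  }
  if (cfg$n_asvs < 2) gbm_abort("`n_asvs` must be >= 2.", "gbm_invalid_config")
  if (cfg$n_samples < 4) {
    gbm_abort("`n_samples` must be >= 4.", "gbm_invalid_config")
  }
  if (cfg$n_samples_high >= cfg$n_samples || cfg$n_samples_high < 2) {
    gbm_abort("`n_samples_high` must leave both groups nonempty (>= 2 each).",
              "gbm_invalid_config")
  }
  if (cfg$depth < cfg$min_depth) {
    gbm_abort("`depth` is below the rarefaction target `min_depth`.",
              "gbm_invalid_config")
  }
  if (any(cfg$n_subjects_per_group < 2)) {
    gbm_abort("Need at least 2 EEG subjects per group.", "gbm_invalid_config")
  }
  invisible(cfg)
}
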