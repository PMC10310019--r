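# band-limited unit-variance noise: white noise filtered into [low, high]
band_noise <- function(n, fs, low, high) {
  bf <- signal::butter(4, c(low, high) / (fs / 2), type = "pass")
  x <- signal::filtfilt(bf, stats::rnorm(n))
  x / stats::sd(x)
}

#' Generate synthetic resting-state EEG with planted group coupling
#'
#' Emulates per-group 19-channel resting-state recordings in which each
#' classic broad band carries band-limited noise. Two mechanisms create
#' dependence: (i) within a subject, channels of the same ROI share a common
#' band-limited series (fixed mixing 0.7), and ROIs share a subject-level
#' latent series mixed in with fraction `coupling`; (ii) across subjects,
#' each band's log-amplitude has a component shared between ROIs with the
#' same fraction `coupling`, so the expected across-subject dependence of
#' ROI band powers - what the MI network measures - is strictly larger in
#' the group with the larger coupling.
#'
#' @param config A [synthetic_config()].
#' @param conditions Eye conditions to simulate (default both).
#' @return A list with `recordings` (list of [eeg_recording()]) and
#'   `manifest` (tibble: `subject_id`, `group`, `condition`, `fs`).
#' @export
generate_eeg <- function(config,
                         conditions = c("open_eyes", "closed_eyes")) {
  validate_synthetic_config(config)
  bands <- eeg_bands()
  roi_spec <- default_roi_spec()
  channels <- montage_1020()
  n_samp <- as.integer(round(config$duration * config$fs))
  n_high <- config$n_subjects_per_group[["high"]]
  n_low <- config$n_subjects_per_group[["low"]]
  groups <- rep(c("H", "L"), c(n_high, n_low))
  ids <- sprintf("S%02d", seq_along(groups))
  sigma_amp <- 0.5  # across-subject log-amplitude spread per band
  kappa <- 0.7      # within-ROI channel coherence

  roi_of <- stats::setNames(as.character(roi_spec$roi), roi_spec$electrode)
  recordings <- with_seed(config$seed, {
    out <- list()
    for (s in seq_along(ids)) {
      coupling <- if (groups[s] == "H") config$coupling_high else config$coupling_low
      for (cond in conditions) {
        data <- matrix(0, nrow = length(channels), ncol = n_samp,
                       dimnames = list(channels, NULL))
        for (b in seq_len(nrow(bands))) {
          lo <- bands$low[b]; hi <- bands$high[b]
          shared_series <- band_noise(n_samp, config$fs, lo, hi)
          z_shared <- stats::rnorm(1)
          roi_series <- list(); roi_amp <- list()
          for (r in unique(roi_of)) {
            roi_series[[r]] <- sqrt(coupling) * shared_series +
              sqrt(1 - coupling) * band_noise(n_samp, config$fs, lo, hi)
            roi_amp[[r]] <- exp(sigma_amp * (sqrt(coupling) * z_shared +
                                               sqrt(1 - coupling) * stats::rnorm(1)))
          }
          for (ch in channels) {
            r <- roi_of[ch]
            if (is.na(r)) {
              # channels outside the five ROIs: independent content
              data[ch, ] <- data[ch, ] +
                exp(sigma_amp * stats::rnorm(1)) *
                band_noise(n_samp, config$fs, lo, hi)
            } else {
              data[ch, ] <- data[ch, ] + roi_amp[[r]] *
                (sqrt(kappa) * roi_series[[r]] +
                   sqrt(1 - kappa) * band_noise(n_samp, config$fs, lo, hi))
            }
          }
        }
        out[[length(out) + 1L]] <- eeg_recording(
          data, fs = config$fs, channels = channels,
          subject_id = ids[s], condition = cond)
      }
    }
    out
  })
  manifest <- purrr::map_dfr(recordings, function(r) {
    tibble::tibble(subject_id = r$subject_id,
                   group = groups[match(r$subject_id, ids)],
                   condition = r$condition, fs = r$fs)
  })
  list(recordings = recordings, manifest = manifest)
}
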