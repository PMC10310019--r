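#' Construct an EEG recording object
#'
#' @param data Channels x samples numeric matrix (microvolts).
#' @param fs Sampling rate in Hz (> 60 so all broad bands are representable).
#' @param channels Channel names in 10-20 order (19 expected).
#' @param subject_id Subject identifier.
#' @param condition `"open_eyes"` or `"closed_eyes"`.
#' @return An `eeg_recording` object.
#' @export
eeg_recording <- function(data, fs, channels = montage_1020(),
                          subject_id = NA_character_,
                          condition = c("open_eyes", "closed_eyes")) {
  condition <- match.arg(condition)
  if (!is.matrix(data) || !is.numeric(data)) {
    gbm_abort("`data` must be a numeric channels x samples matrix.",
              "gbm_validation")
  }
  if (length(channels) != nrow(data)) {
    gbm_abort("`channels` must name every row of `data`.", "gbm_validation")
  }
  if (length(channels) != 19L) {
    gbm_abort("Expected the 19-channel 10-20 montage.", "gbm_validation")
  }
  assert_scalar_number(fs, "fs", positive = TRUE)
  if (fs <= 60) gbm_abort("`fs` must exceed 60 Hz.", "gbm_validation")
  if (anyNA(data) || any(!is.finite(data))) {
    gbm_abort("`data` must be finite.", "gbm_validation")
  }
  rownames(data) <- channels
  structure(list(subject_id = subject_id, condition = condition, fs = fs,
                 channels = channels, data = data),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording %s/%s: %d ch x %d samples @ %g Hz>\n",
              x$subject_id, x$condition, nrow(x$data), ncol(x$data), x$fs))
  invisible(x)
}

#' Zero-phase band-pass filter
#'
#' 4th-order Butterworth applied forwards and backwards
#' (`signal::filtfilt`), so the pass band is preserved with zero phase shift
#' and stop-band attenuation is doubled (about 48 dB one octave outside the
#' band).
#'
#' @param recording An [eeg_recording()].
#' @param low,high Band edges in Hz; defaults 1 and 40.
#' @param order Butterworth order per pass (default 4).
#' @return The filtered recording.
#' @export
bandpass <- function(recording, low = 1, high = 40, order = 4) {
  fs <- recording$fs
  if (!(low > 0 && low < high && high < fs / 2)) {
    gbm_abort("Require 0 < low < high < fs/2.", "gbm_validation")
  }
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  recording$data <- t(apply(recording$data, 1,
                            function(ch) signal::filtfilt(bf, ch)))
  rownames(recording$data) <- recording$channels
  recording
}

#' Split a recording into epochs and reject variance outliers
#'
#' The signal is cut into fixed-length non-overlapping epochs. For every
#' channel, the per-epoch variance is standardised across epochs; an epoch
#' is rejected when any channel's variance z-score exceeds the threshold
#' (one-sided: artifacts inflate variance). A warning is raised when fewer
#' than `min_clean_seconds` of clean data remain.
#'
#' @param recording An [eeg_recording()].
#' @param epoch_seconds Epoch length in seconds (default 2).
#' @param variance_z_threshold Rejection threshold on the variance z-score
#'   (default 3; `Inf` retains everything).
#' @param min_clean_seconds Minimum retained duration before a warning
#'   (default 39 s).
#' @return An `eeg_epochs` object: list with `epochs` (list of channels x
#'   samples matrices), `fs`, `channels`, and `log` (per-epoch tibble with
#'   `epoch`, `max_z`, `retained`).
#' @export
epoch_and_reject <- function(recording, epoch_seconds = 2,
                             variance_z_threshold = 3,
                             min_clean_seconds = 39) {
  fs <- recording$fs
  len <- as.integer(round(epoch_seconds * fs))
  n_epochs <- floor(ncol(recording$data) / len)
  if (n_epochs < 1L) {
    gbm_abort("Recording shorter than one epoch.", "gbm_validation")
  }
  epochs <- lapply(seq_len(n_epochs), function(e) {
    recording$data[, seq((e - 1L) * len + 1L, e * len), drop = FALSE]
  })
  # channels x epochs variance matrix
  v <- vapply(epochs, function(ep) apply(ep, 1, stats::var),
              numeric(nrow(recording$data)))
  v <- matrix(v, nrow = nrow(recording$data))
  mu <- rowMeans(v)
  sdv <- apply(v, 1, stats::sd)
  z <- (v - mu) / ifelse(sdv > 0, sdv, 1)
  max_z <- apply(z, 2, max)
  retained <- !(max_z > variance_z_threshold)
  retained[is.na(retained)] <- TRUE
  if (!any(retained)) {
    gbm_abort("All epochs rejected by the variance criterion.",
              "gbm_empty_result")
  }
  clean_s <- sum(retained) * epoch_seconds
  if (clean_s < min_clean_seconds) {
    warning(sprintf("Only %.1f s of clean data retained (target %.0f s).",
                    clean_s, min_clean_seconds), call. = FALSE)
  }
  structure(list(
    epochs = epochs[retained],
    fs = fs,
    channels = recording$channels,
    log = tibble::tibble(epoch = seq_len(n_epochs), max_z = max_z,
                         retained = retained)
  ), class = "eeg_epochs")
}

# Hann-tapered periodogram of one epoch, normalised so the bin powers sum
# to (approximately) the signal variance; returns power per bin per channel
epoch_periodogram <- function(ep, fs) {
  n <- ncol(ep)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / n)
  xw <- (ep - rowMeans(ep)) * rep(w, each = nrow(ep))
  ft <- t(apply(xw, 1, stats::fft))
  p <- Mod(ft)^2 / (n * sum(w^2))
  freq_fold <- pmin((seq_len(n) - 1) * fs / n, fs - (seq_len(n) - 1) * fs / n)
  list(power = p, freq = freq_fold)
}

#' Absolute band power per channel
#'
#' For each retained epoch, a Hann-tapered periodogram is computed per
#' channel and power is summed over the frequency bins whose centre lies in
#' each band (edges inclusive); the per-epoch values are then averaged.
#' Powers are absolute (microvolt-squared), not relative.
#'
#' @param epochs An `eeg_epochs` object from [epoch_and_reject()].
#' @param bands Band definition tibble (default [eeg_bands()]).
#' @return A tibble with columns `channel`, `band`, `power`.
#' @export
band_power <- function(epochs, bands = eeg_bands()) {
  if (length(epochs$epochs) == 0L) {
    gbm_abort("No epochs to analyse.", "gbm_validation")
  }
  if (any(bands$high >= epochs$fs / 2)) {
    gbm_abort("Band edge at or above Nyquist frequency.", "gbm_validation")
  }
  acc <- matrix(0, nrow = length(epochs$channels), ncol = nrow(bands))
  for (ep in epochs$epochs) {
    pg <- epoch_periodogram(ep, epochs$fs)
    for (b in seq_len(nrow(bands))) {
      sel <- pg$freq >= bands$low[b] & pg$freq <= bands$high[b]
      acc[, b] <- acc[, b] + rowSums(pg$power[, sel, drop = FALSE])
    }
  }
  acc <- acc / length(epochs$epochs)
  tibble::tibble(
    channel = rep(epochs$channels, times = nrow(bands)),
    band = rep(bands$band, each = length(epochs$channels)),
    power = as.vector(acc)
  )
}

#' ROI log absolute power
#'
#' Averages the absolute power of each ROI's three electrodes, then takes
#' the natural log.
#'
#' @param channel_band_power Tibble from [band_power()] (columns `channel`,
#'   `band`, `power`).
#' @param roi_spec ROI definition (default [default_roi_spec()]).
#' @return A tibble with columns `roi`, `band`, `log_power`.
#' @export
roi_log_power <- function(channel_band_power, roi_spec = default_roi_spec()) {
  validate_roi_spec(roi_spec, channels = unique(c(
    as.character(roi_spec$electrode), unique(channel_band_power$channel))))
  missing <- setdiff(roi_spec$electrode, channel_band_power$channel)
  if (length(missing) > 0) {
    gbm_abort(sprintf("Missing electrode(s): %s",
                      paste(missing, collapse = ", ")),
              "gbm_validation")
  }
  roi_spec |>
    dplyr::left_join(channel_band_power, by = c(electrode = "channel"),
                     relationship = "many-to-many") |>
    dplyr::group_by(.data$roi, .data$band) |>
    dplyr::summarise(log_power = log(mean(.data$power)), .groups = "drop")
}

#' Tidy band-power table for a set of recordings
#'
#' Runs the full qEEG chain (band-pass 1-40 Hz, epoching with variance-based
#' rejection, Hann periodogram band power, ROI averaging, natural log) for
#' every recording and stacks the results.
#'
#' @param recordings List of [eeg_recording()] objects.
#' @param bands,roi_spec Band and ROI definitions.
#' @param low,high Filter band edges (Hz).
#' @param epoch_seconds,variance_z_threshold,min_clean_seconds Passed to
#'   [epoch_and_reject()].
#' @return A tibble with columns `subject_id`, `condition`, `roi`, `band`,
#'   `log_power` (the BandPowerTable).
#' @export
bandpower_table <- function(recordings, bands = eeg_bands(),
                            roi_spec = default_roi_spec(),
                            low = 1, high = 40, epoch_seconds = 2,
                            variance_z_threshold = 3,
                            min_clean_seconds = 39) {
  purrr::map_dfr(recordings, function(rec) {
    rec |>
      bandpass(low = low, high = high) |>
      epoch_and_reject(epoch_seconds = epoch_seconds,
                       variance_z_threshold = variance_z_threshold,
                       min_clean_seconds = min_clean_seconds) |>
      band_power(bands = bands) |>
      roi_log_power(roi_spec = roi_spec) |>
      dplyr::mutate(subject_id = rec$subject_id, condition = rec$condition,
                    .before = 1)
  })
}
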