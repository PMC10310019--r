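#' Classic qEEG broad bands
#'
#' The four broad frequency bands used throughout the brain-cortex-activity
#' pipeline: Delta (1-3 Hz), Theta (4-7 Hz), Alpha (8-14 Hz) and
#' Beta (15-30 Hz).
#'
#' @return A tibble with columns `band`, `low` and `high` (Hz).
#' @export
#' @examples
#' eeg_bands()
eeg_bands <- function() {
  tibble::tibble(
    band = factor(c("delta", "theta", "alpha", "beta"),
                  levels = c("delta", "theta", "alpha", "beta")),
    low  = c(1, 4, 8, 15),
    high = c(3, 7, 14, 30)
  )
}

#' 10-20 montage channels used by the pipeline
#'
#' @return Character vector of the 19 electrode names, in montage order.
#' @export
montage_1020 <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "T7", "C3", "Cz", "C4", "T8",
    "P7", "P3", "Pz", "P4", "P8", "O1", "O2")
}

#' Default region-of-interest specification
#'
#' Five ROIs of three electrodes each: left/right anterior, left/right
#' posterior and midline. ROI band power is the arithmetic mean of its three
#' electrodes' absolute power.
#'
#' @return A tibble with columns `roi` and `electrode` (15 rows).
#' @export
#' @examples
#' default_roi_spec()
default_roi_spec <- function() {
  tibble::tibble(
    roi = factor(rep(c("left_anterior", "right_anterior",
                       "left_posterior", "right_posterior", "midline"),
                     each = 3),
                 levels = c("left_anterior", "right_anterior",
                            "left_posterior", "right_posterior", "midline")),
    electrode = c("Fp1", "F3", "F7",
                  "Fp2", "F4", "F8",
                  "P3", "T7", "O1",
                  "P4", "T8", "O2",
                  "Fz", "Cz", "Pz")
  )
}

validate_roi_spec <- function(roi_spec, channels = montage_1020()) {
  if (!all(c("roi", "electrode") %in% names(roi_spec))) {
    gbm_abort("`roi_spec` needs columns `roi` and `electrode`.",
              "gbm_validation")
  }
  counts <- table(roi_spec$roi)
  if (length(counts) != 5L || any(counts != 3L)) {
    gbm_abort("`roi_spec` must define exactly 5 ROIs of 3 electrodes each.",
              "gbm_validation")
  }
  missing <- setdiff(roi_spec$electrode, channels)
  if (length(missing) > 0) {
    gbm_abort(sprintf("ROI electrodes not in the montage: %s",
                      paste(missing, collapse = ", ")),
              "gbm_validation")
  }
  invisible(roi_spec)
}
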