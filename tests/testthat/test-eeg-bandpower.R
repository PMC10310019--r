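test_that("band-pass keeps pass-band tones and kills stop-band tones", {
  fs <- 200
  t <- seq(0, 10, by = 1 / fs)[-1]
  rms <- function(x) sqrt(mean(x^2))

  tone <- function(f) make_recording(length(t), fs = fs,
                                     fill = function(ch, n) sin(2 * pi * f * t))
  in10 <- tone(10); out50 <- tone(50)
  f10 <- bandpass(in10, 1, 40)
  f50 <- bandpass(out50, 1, 40)
  # drop filter edge transients before measuring
  keep <- seq(fs, length(t) - fs)
  expect_lt(abs(rms(f10$data[1, keep]) / rms(in10$data[1, keep]) - 1), 0.05)
  expect_lt(rms(f50$data[1, keep]) / rms(out50$data[1, keep]), 0.10)

  expect_error(bandpass(in10, 0, 40), class = "gbm_validation")
  expect_error(bandpass(in10, 1, 150), class = "gbm_validation")
})

test_that("filtered white noise keeps a flat in-band spectrum", {
  set.seed(21)
  fs <- 128
  rec <- make_recording(fs * 60, fs = fs)
  filt <- bandpass(rec, 1, 40)
  # independent check: plain FFT periodogram of the filtered channel
  x <- filt$data[1, ]
  p <- Mod(stats::fft(x))^2 / length(x)
  freq <- (seq_along(x) - 1) * fs / length(x)
  band_mean <- function(lo, hi) mean(p[freq >= lo & freq <= hi])
  # mean spectral density similar across thirds of the pass band
  thirds <- c(band_mean(5, 15), band_mean(15, 25), band_mean(25, 35))
  expect_lt(max(thirds) / min(thirds), 1.5)
})

test_that("variance-based rejection drops injected artifact epochs", {
  set.seed(22)
  fs <- 128
  rec <- make_recording(fs * 60, fs = fs)

  spoiled <- rec
  idx <- seq(10 * fs + 1, 12 * fs)  # epoch 6 under 2-s epochs
  spoiled$data[3, idx] <- spoiled$data[3, idx] * 10
  ep <- epoch_and_reject(spoiled, epoch_seconds = 2, variance_z_threshold = 3,
                         min_clean_seconds = 39)
  expect_false(ep$log$retained[6])

  # clean stationary noise: >= 95% of epochs survive
  clean <- epoch_and_reject(rec, epoch_seconds = 2, variance_z_threshold = 3,
                            min_clean_seconds = 39)
  expect_gte(mean(clean$log$retained), 0.95)

  # infinite threshold retains everything
  all_in <- epoch_and_reject(rec, epoch_seconds = 2,
                             variance_z_threshold = Inf)
  expect_true(all(all_in$log$retained))

  # a short recording triggers the clean-duration warning
  short <- make_recording(fs * 10, fs = fs)
  expect_warning(epoch_and_reject(short, epoch_seconds = 2,
                                  variance_z_threshold = Inf),
                 regexp = "clean data")

  expect_error(epoch_and_reject(rec, epoch_seconds = 2,
                                variance_z_threshold = -10),
               class = "gbm_empty_result")
})

test_that("band power concentrates a 10 Hz tone in alpha and obeys Parseval", {
  fs <- 128
  t <- seq_len(fs * 40) / fs
  tone <- make_recording(length(t), fs = fs,
                         fill = function(ch, n) sin(2 * pi * 10 * t))
  ep <- epoch_and_reject(tone, epoch_seconds = 2, variance_z_threshold = Inf,
                         min_clean_seconds = 0)
  bp <- band_power(ep)
  ch1 <- bp[bp$channel == "Fp1", ]
  expect_gte(ch1$power[ch1$band == "alpha"] / sum(ch1$power), 0.95)

  # contiguous bands tiling the spectrum recover the signal variance
  set.seed(23)
  noise <- make_recording(fs * 60, fs = fs)
  epn <- epoch_and_reject(noise, epoch_seconds = 2,
                          variance_z_threshold = Inf, min_clean_seconds = 0)
  tiling <- tibble::tibble(band = c("lo", "hi"),
                           low = c(0, 31.76), high = c(31.75, 63.75))
  bpn <- band_power(epn, bands = tiling)
  total <- sum(bpn$power[bpn$channel == "Fp1"])
  expect_lt(abs(total / stats::var(noise$data[1, ]) - 1), 0.02)

  # white noise: power proportional to the number of in-band bins
  classic <- band_power(epn)
  chn <- classic[classic$channel == "O1", ]
  # bin spacing 0.5 Hz at 2-s epochs; count folded bins inside each band
  n_bins <- function(lo, hi) sum(seq(0, fs / 2, by = 0.5) >= lo &
                                   seq(0, fs / 2, by = 0.5) <= hi) * 2
  ratio <- (chn$power[chn$band == "beta"] / chn$power[chn$band == "delta"]) /
    (n_bins(15, 30) / n_bins(1, 3))
  expect_lt(abs(ratio - 1), 0.35)

  expect_error(band_power(ep, bands = tibble::tibble(band = "x", low = 1,
                                                     high = 80)),
               class = "gbm_validation")
})

test_that("ROI log power is the log of the three-electrode mean", {
  cbp <- tidyr::expand_grid(channel = montage_1020(),
                            band = factor("alpha"))
  cbp$power <- 1
  cbp$power[cbp$channel == "Fp1"] <- 1
  cbp$power[cbp$channel == "F3"] <- 2
  cbp$power[cbp$channel == "F7"] <- 3
  roi <- roi_log_power(cbp)
  expect_equal(roi$log_power[roi$roi == "left_anterior"], log(2))
  expect_equal(roi$log_power[roi$roi == "midline"], log(1))

  # permuting electrode rows changes nothing
  roi2 <- roi_log_power(cbp[sample(nrow(cbp)), ])
  expect_equal(roi2$log_power, roi$log_power)

  expect_error(roi_log_power(cbp[cbp$channel != "Cz", ]),
               class = "gbm_validation", regexp = "Cz")
})

test_that("scaling the raw signal shifts log power by 2 log c", {
  set.seed(24)
  fs <- 128
  rec <- make_recording(fs * 30, fs = fs)
  scaled <- rec
  scaled$data <- 3 * scaled$data
  chain <- function(r) {
    r |>
      bandpass() |>
      epoch_and_reject(variance_z_threshold = Inf, min_clean_seconds = 0) |>
      band_power() |>
      roi_log_power()
  }
  expect_equal(chain(scaled)$log_power, chain(rec)$log_power + 2 * log(3),
               tolerance = 1e-8)
})
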