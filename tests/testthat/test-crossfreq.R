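srate <- 500
tone_component <- function(freq, duration = 4, amp = 1, band = c(8, 14)) {
  t <- (seq_len(duration * srate) - 1) / srate
  component(amp * cos(2 * pi * freq * t), srate, band)
}

test_that("spectrogram localizes tones on the 0.1-Hz grid", {
  fr <- spectrogram_highres(tone_component(10))
  peaks <- fr$freqs[apply(fr$amplitude, 1, which.max)]
  expect_true(all(abs(peaks - 10) < 1e-9))
  # off-grid tone quantizes to a neighboring bin
  fr2 <- spectrogram_highres(tone_component(10.05))
  peaks2 <- fr2$freqs[apply(fr2$amplitude, 1, which.max)]
  expect_true(all(peaks2 %in% c(10.0, 10.1)))
  # frame arithmetic: (4 - 1)/0.1 + 1 = 31 frames, centers 0.5..3.5 s
  expect_equal(nrow(fr$amplitude), 31)
  expect_equal(range(fr$times), c(0.5, 3.5))
  expect_equal(fr$freqs[2] - fr$freqs[1], 0.1)
  expect_error(spectrogram_highres(component(rnorm(300), srate, c(8, 14))),
               "shorter")
})

test_that("aperiodic trend fit is exact on a pure power law", {
  freqs <- seq(1, 30, 0.1)
  a <- 3.7
  fake <- structure(list(amplitude = matrix(a / freqs, 1), freqs = freqs),
                    class = "oc_frames")
  tr <- fit_aperiodic_trend(fake)
  expect_equal(tr$slope, -1, tolerance = 1e-10)
  expect_equal(tr$intercept, log10(a), tolerance = 1e-10)
  expect_equal(predict(tr, 10), a / 10, tolerance = 1e-8)
  # white-noise amplitude spectrum: slope ~ 0
  set.seed(7)
  wn <- component(matrix(rnorm(20 * 4 * srate), nrow = 20), srate, c(8, 14))
  trw <- fit_aperiodic_trend(spectrogram_highres(wn))
  expect_lt(abs(trw$slope), 0.05)
  # robustness: one narrow peak barely moves the fit
  peaky <- fake
  peaky$amplitude[1, freqs >= 10 & freqs <= 10.4] <-
    peaky$amplitude[1, freqs >= 10 & freqs <= 10.4] + 2
  trp <- fit_aperiodic_trend(peaky)
  expect_lt(abs(trp$slope - tr$slope) / abs(tr$slope), 0.1)
})

test_that("band peak detection respects the trend gate and tie rules", {
  freqs <- seq(1, 30, 0.1)
  trend <- structure(list(slope = 0, intercept = 0), class = "oc_trend")
  # trend amplitude = 1 everywhere; single dominant peak at 12
  amp <- rep(0.5, length(freqs))
  amp[freqs == 12] <- 3
  expect_equal(detect_band_peak(amp, freqs, c(8, 14), trend), 12)
  # two suprathreshold peaks: larger amplitude wins
  amp[freqs == 13] <- 2
  expect_equal(detect_band_peak(amp, freqs, c(8, 14), trend), 12)
  # equal-amplitude peaks: tie broken toward the lower frequency
  amp[freqs == 13] <- 3
  expect_equal(detect_band_peak(amp, freqs, c(8, 14), trend), 12)
  # everything below trend: none
  expect_true(is.na(detect_band_peak(rep(0.5, length(freqs)), freqs,
                                     c(8, 14), trend)))
  # uniform rescaling of frame and trend together leaves detection invariant
  trend10 <- structure(list(slope = 0, intercept = 1), class = "oc_trend")
  expect_equal(detect_band_peak(amp * 10, freqs, c(8, 14), trend10), 12)
})

test_that("noise-only detection rate matches a Monte Carlo replicate", {
  # trend-only (1/f) frames: rate is reproducible across independent draws
  # and far below the planted-peak rate
  rate_for <- function(seed) {
    x <- matrix(generate_pink_noise(20 * 4 * srate, 1, srate, seed = seed),
                nrow = 20)
    cmp <- component(x, srate, c(8, 14))
    fr <- spectrogram_highres(cmp)
    pk <- detect_band_peaks(fr, c(8, 14), fit_aperiodic_trend(fr))
    mean(!is.na(pk))
  }
  r1 <- rate_for(42)
  r2 <- rate_for(43) # independent Monte Carlo oracle
  expect_lt(abs(r1 - r2), 0.1)
  fr_tone <- spectrogram_highres(tone_component(11, amp = 5))
  x <- matrix(generate_pink_noise(20 * 4 * srate, 1, srate, seed = 44),
              nrow = 20)
  trend <- fit_aperiodic_trend(spectrogram_highres(component(x, srate,
                                                             c(8, 14))))
  pk_tone <- detect_band_peaks(fr_tone, c(8, 14), trend)
  expect_equal(mean(!is.na(pk_tone)), 1)
  expect_lt(r1, 0.95)
})

test_that("ratio occurrence bins fixed harmonic ratios exactly", {
  occ <- ratio_occurrence(rep(12, 50), rep(6, 50))
  expect_equal(occ$percent[occ$ratio_bin == 2.0], 100)
  expect_equal(sum(occ$percent), 100)
  occ2 <- ratio_occurrence(rep(10, 8), rep(4, 8))
  expect_equal(occ2$percent[occ2$ratio_bin == 2.5], 100)
  # rounding is half-away-from-zero: 10/8 = 1.25 -> bin 1.3 (not 1.2)
  occ3 <- ratio_occurrence(rep(10, 4), rep(8, 4))
  expect_equal(occ3$percent[occ3$ratio_bin == 1.3], 100)
  # no valid frames: all-zero percentages, not an error
  occ4 <- ratio_occurrence(c(NA, 12), c(6, NA))
  expect_true(all(occ4$percent == 0))
  expect_equal(attr(occ4, "n_frames_with_ratio"), 0)
  # out-of-range ratios are discarded
  occ5 <- ratio_occurrence(c(12, 29), c(6, 5))
  expect_equal(attr(occ5, "n_frames_with_ratio"), 1)
  expect_equal(sum(occ5$percent), 100)
})

test_that("per-bin condition comparison controls the null and flags degeneracy", {
  # identical conditions: p = 1 everywhere, nothing significant
  bins <- seq(1, 3.5, 0.1)
  base <- tidyr::expand_grid(subject = 1:6, ratio_bin = bins)
  set.seed(9)
  base$pct <- runif(nrow(base), 0, 10)
  occ <- dplyr::bind_rows(
    dplyr::mutate(base, condition = "fixation", percent = pct),
    dplyr::mutate(base, condition = "delay", percent = pct)
  )
  res <- compare_ratio_bins(occ)
  expect_false(any(res$significant))
  expect_true(all(res$degenerate))
  # a real shift in one bin is detected
  occ2 <- occ
  shift <- occ2$condition == "delay" & occ2$ratio_bin == 2.0
  set.seed(10)
  occ2$percent[shift] <- occ2$percent[shift] + 20 + rnorm(sum(shift), 0, 0.5)
  res2 <- compare_ratio_bins(occ2)
  expect_true(res2$significant[res2$ratio_bin == 2.0])
  expect_equal(sum(res2$significant), 1)
})
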