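#' High-resolution short-time Fourier transform of a component
#'
#' 1-s Hamming windows stepped by 0.1 s (90% overlap), zero-padded to a
#' 0.1-Hz frequency grid between `fmin` and `fmax`; zero-padding (rather
#' than longer windows) realizes the fine grid while preserving the 1-s
#' temporal resolution. Amplitude is the magnitude spectrum.
#'
#' @param comp An `oc_component` (trials x samples).
#' @param window_s STFT window length, s.
#' @param hop_s Hop between frame centers, s.
#' @param fmin,fmax Frequency range, Hz.
#' @param df Frequency grid spacing, Hz.
#' @return An object of class `oc_frames`: `amplitude`
#'   (frames x frequencies), `freqs`, `times` (frame centers, s, per
#'   trial), `trial` and `condition` per frame.
#' @export
spectrogram_highres <- function(comp, window_s = 1, hop_s = 0.1,
                                fmin = 1, fmax = 30, df = 0.1) {
  srate <- comp$srate
  win <- round(window_s * srate)
  hop <- max(1L, round(hop_s * srate))
  n <- ncol(comp$series)
  if (n < win) abort("Trial shorter than the STFT window.")
  nfft <- round(srate / df)
  freqs <- seq(fmin, fmax, by = df)
  f_idx <- round(freqs / df) + 1L
  wvec <- signal::hamming(win)
  starts <- seq(1L, n - win + 1L, by = hop)
  n_frames <- length(starts)
  n_trials <- nrow(comp$series)

  amp <- matrix(0, n_trials * n_frames, length(freqs))
  times <- numeric(n_trials * n_frames)
  trial <- integer(n_trials * n_frames)
  segs <- matrix(0, nfft, n_frames)
  seg_idx <- outer(0:(win - 1L), starts, `+`)
  for (tr in seq_len(n_trials)) {
    segs[seq_len(win), ] <- matrix(comp$series[tr, seg_idx], win) * wvec
    sp <- stats::mvfft(segs)
    rows <- (tr - 1L) * n_frames + seq_len(n_frames)
    amp[rows, ] <- t(Mod(sp[f_idx, , drop = FALSE]))
    times[rows] <- (starts - 1L + win / 2) / srate
    trial[rows] <- tr
  }
  structure(list(
    amplitude = amp, freqs = freqs, times = times, trial = trial,
    condition = comp$condition[trial], srate = srate,
    label = comp$label
  ), class = "oc_frames")
}

#' @export
print.oc_frames <- function(x, ...) {
  cat(sprintf("<oc_frames> %d frames x %d freqs (%g-%g Hz @ %g Hz)\n",
              nrow(x$amplitude), length(x$freqs), min(x$freqs), max(x$freqs),
              x$freqs[2] - x$freqs[1]))
  invisible(x)
}

#' Aperiodic (1/f) spectral trend
#'
#' Ordinary least squares on `log10(frequency)` vs `log10(mean amplitude)`
#' of the spectrum pooled across all supplied frames (both conditions), one
#' trend per component. Non-positive bins are excluded with a warning.
#'
#' @param frames An `oc_frames` object or a list of them (e.g. one per
#'   condition).
#' @return An object of class `oc_trend` with `slope`, `intercept`
#'   (log10 amplitude at 1 Hz) and the pooled mean spectrum.
#' @export
fit_aperiodic_trend <- function(frames) {
  if (inherits(frames, "oc_frames")) frames <- list(frames)
  freqs <- frames[[1]]$freqs
  tot <- numeric(length(freqs))
  n <- 0L
  for (fr in frames) {
    if (!identical(fr$freqs, freqs)) abort("Frames share one frequency grid.")
    tot <- tot + colSums(fr$amplitude)
    n <- n + nrow(fr$amplitude)
  }
  mean_amp <- tot / n
  keep <- mean_amp > 0 & freqs > 0
  if (!all(keep)) warn("Non-positive spectral bins excluded from the 1/f fit.")
  fit <- lm(log10(mean_amp[keep]) ~ log10(freqs[keep]))
  structure(list(
    slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
    freqs = freqs, mean_amplitude = mean_amp
  ), class = "oc_trend")
}

#' Evaluate an aperiodic trend at given frequencies
#' @param object An `oc_trend`.
#' @param freq Frequencies, Hz.
#' @param ... Unused.
#' @return Trend amplitude at `freq`.
#' @export
predict.oc_trend <- function(object, freq, ...) {
  10^(object$intercept + object$slope * log10(freq))
}

#' @export
print.oc_trend <- function(x, ...) {
  cat(sprintf("<oc_trend> log-log slope %.3f, intercept %.3f\n",
              x$slope, x$intercept))
  invisible(x)
}

# one frame: highest suprathreshold local maximum strictly inside the band;
# ties broken toward lower frequency. Returns Hz or NA.
peak_in_band <- function(amp, freqs, band, thr) {
  idx <- which(freqs > band[1] & freqs < band[2])
  idx <- idx[idx > 1 & idx < length(freqs)]
  if (length(idx) == 0) return(NA_real_)
  is_max <- amp[idx] > amp[idx - 1L] & amp[idx] >= amp[idx + 1L]
  cand <- idx[is_max & amp[idx] > thr[idx]]
  if (length(cand) == 0) return(NA_real_)
  freqs[cand[which.max(amp[cand])]]
}

#' Detect transient band-limited spectral peaks above the 1/f trend
#'
#' For each STFT frame, finds local maxima strictly inside the band,
#' discards those at or below the aperiodic trend, and returns the
#' frequency of the largest surviving peak (ties go to the lower
#' frequency); `NA` when no peak survives — absence is a valid outcome.
#'
#' @param frames An `oc_frames` object.
#' @param band Search band `(low, high)` Hz.
#' @param trend An `oc_trend` from [fit_aperiodic_trend()].
#' @return Numeric vector of per-frame peak frequencies (Hz) with `NA`
#'   where no suprathreshold peak exists.
#' @export
detect_band_peaks <- function(frames, band, trend) {
  if (band[1] < min(frames$freqs) || band[2] > max(frames$freqs)) {
    abort("`band` must lie within the frame frequency range.")
  }
  thr <- predict(trend, frames$freqs)
  apply(frames$amplitude, 1, peak_in_band,
        freqs = frames$freqs, band = band, thr = thr)
}

#' Single-frame peak detection
#'
#' @param amplitude Amplitude spectrum of one frame.
#' @param freqs Frequency grid, Hz.
#' @param band Search band `(low, high)` Hz.
#' @param trend An `oc_trend`.
#' @return Peak frequency in Hz, or `NA`.
#' @export
detect_band_peak <- function(amplitude, freqs, band, trend) {
  peak_in_band(amplitude, freqs, band, predict(trend, freqs))
}

#' Occurrence distribution of transient alpha:theta frequency ratios
#'
#' Frames in which both components show a suprathreshold peak contribute
#' the ratio `f_alpha / f_theta`, rounded half-away-from-zero to one
#' decimal; ratios outside the bin range are discarded. Occurrence is the
#' percentage of contributing frames per ratio bin and sums to 100 when any
#' frame contributes.
#'
#' @param alpha_peaks,theta_peaks Aligned per-frame peak frequencies
#'   (Hz, `NA` for none), as from [detect_band_peaks()].
#' @param bins Ratio bin labels (defaults to 1.0, 1.1, ..., 3.5).
#' @return A tibble of class `oc_ratio_occ` with `ratio_bin` and `percent`;
#'   the number of contributing frames is in attribute
#'   `n_frames_with_ratio`.
#' @export
ratio_occurrence <- function(alpha_peaks, theta_peaks,
                             bins = seq(1, 3.5, by = 0.1)) {
  if (length(alpha_peaks) != length(theta_peaks)) {
    abort("Peak lists must be aligned (equal length).")
  }
  both <- !is.na(alpha_peaks) & !is.na(theta_peaks)
  r <- round_half_up(alpha_peaks[both] / theta_peaks[both], 1)
  key <- as.integer(round(r * 10))
  bin_key <- as.integer(round(bins * 10))
  hit <- match(key, bin_key)
  hit <- hit[!is.na(hit)]
  n_valid <- length(hit)
  pct <- if (n_valid > 0) 100 * tabulate(hit, length(bins)) / n_valid else
    numeric(length(bins))
  out <- tibble(ratio_bin = bins, percent = pct)
  attr(out, "n_frames_with_ratio") <- n_valid
  class(out) <- c("oc_ratio_occ", class(out))
  out
}

#' Per-bin paired comparison of ratio occurrence between conditions
#'
#' Paired t test per ratio bin on the per-subject occurrence difference
#' (first condition minus second), with Benjamini-Hochberg FDR correction
#' across bins. Bins with zero difference variance across subjects are
#' flagged `degenerate` and reported as non-significant.
#'
#' @param occurrence Long tibble with columns `subject`, `condition`,
#'   `ratio_bin`, `percent` (both conditions for every subject).
#' @param conditions Length-2 character: difference is
#'   `conditions[1] - conditions[2]`.
#' @param q FDR level.
#' @return Tibble with `ratio_bin`, `mean_diff`, `t`, `df`, `p`, `p_adj`,
#'   `significant`, `degenerate`.
#' @export
compare_ratio_bins <- function(occurrence, conditions = c("delay", "fixation"),
                               q = 0.05) {
  need <- c("subject", "condition", "ratio_bin", "percent")
  if (!all(need %in% names(occurrence))) {
    abort("`occurrence` needs columns subject, condition, ratio_bin, percent.")
  }
  wide <- occurrence |>
    dplyr::filter(.data$condition %in% conditions) |>
    tidyr::pivot_wider(id_cols = c("subject", "ratio_bin"),
                       names_from = "condition", values_from = "percent")
  if (!all(conditions %in% names(wide))) {
    abort("Both requested conditions must be present.")
  }
  res <- wide |>
    dplyr::group_by(.data$ratio_bin) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_diff = mean(.data[[conditions[1]]] - .data[[conditions[2]]]),
      sd_diff = sd(.data[[conditions[1]]] - .data[[conditions[2]]]),
      .groups = "drop"
    )
  if (any(res$n < 2)) abort("Need >= 2 subjects per bin.")
  res <- res |>
    dplyr::mutate(
      degenerate = .data$sd_diff == 0,
      t = dplyr::if_else(.data$degenerate, NA_real_,
                         .data$mean_diff / (.data$sd_diff / sqrt(.data$n))),
      df = .data$n - 1,
      p = dplyr::if_else(.data$degenerate, 1,
                         2 * pt(-abs(.data$t), .data$n - 1))
    )
  res$p_adj <- p.adjust(res$p, method = "BH")
  res$significant <- res$p_adj <= q & !res$degenerate
  dplyr::select(res, "ratio_bin", "mean_diff", "t", "df", "p", "p_adj",
                "significant", "degenerate")
}
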