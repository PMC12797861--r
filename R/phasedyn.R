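#' Zero-phase band-pass filtering of a component
#'
#' Applies a Hamming-window linear-phase FIR band-pass with exact group-delay
#' compensation, giving a zero phase response in a single pass. The filter
#' order is `cycles` cycles of the band's low edge.
#'
#' @param component An `oc_component` (or numeric vector/matrix with
#'   `srate` given).
#' @param band Pass band `(low, high)` Hz; defaults to the component band.
#' @param cycles Filter order in cycles of the low band edge.
#' @param srate Sampling rate for raw numeric input.
#' @return The filtered `oc_component` with the applied `filter_order`
#'   recorded (used downstream for edge exclusion).
#' @export
bandpass_zero_phase <- function(component, band = NULL, cycles = 3,
                                srate = NULL) {
  if (!inherits(component, "oc_component")) {
    component <- component(component, srate = srate,
                           band = band %||% abort("`band` required."))
  }
  band <- band %||% component$band
  srate <- component$srate
  h <- design_bandpass(band, srate, cycles)
  ord <- length(h) - 1L
  n <- ncol(component$series)
  if (n <= 3 * ord) {
    abort(sprintf(
      "Trial too short for the band-pass filter: need > %d samples (3 x order %d at %g Hz), got %d.",
      3 * ord, ord, srate, n))
  }
  out <- component
  out$series <- t(apply(component$series, 1, fir_apply, h = h))
  out$band <- band
  out$filter_order <- ord
  out
}

#' Instantaneous phase, amplitude and frequency of a narrowband component
#'
#' Computes the analytic signal by Hilbert transform per trial; phase is the
#' analytic argument (wrapped to `(-pi, pi]`), amplitude the analytic
#' modulus, and instantaneous frequency the Savitzky-Golay derivative of the
#' unwrapped phase divided by `2*pi` (the derivative filter smooths the
#' phase trajectory and suppresses unwrap jitter). Samples within the filter
#' and smoothing transients at the trial edges are flagged invalid.
#'
#' @param filtered A band-pass-filtered `oc_component` (see
#'   [bandpass_zero_phase()]).
#' @param sg_order Savitzky-Golay polynomial order.
#' @param sg_window Savitzky-Golay window length in samples; odd and
#'   greater than `sg_order`.
#' @param edge_factor Multiples of the filter order excluded at each trial
#'   edge (on top of the Savitzky-Golay half-window).
#' @return An object of class `oc_trace` with trials x samples matrices
#'   `phase` (rad), `amplitude`, `ifreq` (Hz), the per-sample `valid` mask,
#'   `srate` and the per-trial `condition` labels.
#' @export
analytic_trace <- function(filtered, sg_order = 3, sg_window = 51,
                           edge_factor = 1.5) {
  if (sg_window %% 2 == 0 || sg_window <= sg_order) {
    abort("`sg_window` must be odd and greater than `sg_order`.")
  }
  srate <- filtered$srate
  ser <- filtered$series
  n <- ncol(ser)
  phase <- amp <- ifr <- matrix(0, nrow(ser), n)
  sg <- signal::sgolay(p = sg_order, n = sg_window, m = 1, ts = 1 / srate)
  for (tr in seq_len(nrow(ser))) {
    z <- hilbert_analytic(ser[tr, ])
    ph <- Arg(z)
    phase[tr, ] <- wrap_phase(ph)
    amp[tr, ] <- Mod(z)
    unwrapped <- signal::unwrap(ph)
    ifr[tr, ] <- signal::sgolayfilt(unwrapped, sg) / (2 * pi)
  }
  ord <- filtered$filter_order %||% 0L
  edge <- ceiling(edge_factor * ord) + (sg_window - 1L) / 2L
  valid <- rep(FALSE, n)
  if (n > 2 * edge) valid[(edge + 1L):(n - edge)] <- TRUE
  if (!any(valid)) {
    abort(sprintf("No valid samples: trial length %d <= 2 x edge %d.", n, edge))
  }
  structure(list(
    phase = phase, amplitude = amp, ifreq = ifr, valid = valid,
    srate = srate, condition = filtered$condition,
    band = filtered$band, label = filtered$label
  ), class = "oc_trace")
}

#' Subset the trials of a trace or component
#'
#' @param x An `oc_trace` or `oc_component`.
#' @param idx Trial indices or a logical mask.
#' @return The subset object.
#' @export
subset_trials <- function(x, idx) {
  if (inherits(x, "oc_trace")) {
    for (f in c("phase", "amplitude", "ifreq")) x[[f]] <- x[[f]][idx, , drop = FALSE]
    x$condition <- x$condition[idx]
  } else if (inherits(x, "oc_component")) {
    x$series <- x$series[idx, , drop = FALSE]
    x$condition <- x$condition[idx]
  } else {
    abort("`x` must be an oc_trace or oc_component.")
  }
  x
}

# Sliding-window mean resultant lengths of a phase-difference vector over
# the valid span. Returns per-window PLVs.
window_plv <- function(dphi, win, step) {
  z <- exp(1i * dphi)
  cz <- c(0, cumsum(z))
  starts <- seq(1L, length(dphi) - win + 1L, by = step)
  Mod(cz[starts + win] - cz[starts]) / win
}

#' Sliding-window phase-locking value between two traces
#'
#' PLV within each window is the mean vector length of the (generalized)
#' phase differences `phi_alpha - k * phi_theta`; windows slide over the
#' jointly valid span of each trial, the per-trial value is the mean over
#' windows and the condition value the mean over trials.
#'
#' @param theta_trace,alpha_trace `oc_trace` objects of equal geometry.
#' @param ratio_k Integer frequency ratio for the generalized phase
#'   difference; `1` is the plain difference.
#' @param window_ms,step_ms Sliding-window length and step, ms.
#' @return An object of class `oc_plv`: `per_trial`, `condition_mean`,
#'   `window_ms`, `step_ms`, `n_windows`.
#' @export
compute_plv <- function(theta_trace, alpha_trace, ratio_k = 1,
                        window_ms = 300, step_ms = 50) {
  if (!identical(dim(theta_trace$phase), dim(alpha_trace$phase)) ||
      theta_trace$srate != alpha_trace$srate) {
    abort("Traces must share geometry and sampling rate.")
  }
  if (ratio_k < 1) abort("`ratio_k` must be >= 1.")
  srate <- theta_trace$srate
  valid <- theta_trace$valid & alpha_trace$valid
  span <- range(which(valid))
  win <- round(window_ms / 1000 * srate)
  step <- max(1L, round(step_ms / 1000 * srate))
  if (span[2] - span[1] + 1L < win) {
    abort("PLV window longer than the valid trial span.")
  }
  cols <- span[1]:span[2]
  per_trial <- vapply(seq_len(nrow(theta_trace$phase)), function(tr) {
    dphi <- alpha_trace$phase[tr, cols] - ratio_k * theta_trace$phase[tr, cols]
    mean(window_plv(dphi, win, step))
  }, numeric(1))
  structure(list(
    per_trial = per_trial, condition_mean = mean(per_trial),
    window_ms = window_ms, step_ms = step_ms,
    n_windows = length(seq(1L, length(cols) - win + 1L, by = step))
  ), class = "oc_plv")
}

#' @export
print.oc_plv <- function(x, ...) {
  cat(sprintf("<oc_plv> mean %.3f over %d trials (%g ms windows, %g ms steps)\n",
              x$condition_mean, length(x$per_trial), x$window_ms, x$step_ms))
  invisible(x)
}

# circular moving average with odd window
circular_ma <- function(y, window) {
  if (window %% 2 == 0) abort("Smoothing window must be odd.")
  k <- (window - 1L) / 2L
  n <- length(y)
  idx <- outer(seq_len(n), -k:k, `+`)
  idx <- ((idx - 1L) %% n) + 1L
  rowMeans(matrix(y[idx], n, window))
}

#' Phase-response curve with detuning and coupling strength
#'
#' Pools instantaneous phase and frequency differences across trials, bins
#' phase differences into `n_bins` equal bins over `(-pi, pi]`, takes the
#' median frequency difference per bin, smooths with a circular moving
#' average and fits a smoothing spline with periodic boundary handling
#' (triple-tiled abscissa). Detuning is the mean frequency difference across
#' the curve and coupling strength the peak-to-trough range of the fitted
#' spline. For a symmetric Kuramoto pair with gain `epsilon` (rad/s) the
#' expected curve is `detuning - (2*epsilon/(2*pi)) * sin(dphi)`, so the
#' recovered coupling strength estimates `4*epsilon/(2*pi)` Hz.
#'
#' @param theta_trace,alpha_trace `oc_trace` objects over the same trials.
#' @param smooth_window Circular moving-average window, bins (odd).
#' @param spline_penalty Optional `spar` for [stats::smooth.spline()];
#'   `NULL` uses generalized cross-validation.
#' @param n_bins Number of phase bins (24 bins of width pi/12 by default).
#' @param ratio_k Integer ratio for the generalized phase difference.
#' @param max_empty Maximum number of empty bins tolerated; up to this many
#'   are interpolated circularly from their neighbors, more raise an
#'   insufficient-coverage error.
#' @return An object of class `oc_prc` with `bin_centers`,
#'   `bin_median_dfreq` (NA where a bin was empty), `smoothed`,
#'   `spline_grid`, `spline_values`, `detuning` (mean of bin medians),
#'   `detuning_spline` (mean of the fitted spline), `coupling_strength`
#'   and `n_obs_per_bin`.
#' @export
estimate_prc <- function(theta_trace, alpha_trace, smooth_window = 3,
                         spline_penalty = NULL, n_bins = 24, ratio_k = 1,
                         max_empty = 4) {
  valid <- theta_trace$valid & alpha_trace$valid
  dphi <- wrap_phase(alpha_trace$phase[, valid, drop = FALSE] -
                       ratio_k * theta_trace$phase[, valid, drop = FALSE])
  dfreq <- alpha_trace$ifreq[, valid, drop = FALSE] -
    ratio_k * theta_trace$ifreq[, valid, drop = FALSE]
  dphi <- as.vector(dphi)
  dfreq <- as.vector(dfreq)

  width <- 2 * pi / n_bins
  bin <- pmin(pmax(ceiling((dphi + pi) / width), 1L), n_bins)
  centers <- -pi + (seq_len(n_bins) - 0.5) * width
  n_obs <- tabulate(bin, n_bins)
  med <- rep(NA_real_, n_bins)
  for (b in which(n_obs > 0)) med[b] <- median(dfreq[bin == b])

  empty <- which(n_obs == 0)
  if (length(empty) > max_empty) {
    abort(sprintf("Insufficient phase coverage: %d of %d bins empty.",
                  length(empty), n_bins),
          class = "oscicouple_insufficient_coverage")
  }
  filled <- med
  if (length(empty) > 0) {
    # circular linear interpolation from nearest non-empty neighbors
    occ <- which(n_obs > 0)
    for (b in empty) {
      dl <- (b - occ) %% n_bins
      dr <- (occ - b) %% n_bins
      left <- occ[which.min(replace(dl, dl == 0, n_bins))]
      right <- occ[which.min(replace(dr, dr == 0, n_bins))]
      wl <- min((b - left) %% n_bins, n_bins)
      wr <- min((right - b) %% n_bins, n_bins)
      filled[b] <- (med[left] * wr + med[right] * wl) / (wl + wr)
    }
  }
  smoothed <- circular_ma(filled, smooth_window)

  # periodic spline: tile three periods, fit, evaluate the central one
  xs <- c(centers - 2 * pi, centers, centers + 2 * pi)
  ys <- rep(smoothed, 3)
  fit <- if (is.null(spline_penalty)) {
    smooth.spline(xs, ys, cv = FALSE)
  } else {
    smooth.spline(xs, ys, spar = spline_penalty)
  }
  grid <- seq(-pi, pi, length.out = 241)
  sv <- predict(fit, grid)$y

  structure(list(
    bin_centers = centers, bin_median_dfreq = med, smoothed = smoothed,
    spline_grid = grid, spline_values = sv,
    detuning = mean(filled),
    detuning_spline = mean(sv),
    coupling_strength = max(sv) - min(sv),
    n_obs_per_bin = n_obs, n_bins = n_bins, ratio_k = ratio_k
  ), class = "oc_prc")
}

#' @export
print.oc_prc <- function(x, ...) {
  cat(sprintf("<oc_prc> detuning %.3f Hz (spline mean %.3f), coupling strength %.3f Hz, %d/%d bins occupied\n",
              x$detuning, x$detuning_spline, x$coupling_strength,
              sum(x$n_obs_per_bin > 0), x$n_bins))
  invisible(x)
}

#' Phase-locking value over a coupling-by-detuning grid
#'
#' Simulates weakly coupled phase-oscillator pairs on a grid of coupling
#' gains and detunings and measures the sliding-window PLV of their phase
#' difference, reproducing the Arnold-tongue structure: PLV rises with
#' coupling and falls with absolute detuning.
#'
#' @param epsilons Coupling gains, rad/s.
#' @param detunings Frequency detunings, Hz (oscillator 2 sits `detuning`
#'   Hz above oscillator 1 at `base_freq`).
#' @param n_trials Trials per grid cell.
#' @param duration Trial duration, s.
#' @param srate Sampling rate, Hz.
#' @param phase_noise_sd Phase-diffusion SD, rad/sqrt(s).
#' @param base_freq Natural frequency of oscillator 1, Hz.
#' @param window_ms,step_ms PLV window and step, ms.
#' @param seed Integer seed.
#' @return A tibble with `epsilon`, `detuning` and mean `plv` per cell.
#' @export
arnold_tongue_grid <- function(epsilons, detunings, n_trials = 10,
                               duration = 2, srate = 500,
                               phase_noise_sd = 1, base_freq = 6,
                               window_ms = 300, step_ms = 50, seed = 1L) {
  cells <- expand.grid(epsilon = epsilons, detuning = detunings,
                       KEEP.OUT.ATTRS = FALSE)
  n_cells <- nrow(cells)
  n_steps <- round(duration * srate)
  win <- round(window_ms / 1000 * srate)
  step <- max(1L, round(step_ms / 1000 * srate))
  eps <- rep(cells$epsilon, each = n_trials)
  det <- rep(cells$detuning, each = n_trials)
  plv_cell <- with_seed(seed, {
    init1 <- runif(n_cells * n_trials, -pi, pi)
    init2 <- runif(n_cells * n_trials, -pi, pi)
    ph <- sim_phases_batch(base_freq, base_freq + det, eps, eps,
                           phase_noise_sd, n_steps, 1 / srate, init1, init2)
    dphi <- ph$theta2 - ph$theta1
    plv_trial <- vapply(seq_len(ncol(dphi)), function(j) {
      mean(window_plv(dphi[, j], win, step))
    }, numeric(1))
    colMeans(matrix(plv_trial, nrow = n_trials))
  })
  tibble(epsilon = cells$epsilon, detuning = cells$detuning, plv = plv_cell)
}
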