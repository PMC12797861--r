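#' Spatio-spectral decomposition of epoched multichannel data
#'
#' Finds spatial filters maximizing narrowband power relative to flanking
#' frequencies by a generalized eigenvalue decomposition of two covariance
#' matrices: one from band-pass-filtered data (signal) and one from data
#' filtered to the flanking bands (noise). Trials are concatenated for
#' covariance estimation and both covariances receive shrinkage
#' regularization toward the identity.
#'
#' @param epochs An [trial_epochs()] object with >= 2 channels.
#' @param band Target band `(low, high)` in Hz, inside `(0, srate/2)`.
#' @param flank_width Width of the flanking bands beyond each band edge, Hz.
#' @param transition Gap between the band edge and the flanking stopband
#'   edge, Hz.
#' @param shrinkage Shrinkage weight toward the scaled identity in `[0, 1)`.
#' @param cycles FIR order in cycles of the relevant low edge.
#' @return An object of class `oc_ssd` with `filters` (channels x
#'   components, unit-norm columns, sign fixed so the largest-magnitude
#'   entry is positive), `patterns` (forward models), `gev_values`
#'   (descending band-to-flank power ratios), `band` and `flanks`.
#' @export
compute_ssd <- function(epochs, band, flank_width = 2, transition = 1,
                        shrinkage = 0.05, cycles = 3) {
  if (!inherits(epochs, "oc_epochs")) abort("`epochs` must be an oc_epochs object.")
  d <- dim(epochs$data)
  if (d[2] < 2) abort("SSD needs at least 2 channels.")
  srate <- epochs$srate
  if (band[1] <= 0 || band[2] >= srate / 2) {
    abort("`band` must lie inside (0, srate/2).")
  }
  wide <- c(max(band[1] - flank_width, 0.5), band[2] + flank_width)
  stop_band <- c(band[1] - transition, band[2] + transition)

  # (trials * samples) x channels, trials concatenated
  x <- matrix(aperm(epochs$data, c(3, 1, 2)), nrow = d[3] * d[1], ncol = d[2])
  # covariances only involve content below wide[2]; decimating first (with
  # ample margin above the top analysis frequency) shortens both the data
  # and the kernels without touching the spatial structure
  q <- max(1L, floor(srate / (5 * wide[2])))
  srate_cov <- srate / q
  if (q > 1L) {
    x <- apply(x, 2, signal::decimate, q = q, ftype = "fir")
  }
  h_sig <- design_bandpass(band, srate_cov, cycles)
  h_wide <- design_bandpass(wide, srate_cov, cycles)
  h_stop <- design_bandstop(stop_band, srate_cov, cycles)
  # flank chain as one composite symmetric kernel (bandpass then bandstop)
  h_flank <- stats::convolve(h_wide, rev(h_stop), type = "open")

  # one forward FFT per channel shared by both filter chains
  xs <- matrix(0, nrow(x), d[2])
  xn <- matrix(0, nrow(x), d[2])
  for (ch in seq_len(d[2])) {
    f <- fir_apply_multi(x[, ch], list(h_sig, h_flank))
    xs[, ch] <- f[, 1]
    xn[, ch] <- f[, 2]
  }

  cov_shrunk <- function(m) {
    cc <- stats::cov(m)
    (1 - shrinkage) * cc + shrinkage * mean(diag(cc)) * diag(nrow(cc))
  }
  # normalize by each chain's white-noise power gain so the generalized
  # eigenvalues read as band-to-flank power ratios per unit bandwidth
  # (white-noise input then gives eigenvalues of ~1)
  cs <- cov_shrunk(xs) / sum(h_sig^2)
  cn <- cov_shrunk(xn) / sum(h_flank^2)

  en <- eigen(cn, symmetric = TRUE)
  tol <- max(en$values) * 1e-10
  if (any(en$values < tol)) {
    warn("Noise covariance near rank-deficient; shrinkage keeps it invertible.")
    en$values <- pmax(en$values, tol)
  }
  k <- en$vectors %*% diag(1 / sqrt(en$values), d[2]) %*% t(en$vectors)
  m <- k %*% cs %*% k
  m <- (m + t(m)) / 2
  em <- eigen(m, symmetric = TRUE)
  w <- k %*% em$vectors
  # unit norm, positive largest-magnitude entry: reproducible sign convention
  for (j in seq_len(ncol(w))) {
    w[, j] <- w[, j] / sqrt(sum(w[, j]^2))
    i_max <- which.max(abs(w[, j]))
    if (w[i_max, j] < 0) w[, j] <- -w[, j]
  }
  patterns <- cs %*% w %*% solve(t(w) %*% cs %*% w)
  structure(list(
    filters = w, patterns = patterns, gev_values = em$values,
    band = band,
    flanks = list(lower = c(wide[1], band[1] - transition),
                  upper = c(band[2] + transition, wide[2])),
    srate = srate, channel_names = epochs$channel_names
  ), class = "oc_ssd")
}

#' @export
print.oc_ssd <- function(x, ...) {
  cat(sprintf("<oc_ssd> band %g-%g Hz, %d components; top ratios: %s\n",
              x$band[1], x$band[2], ncol(x$filters),
              paste(signif(utils::head(x$gev_values, 3), 3), collapse = ", ")))
  invisible(x)
}

# Welch-averaged one-sided power spectrum of the rows of a trials x samples
# matrix. Returns freq and mean power.
welch_psd <- function(series, srate, seg_s = 2) {
  if (is.vector(series)) series <- matrix(series, nrow = 1)
  n <- ncol(series)
  seg <- min(round(seg_s * srate), n)
  if (seg < 2) abort("Series too short for a Welch spectrum.")
  hop <- max(1L, seg %/% 2L)
  win <- signal::hamming(seg)
  u <- sum(win^2)
  starts <- seq(1L, n - seg + 1L, by = hop)
  acc <- numeric(seg %/% 2L + 1L)
  count <- 0L
  for (r in seq_len(nrow(series))) {
    for (s0 in starts) {
      seg_x <- series[r, s0:(s0 + seg - 1L)]
      seg_x <- (seg_x - mean(seg_x)) * win
      p <- Mod(fft(seg_x))^2 / u
      acc <- acc + p[seq_len(seg %/% 2L + 1L)]
      count <- count + 1L
    }
  }
  list(freq = (seq_len(seg %/% 2L + 1L) - 1L) * srate / seg,
       power = acc / count)
}

#' Band-to-flank signal-to-noise ratio of a component
#'
#' SNR is the mean Welch-spectrum power inside the target band divided by
#' the mean power over the flanking bands.
#'
#' @param component An `oc_component`, or a numeric vector/matrix
#'   (trials x samples) of the component time course.
#' @param band Target band `(low, high)` Hz. Defaults to the component's.
#' @param flanks List of two `(low, high)` flanking bands. Defaults to the
#'   component's.
#' @param srate Sampling rate (needed for raw numeric input).
#' @return A single non-negative ratio.
#' @export
component_snr <- function(component, band = NULL, flanks = NULL,
                          srate = NULL) {
  if (inherits(component, "oc_component")) {
    band <- band %||% component$band
    flanks <- flanks %||% component$flanks
    srate <- srate %||% component$srate
    series <- component$series
  } else {
    series <- component
    if (is.null(band) || is.null(flanks) || is.null(srate)) {
      abort("`band`, `flanks` and `srate` are required for raw input.")
    }
  }
  ps <- welch_psd(series, srate)
  in_band <- ps$freq >= band[1] & ps$freq <= band[2]
  in_flank <- Reduce(`|`, lapply(flanks, function(f) {
    ps$freq >= f[1] & ps$freq <= f[2]
  }))
  if (!any(in_band) || !any(in_flank)) {
    abort("Band or flank contains no spectral bins; series too short.")
  }
  p_flank <- mean(ps$power[in_flank])
  if (p_flank <= 0) abort("Zero flanking power: degenerate input.")
  mean(ps$power[in_band]) / p_flank
}

#' Select the target narrowband component from an SSD decomposition
#'
#' Optionally gates components by the absolute correlation of their forward
#' pattern with a spatial template (the stand-in for anatomical selection on
#' synthetic data), then returns the surviving component with the highest
#' band-to-flank SNR, projected through its spatial filter.
#'
#' @param filterset An `oc_ssd` object.
#' @param epochs The [trial_epochs()] the filters were derived from (or
#'   compatible data to project).
#' @param template_pattern Optional channel-weight template; `NULL` skips
#'   the gate.
#' @param threshold Minimum absolute pattern-template correlation.
#' @param label Label to attach (e.g. `"frontal_theta"`).
#' @param max_components Consider at most this many top components.
#' @return An object of class `oc_component`: `series` (trials x samples),
#'   `srate`, `band`, `flanks`, `snr`, `label`, `filter`, `pattern`,
#'   and the per-trial `condition` labels.
#' @export
select_component <- function(filterset, epochs, template_pattern = NULL,
                             threshold = 0.7, label = "component",
                             max_components = NULL) {
  if (ncol(filterset$filters) == 0) abort("Empty filter set.")
  n_comp <- min(max_components %||% ncol(filterset$filters),
                ncol(filterset$filters))
  cand <- seq_len(n_comp)
  if (!is.null(template_pattern)) {
    match_r <- vapply(cand, function(j) {
      abs(cor(filterset$patterns[, j], template_pattern))
    }, numeric(1))
    cand <- cand[match_r >= threshold]
    if (length(cand) == 0) {
      abort("No component matches the spatial template.",
            class = "oscicouple_no_component")
    }
  }
  d <- dim(epochs$data)
  project <- function(j) {
    w <- filterset$filters[, j]
    ser <- matrix(0, d[1], d[3])
    for (tr in seq_len(d[1])) ser[tr, ] <- w %*% epochs$data[tr, , ]
    ser
  }
  snrs <- vapply(cand, function(j) {
    component_snr(project(j), band = filterset$band,
                  flanks = filterset$flanks, srate = epochs$srate)
  }, numeric(1))
  best <- cand[which.max(snrs)]
  structure(list(
    series = project(best), srate = epochs$srate,
    band = filterset$band, flanks = filterset$flanks,
    snr = max(snrs), label = label,
    filter = filterset$filters[, best],
    pattern = filterset$patterns[, best],
    component_index = best,
    condition = epochs$condition
  ), class = "oc_component")
}

#' Construct a component time series directly
#'
#' Wraps a trials x samples matrix (or a single vector) as an
#' `oc_component`, the carrier used by the phase-dynamics and
#' cross-frequency modules. Useful when the component is obtained outside
#' SSD (e.g. a simulated source projection).
#'
#' @param series Numeric vector or trials x samples matrix.
#' @param srate Sampling rate, Hz.
#' @param band Nominal band `(low, high)` Hz.
#' @param label Component label.
#' @param condition Optional per-trial condition labels.
#' @param snr Optional band-to-flank SNR.
#' @return An `oc_component`.
#' @export
component <- function(series, srate, band, label = "component",
                      condition = NULL, snr = NA_real_) {
  if (is.vector(series)) series <- matrix(series, nrow = 1)
  if (!all(is.finite(series))) abort("`series` must be finite.")
  stopifnot_scalar_pos(srate, "srate")
  structure(list(
    series = series, srate = srate, band = band,
    flanks = list(lower = c(max(band[1] - 2, 0.5), band[1] - 1),
                  upper = c(band[2] + 1, band[2] + 2)),
    snr = snr, label = label, filter = NULL, pattern = NULL,
    condition = condition %||% rep("all", nrow(series))
  ), class = "oc_component")
}

#' @export
print.oc_component <- function(x, ...) {
  cat(sprintf("<oc_component> '%s' %d trials x %d samples @ %g Hz, band %g-%g Hz, SNR %.3g\n",
              x$label, nrow(x$series), ncol(x$series), x$srate,
              x$band[1], x$band[2], x$snr))
  invisible(x)
}
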