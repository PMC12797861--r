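#' Uniform-count (quantile) discretization of a real series
#'
#' Rank-based binning assigning `floor(n/n_bins)` or `ceiling(n/n_bins)`
#' samples to each bin apart from ties; tied values share the lower bin.
#' The symbol sequence is invariant under strictly monotone transforms of
#' the data, which maximizes sensitivity to dependence regardless of
#' marginal shape.
#'
#' @param x Real series (length >= `n_bins`, non-constant).
#' @param n_bins Number of symbols (>= 2).
#' @param runs Optional integer run lengths partitioning `x` into
#'   independent segments (e.g. trials); lag-based estimators never pair
#'   samples across run boundaries.
#' @return An object of class `oc_symbols`: integer `symbols` in
#'   `0..n_bins-1`, `n_bins`, the original-unit `bin_edges`, and `runs`.
#' @export
discretize_uniform_count <- function(x, n_bins = 4, runs = NULL) {
  if (n_bins < 2) abort("`n_bins` must be >= 2.")
  n <- length(x)
  if (n < n_bins) abort("Series shorter than `n_bins`.")
  if (!all(is.finite(x))) abort("`x` must be finite.")
  if (max(x) == min(x)) abort("Constant series: quantile edges degenerate.")
  if (is.null(runs)) runs <- n
  if (sum(runs) != n) abort("`runs` must sum to length(x).")
  ranks <- rank(x, ties.method = "min")
  sym <- as.integer(floor((ranks - 1) * n_bins / n))
  sym <- pmin(sym, n_bins - 1L)
  structure(list(
    symbols = sym, n_bins = as.integer(n_bins),
    bin_edges = quantile(x, (1:(n_bins - 1)) / n_bins, names = FALSE),
    runs = as.integer(runs)
  ), class = "oc_symbols")
}

entropy_from_counts <- function(counts) {
  p <- counts[counts > 0]
  p <- p / sum(p)
  -sum(p * log2(p))
}

as_symbols <- function(x) {
  if (inherits(x, "oc_symbols")) return(x)
  abort("Input must be an `oc_symbols` object (see discretize_uniform_count()).")
}

#' Plug-in mutual information between two symbol series, in bits
#'
#' `MI = H(X) + H(Y) - H(X,Y)` with plug-in (maximum-likelihood) entropies
#' in log base 2. Symmetric in its arguments and non-negative.
#'
#' @param x,y `oc_symbols` of equal length.
#' @return Mutual information in bits.
#' @export
mutual_information <- function(x, y) {
  x <- as_symbols(x); y <- as_symbols(y)
  if (length(x$symbols) != length(y$symbols)) {
    abort("Symbol series must have equal length.")
  }
  kx <- x$n_bins; ky <- y$n_bins
  cx <- tabulate(x$symbols + 1L, kx)
  cy <- tabulate(y$symbols + 1L, ky)
  cxy <- tabulate(x$symbols * ky + y$symbols + 1L, kx * ky)
  mi <- entropy_from_counts(cx) + entropy_from_counts(cy) -
    entropy_from_counts(cxy)
  max(mi, 0)
}

# indices of (t, t-1, t-lag) triples that stay inside each run
lagged_triples <- function(runs, lag) {
  stops <- cumsum(runs)
  starts <- stops - runs + 1L
  idx <- unlist(lapply(seq_along(runs), function(r) {
    if (runs[r] <= lag) return(integer(0))
    (starts[r] + lag):stops[r]
  }))
  idx
}

#' Transfer entropy at a single lag, in bits
#'
#' Conditional-mutual-information formulation:
#' `TE = I(dst_t ; src_{t-lag} | dst_{t-1})`, estimated by plug-in entropies
#' over the empirical triple joint distribution and clipped at zero against
#' floating-point error. When the series carry run boundaries (trials), no
#' `(t, t-1, t-lag)` triple crosses a boundary.
#'
#' @param src,dst `oc_symbols` of equal length (and identical runs).
#' @param lag Positive lag in samples.
#' @return Transfer entropy in bits.
#' @export
transfer_entropy_at_lag <- function(src, dst, lag) {
  src <- as_symbols(src); dst <- as_symbols(dst)
  n <- length(dst$symbols)
  if (length(src$symbols) != n) abort("Series must have equal length.")
  if (!identical(src$runs, dst$runs)) abort("Series must share run structure.")
  if (lag < 1) abort("`lag` must be >= 1.")
  if (n <= lag + 1) abort("`lag` too large for the series length.")
  t_idx <- lagged_triples(dst$runs, lag)
  if (length(t_idx) < 2) abort("`lag` leaves no usable samples in any run.")
  xt <- dst$symbols[t_idx]          # destination present
  yl <- src$symbols[t_idx - lag]    # lagged source
  zp <- dst$symbols[t_idx - 1L]     # destination past
  kx <- dst$n_bins; ky <- src$n_bins
  # joint codes
  cz <- tabulate(zp + 1L, kx)
  cxz <- tabulate(xt * kx + zp + 1L, kx * kx)
  cyz <- tabulate(yl * kx + zp + 1L, ky * kx)
  cxyz <- tabulate((xt * ky + yl) * kx + zp + 1L, kx * ky * kx)
  te <- entropy_from_counts(cxz) + entropy_from_counts(cyz) -
    entropy_from_counts(cz) - entropy_from_counts(cxyz)
  max(te, 0)
}

#' Lag-averaged transfer entropy
#'
#' Arithmetic mean of the per-lag transfer entropies over a range of lags,
#' accommodating unknown interaction delays.
#'
#' @inheritParams transfer_entropy_at_lag
#' @param lags Integer lags in samples (default 1 to 20).
#' @return Mean transfer entropy in bits.
#' @export
transfer_entropy_avg <- function(src, dst, lags = 1:20) {
  mean(vapply(lags, function(l) transfer_entropy_at_lag(src, dst, l),
              numeric(1)))
}

#' Information-theoretic connectivity between two component series
#'
#' Convenience wrapper for the pipeline: restricts both band-limited
#' component series to their valid samples, decimates to the
#' information-theory sampling rate with an anti-aliasing FIR, pools trials
#' (preserving trial boundaries for the lagged estimator), discretizes by
#' uniform counts and returns MI and lag-averaged TE in both directions.
#'
#' @param theta_series,alpha_series trials x samples matrices.
#' @param srate Sampling rate of the inputs, Hz.
#' @param valid Logical per-sample mask (e.g. from an `oc_trace`); `NULL`
#'   keeps all samples.
#' @param n_bins Number of symbols.
#' @param lags Lags in samples at the decimated rate.
#' @param srate_it Target sampling rate, Hz; `srate/srate_it` must be a
#'   positive integer.
#' @return One-row tibble: `mi`, `te_a2p` (theta to alpha), `te_p2a`
#'   (alpha to theta), `n_bins`, `srate_it`.
#' @export
it_metrics <- function(theta_series, alpha_series, srate, valid = NULL,
                       n_bins = 4, lags = 1:20, srate_it = 250) {
  fac <- srate / srate_it
  if (fac != round(fac) || fac < 1) {
    abort("`srate/srate_it` must be a positive integer.")
  }
  fac <- as.integer(fac)
  if (is.null(valid)) valid <- rep(TRUE, ncol(theta_series))
  cols <- which(valid)
  dec <- function(v) {
    if (fac == 1) return(v)
    signal::decimate(v, fac, ftype = "fir")
  }
  tt <- lapply(seq_len(nrow(theta_series)),
               function(tr) dec(theta_series[tr, cols]))
  aa <- lapply(seq_len(nrow(alpha_series)),
               function(tr) dec(alpha_series[tr, cols]))
  runs <- vapply(tt, length, integer(1))
  st <- discretize_uniform_count(unlist(tt), n_bins, runs = runs)
  sa <- discretize_uniform_count(unlist(aa), n_bins, runs = runs)
  tibble(
    mi = mutual_information(st, sa),
    te_a2p = transfer_entropy_avg(st, sa, lags),
    te_p2a = transfer_entropy_avg(sa, st, lags),
    n_bins = n_bins, srate_it = srate_it
  )
}
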