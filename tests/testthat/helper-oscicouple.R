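# Shared fixture builders and independent brute-force oracles.

# Component-level coupled pair: two simulated sources observed as cosines
# plus white noise at a given SNR, carried through band-pass + Hilbert.
make_trace_pair <- function(omega_t, omega_a, epsilon, phase_noise_sd,
                            n_trials = 20, duration = 4, srate = 500,
                            seed = 1, snr_db = 20,
                            band_t = c(4, 8), band_a = c(8, 14),
                            eps_t2a = NULL, eps_a2t = NULL) {
  n <- duration * srate
  st <- matrix(0, n_trials, n)
  sa <- matrix(0, n_trials, n)
  set.seed(seed)
  for (tr in seq_len(n_trials)) {
    s <- simulate_coupled_phases(omega_t, omega_a, epsilon, phase_noise_sd,
                                 duration, srate, seed = seed * 10000 + tr,
                                 init_phase = runif(2, -pi, pi),
                                 epsilon_1on2 = eps_t2a,
                                 epsilon_2on1 = eps_a2t)
    st[tr, ] <- cos(s$theta1)
    sa[tr, ] <- cos(s$theta2)
  }
  amp_n <- sqrt(0.5 / 10^(snr_db / 10)) # source power is 1/2
  st <- st + matrix(rnorm(length(st), 0, amp_n), nrow = n_trials)
  sa <- sa + matrix(rnorm(length(sa), 0, amp_n), nrow = n_trials)
  tt <- analytic_trace(bandpass_zero_phase(component(st, srate, band_t)))
  ta <- analytic_trace(bandpass_zero_phase(component(sa, srate, band_a)))
  list(theta = tt, alpha = ta)
}

# Brute-force plug-in MI over explicit probability tables (independent of
# the package's counting path).
mi_brute <- function(sx, sy, kx, ky) {
  n <- length(sx)
  pj <- matrix(0, kx, ky)
  for (i in seq_len(n)) pj[sx[i] + 1, sy[i] + 1] <- pj[sx[i] + 1, sy[i] + 1] + 1
  pj <- pj / n
  px <- rowSums(pj)
  py <- colSums(pj)
  mi <- 0
  for (a in seq_len(kx)) {
    for (b in seq_len(ky)) {
      if (pj[a, b] > 0) {
        mi <- mi + pj[a, b] * log2(pj[a, b] / (px[a] * py[b]))
      }
    }
  }
  mi
}

# Brute-force conditional-MI transfer entropy I(dst_t; src_{t-lag} | dst_{t-1})
# from explicit triple tables, honoring run boundaries.
te_brute <- function(src, dst, lag, ks, kd, runs = NULL) {
  n <- length(src)
  if (is.null(runs)) runs <- n
  stops <- cumsum(runs)
  starts <- stops - runs + 1
  xs <- integer(0); ys <- integer(0); zs <- integer(0)
  for (r in seq_along(runs)) {
    if (runs[r] <= lag) next
    t_idx <- (starts[r] + lag):stops[r]
    xs <- c(xs, dst[t_idx])
    ys <- c(ys, src[t_idx - lag])
    zs <- c(zs, dst[t_idx - 1])
  }
  m <- length(xs)
  pj <- array(0, c(kd, ks, kd))
  for (i in seq_len(m)) {
    pj[xs[i] + 1, ys[i] + 1, zs[i] + 1] <- pj[xs[i] + 1, ys[i] + 1, zs[i] + 1] + 1
  }
  pj <- pj / m
  te <- 0
  for (z in seq_len(kd)) {
    pz <- sum(pj[, , z])
    if (pz == 0) next
    for (x in seq_len(kd)) {
      for (y in seq_len(ks)) {
        p <- pj[x, y, z]
        if (p > 0) {
          pxz <- sum(pj[x, , z])
          pyz <- sum(pj[, y, z])
          te <- te + p * log2(p * pz / (pxz * pyz))
        }
      }
    }
  }
  te
}

# wrap an integer symbol vector as the package's symbol container
as_oc_symbols <- function(sym, n_bins, runs = NULL) {
  structure(list(symbols = as.integer(sym), n_bins = as.integer(n_bins),
                 bin_edges = numeric(0),
                 runs = as.integer(runs %||% length(sym))),
            class = "oc_symbols")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# multichannel rendering with a single planted 10-Hz source
planted_source <- function(seed = 7, snr_db = 10, n_channels = 8,
                           n_trials = 20) {
  spec <- condition_spec("c", omega_theta = 5, omega_alpha = 10, epsilon = 0,
                         phase_noise_sd = 1, amp_theta = 0, amp_alpha = 1,
                         snr_db = snr_db, n_trials = n_trials,
                         trial_duration = 3)
  render_sensor_trials(NULL, spec, n_channels = n_channels, seed = seed)
}
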