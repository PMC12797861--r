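srate <- 500

test_that("band-pass is zero-phase, selective and kills DC", {
  t <- (seq_len(6 * srate) - 1) / srate
  tone10 <- component(cos(2 * pi * 10 * t), srate, c(8, 14))
  f10 <- bandpass_zero_phase(tone10)
  mid <- 1000:2000
  # zero-phase: cross-correlation peak at lag 0
  cc <- stats::ccf(f10$series[1, mid], tone10$series[1, mid], lag.max = 20,
                   plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  expect_lt(abs(max(f10$series[1, mid]) - 1), 0.05) # unity passband gain
  # 3 Hz tone through 8-14: heavily attenuated
  tone3 <- component(cos(2 * pi * 3 * t), srate, c(8, 14))
  f3 <- bandpass_zero_phase(tone3)
  expect_lt(sqrt(mean(f3$series[1, mid]^2)) / sqrt(0.5), 0.01)
  # DC input -> ~0
  dc <- component(rep(1, 6 * srate), srate, c(8, 14))
  fdc <- bandpass_zero_phase(dc)
  expect_lt(max(abs(fdc$series[1, mid])), 1e-3)
  # short trial: explicit error naming the minimum length
  shorty <- component(rnorm(300), srate, c(4, 8))
  expect_error(bandpass_zero_phase(shorty), "need > ")
})

test_that("analytic trace recovers tone and chirp instantaneous frequency", {
  t <- (seq_len(4 * srate) - 1) / srate
  tone <- bandpass_zero_phase(component(2.5 * cos(2 * pi * 10 * t), srate,
                                        c(8, 14)))
  tr <- analytic_trace(tone)
  expect_lt(max(abs(tr$ifreq[1, tr$valid] - 10)), 0.01)
  # Hilbert envelope ~ A up to FIR passband ripple (~1%)
  expect_lt(max(abs(tr$amplitude[1, tr$valid] - 2.5)) / 2.5, 0.04)
  expect_true(all(tr$phase > -pi & tr$phase <= pi))
  # linear chirp 8 -> 12 Hz over 4 s: f(t) = 8 + t, analytic oracle
  chirp <- cos(2 * pi * (8 * t + t^2 / 2))
  trc <- analytic_trace(bandpass_zero_phase(component(chirp, srate, c(6, 14))))
  f_true <- 8 + t
  expect_lt(max(abs(trc$ifreq[1, trc$valid] - f_true[trc$valid])), 0.1)
  # validation
  expect_error(analytic_trace(tone, sg_window = 50), "odd")
  expect_error(analytic_trace(tone, sg_order = 5, sg_window = 5), "odd|greater")
})

test_that("PLV is exact for deterministic phase relations and bounded", {
  t <- (seq_len(4 * srate) - 1) / srate
  base <- bandpass_zero_phase(component(cos(2 * pi * 10 * t), srate, c(8, 14)))
  tr1 <- analytic_trace(base)
  p_self <- compute_plv(tr1, tr1)
  expect_equal(p_self$condition_mean, 1, tolerance = 1e-12)
  # constant phase offset leaves PLV at 1
  shifted <- bandpass_zero_phase(component(cos(2 * pi * 10 * t + 1.1), srate,
                                           c(8, 14)))
  tr2 <- analytic_trace(shifted)
  p_off <- compute_plv(tr1, tr2)
  expect_equal(p_off$condition_mean, 1, tolerance = 1e-3)
  expect_true(all(p_off$per_trial >= 0 & p_off$per_trial <= 1))
})

test_that("PLV of independent uniform phases matches the Rayleigh expectation", {
  # E[R] ~ sqrt(pi)/(2 sqrt(N)) for N independent uniform phases per window;
  # non-overlapping windows keep draws independent
  set.seed(6)
  N <- 150
  n_win <- 1000
  n <- N * n_win
  fake <- function() {
    structure(list(phase = matrix(runif(n, -pi, pi), 1),
                   ifreq = matrix(0, 1, n), amplitude = matrix(1, 1, n),
                   valid = rep(TRUE, n), srate = srate, condition = "all"),
              class = "oc_trace")
  }
  p <- compute_plv(fake(), fake(), window_ms = N / srate * 1000,
                   step_ms = N / srate * 1000)
  expected <- sqrt(pi) / (2 * sqrt(N))
  expect_lt(abs(p$condition_mean - expected) / expected, 0.2)
})

test_that("PRC recovers detuning with uncoupled oscillators", {
  pair <- make_trace_pair(6, 10, epsilon = 0, phase_noise_sd = 1,
                          seed = 21, band_a = c(8, 12))
  prc <- estimate_prc(pair$theta, pair$alpha)
  expect_lt(abs(prc$detuning - 4), 0.2)
  # coupling-strength noise floor: compare against a permutation control
  # that destroys any phase-frequency relation by trial misalignment
  perm <- pair$alpha
  reord <- c(2:nrow(perm$phase), 1)
  perm$phase <- perm$phase[reord, , drop = FALSE]
  prc_perm <- estimate_prc(pair$theta,
                           modifyList(pair$alpha, list(phase = perm$phase)))
  expect_lt(prc$coupling_strength, 2 * prc_perm$coupling_strength + 0.1)
})

test_that("PRC recovers coupling strength from the closed-form 4*eps/2pi", {
  for (eps in c(1.5, 3)) {
    pair <- make_trace_pair(6, 7, epsilon = eps, phase_noise_sd = 1,
                            seed = 31 + eps, band_t = c(3.5, 8.5),
                            band_a = c(4.5, 9.5))
    prc <- estimate_prc(pair$theta, pair$alpha)
    expected <- 4 * eps / (2 * pi)
    expect_lt(abs(prc$coupling_strength - expected) / expected, 0.15)
    # the PRC shape is ~ detuning - (2 eps / 2 pi) sin(dphi): the spline
    # trough sits near +pi/2 and the peak near -pi/2
    expect_lt(abs(prc$spline_grid[which.min(prc$spline_values)] - pi / 2), 0.8)
    expect_lt(abs(prc$spline_grid[which.max(prc$spline_values)] + pi / 2), 0.8)
  }
})

test_that("a flat frequency difference yields near-zero coupling strength", {
  # inject a constant frequency difference with uniform phase coverage
  set.seed(8)
  n <- 40000
  fake_trace <- function(phase, ifreq) {
    structure(list(phase = matrix(phase, 1), ifreq = matrix(ifreq, 1),
                   amplitude = matrix(1, 1, length(phase)),
                   valid = rep(TRUE, length(phase)), srate = srate,
                   condition = "all"),
              class = "oc_trace")
  }
  ph_t <- runif(n, -pi, pi)
  ph_a <- runif(n, -pi, pi)
  tt <- fake_trace(ph_t, rep(6, n) + rnorm(n, 0, 0.3))
  ta <- fake_trace(ph_a, rep(9, n) + rnorm(n, 0, 0.3))
  prc <- estimate_prc(tt, ta)
  expect_lt(prc$coupling_strength, 0.05)
  expect_lt(abs(prc$detuning - 3), 0.05)
})

test_that("locked noiseless pairs are rejected for insufficient coverage", {
  # hard lock concentrates the phase difference in very few bins
  pair <- make_trace_pair(8, 8.2, epsilon = 4, phase_noise_sd = 0,
                          n_trials = 4, seed = 41,
                          band_t = c(6, 10), band_a = c(6, 10))
  expect_error(estimate_prc(pair$theta, pair$alpha),
               class = "oscicouple_insufficient_coverage")
})
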