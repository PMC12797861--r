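#' Ground-truth parameters for a pair of weakly coupled oscillators
#'
#' Collects the hidden parameters of the synthetic generator: natural
#' frequencies of the theta-like and alpha-like sources, the phase-coupling
#' gain, the phase-diffusion noise level, source amplitudes, per-channel
#' mixing vectors, and the background-noise description. Recovery of these
#' parameters is what the analysis modules are tested against.
#'
#' @param omega_theta,omega_alpha Natural frequencies in Hz
#'   (`omega_theta < omega_alpha`).
#' @param epsilon Symmetric phase-coupling gain, rad/s (>= 0).
#' @param epsilon_t2a,epsilon_a2t Optional asymmetric gains: the influence of
#'   the theta oscillator on the alpha oscillator and vice versa. Default to
#'   `epsilon` (symmetric coupling).
#' @param phase_noise_sd Phase-diffusion standard deviation, rad/sqrt(s).
#' @param amp_theta,amp_alpha Source amplitudes (arbitrary units).
#' @param mixing_theta,mixing_alpha Per-channel mixing weight vectors; they
#'   are normalized to unit Euclidean norm. `NULL` means "use the default
#'   smooth frontal/parietal profiles for the requested channel count".
#' @param noise_exponent Spectral exponent of the 1/f background (>= 0).
#' @param snr_db Source-to-background power ratio in dB.
#' @param amp_env_freq,amp_env_depth Optional slow sinusoidal amplitude
#'   envelope (Hz, relative depth in `[0, 1)`); depth 0 disables it.
#' @param seed Integer RNG seed.
#' @return An object of class `oc_ground_truth` (a named list).
#' @export
oscillator_ground_truth <- function(omega_theta = 6, omega_alpha = 10,
                                    epsilon = 3,
                                    epsilon_t2a = NULL, epsilon_a2t = NULL,
                                    phase_noise_sd = 1.5,
                                    amp_theta = 1, amp_alpha = 1,
                                    mixing_theta = NULL, mixing_alpha = NULL,
                                    noise_exponent = 1, snr_db = 10,
                                    amp_env_freq = 0, amp_env_depth = 0,
                                    seed = 1L) {
  stopifnot_scalar_pos(omega_theta, "omega_theta")
  stopifnot_scalar_pos(omega_alpha, "omega_alpha")
  if (omega_theta >= omega_alpha) {
    abort("`omega_theta` must be strictly below `omega_alpha`.")
  }
  if (epsilon < 0) abort("`epsilon` must be >= 0.")
  if (phase_noise_sd < 0) abort("`phase_noise_sd` must be >= 0.")
  if (noise_exponent < 0) abort("`noise_exponent` must be >= 0.")
  if (amp_env_depth < 0 || amp_env_depth >= 1) {
    abort("`amp_env_depth` must be in [0, 1).")
  }
  norm_mix <- function(m, nm) {
    if (is.null(m)) return(NULL)
    if (all(m == 0)) abort(sprintf("`%s` must not be all zero.", nm))
    m / sqrt(sum(m^2))
  }
  structure(list(
    omega_theta = omega_theta, omega_alpha = omega_alpha,
    epsilon = epsilon,
    epsilon_t2a = epsilon_t2a %||% epsilon,
    epsilon_a2t = epsilon_a2t %||% epsilon,
    phase_noise_sd = phase_noise_sd,
    amp_theta = amp_theta, amp_alpha = amp_alpha,
    mixing_theta = norm_mix(mixing_theta, "mixing_theta"),
    mixing_alpha = norm_mix(mixing_alpha, "mixing_alpha"),
    noise_exponent = noise_exponent, snr_db = snr_db,
    amp_env_freq = amp_env_freq, amp_env_depth = amp_env_depth,
    seed = as.integer(seed)
  ), class = "oc_ground_truth")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Condition specification for the synthetic study
#'
#' Describes one experimental condition (e.g. pre-stimulus fixation or the
#' working-memory delay): the oscillator parameters in force during that
#' condition plus the trial structure.
#'
#' @inheritParams oscillator_ground_truth
#' @param label Condition label, e.g. `"fixation"` or `"delay"`.
#' @param n_trials Number of trials (>= 2).
#' @param trial_duration Trial duration in seconds (>= 1).
#' @return An object of class `oc_condition_spec`.
#' @export
condition_spec <- function(label,
                           omega_theta = 6, omega_alpha = 10, epsilon = 3,
                           epsilon_t2a = NULL, epsilon_a2t = NULL,
                           phase_noise_sd = 1.5,
                           amp_theta = 1, amp_alpha = 1,
                           noise_exponent = 1, snr_db = 10,
                           amp_env_freq = 0, amp_env_depth = 0,
                           n_trials = 96, trial_duration = 3) {
  if (n_trials < 2) abort("`n_trials` must be >= 2.")
  if (trial_duration < 1) abort("`trial_duration` must be >= 1 s.")
  structure(list(
    label = label,
    omega_theta = omega_theta, omega_alpha = omega_alpha,
    epsilon = epsilon,
    epsilon_t2a = epsilon_t2a %||% epsilon,
    epsilon_a2t = epsilon_a2t %||% epsilon,
    phase_noise_sd = phase_noise_sd,
    amp_theta = amp_theta, amp_alpha = amp_alpha,
    noise_exponent = noise_exponent, snr_db = snr_db,
    amp_env_freq = amp_env_freq, amp_env_depth = amp_env_depth,
    n_trials = as.integer(n_trials), trial_duration = trial_duration
  ), class = "oc_condition_spec")
}

#' Condition-labeled epoched multichannel time series
#'
#' The pipeline's universal carrier: a `trials x channels x samples` array at
#' a fixed sampling rate with one condition label per trial.
#'
#' @param data Numeric array, `trials x channels x samples`; all finite.
#' @param srate Sampling rate, Hz.
#' @param condition Character vector, one label per trial.
#' @param channel_names Optional channel names.
#' @return An object of class `oc_epochs`.
#' @export
trial_epochs <- function(data, srate, condition,
                         channel_names = NULL) {
  if (length(dim(data)) != 3L) abort("`data` must be trials x channels x samples.")
  if (!all(is.finite(data))) abort("`data` must be all finite.")
  stopifnot_scalar_pos(srate, "srate")
  if (length(condition) != dim(data)[1]) {
    abort("`condition` must have one label per trial.")
  }
  channel_names <- channel_names %||% paste0("ch", seq_len(dim(data)[2]))
  structure(list(
    data = data, srate = srate,
    condition = as.character(condition),
    channel_names = channel_names
  ), class = "oc_epochs")
}

#' @export
print.oc_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<oc_epochs> %d trials x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$srate))
  print(table(x$condition))
  invisible(x)
}

# Batched Euler-Maruyama integration of two mutually coupled phase
# oscillators; columns are independent realizations. Returns unwrapped
# phases as n_steps x n_sims matrices. Must be called inside an RNG context.
sim_phases_batch <- function(omega1, omega2, eps_on_1, eps_on_2,
                             phase_noise_sd, n_steps, dt,
                             init1, init2) {
  n_sims <- length(init1)
  th1 <- matrix(0, n_steps, n_sims)
  th2 <- matrix(0, n_steps, n_sims)
  th1[1, ] <- init1
  th2[1, ] <- init2
  w1 <- 2 * pi * omega1
  w2 <- 2 * pi * omega2
  sqdt <- sqrt(dt)
  noisy <- any(phase_noise_sd > 0)
  for (i in seq_len(n_steps - 1L)) {
    d <- th2[i, ] - th1[i, ]
    s <- sin(d)
    inc1 <- (w1 + eps_on_1 * s) * dt
    inc2 <- (w2 - eps_on_2 * s) * dt
    if (noisy) {
      inc1 <- inc1 + phase_noise_sd * sqdt * rnorm(n_sims)
      inc2 <- inc2 + phase_noise_sd * sqdt * rnorm(n_sims)
    }
    th1[i + 1L, ] <- th1[i, ] + inc1
    th2[i + 1L, ] <- th2[i, ] + inc2
  }
  list(theta1 = th1, theta2 = th2)
}

#' Simulate two weakly coupled stochastic phase oscillators
#'
#' Integrates the Kuramoto-type phase equations with additive Wiener phase
#' noise by the Euler-Maruyama scheme at `dt = 1/srate`:
#' `d(phi1) = 2*pi*omega1*dt + eps_on_1*sin(phi2 - phi1)*dt + sd*dW`, and
#' symmetrically for the second oscillator. With symmetric coupling gain
#' `epsilon` and zero noise the pair phase-locks iff
#' `epsilon >= pi * |omega2 - omega1|` (the Arnold-tongue boundary).
#'
#' @param omega1,omega2 Natural frequencies, Hz.
#' @param epsilon Symmetric coupling gain, rad/s.
#' @param phase_noise_sd Phase-diffusion SD, rad/sqrt(s).
#' @param duration Duration, s.
#' @param srate Sampling rate, Hz.
#' @param seed Integer seed; the result is a pure function of all arguments.
#' @param init_phase Initial phases (rad), length 2.
#' @param epsilon_1on2,epsilon_2on1 Optional asymmetric gains: influence of
#'   oscillator 1 on oscillator 2 and vice versa; default `epsilon`.
#' @return A list with unwrapped phase vectors `theta1`, `theta2` (rad),
#'   the time vector `t` (s) and `srate`.
#' @export
simulate_coupled_phases <- function(omega1, omega2, epsilon,
                                    phase_noise_sd = 0,
                                    duration = 10, srate = 500, seed = 1L,
                                    init_phase = c(0, 0),
                                    epsilon_1on2 = NULL, epsilon_2on1 = NULL) {
  stopifnot_scalar_pos(duration, "duration")
  stopifnot_scalar_pos(srate, "srate")
  n <- round(duration * srate)
  if (n < 2) abort("`duration * srate` must give at least 2 samples.")
  if (epsilon < 0) abort("`epsilon` must be >= 0.")
  e21 <- epsilon_2on1 %||% epsilon # influence of osc 2 on osc 1
  e12 <- epsilon_1on2 %||% epsilon # influence of osc 1 on osc 2
  out <- with_seed(seed, {
    sim_phases_batch(omega1, omega2, e21, e12, phase_noise_sd,
                     n, 1 / srate, init_phase[1], init_phase[2])
  })
  list(theta1 = drop(out$theta1), theta2 = drop(out$theta2),
       t = (seq_len(n) - 1) / srate, srate = srate)
}

#' Generate 1/f (power-law) background noise
#'
#' Spectral-synthesis method: Gaussian Fourier coefficients shaped so the
#' power spectrum follows `f^(-exponent)`, inverse-transformed to a real,
#' zero-mean, unit-variance series. `exponent = 0` gives white noise.
#'
#' @param n_samples Number of samples (>= 2).
#' @param exponent Spectral exponent (>= 0).
#' @param srate Sampling rate, Hz (affects labeling only; the series is
#'   normalized to unit variance).
#' @param seed Integer seed.
#' @return Numeric vector of length `n_samples`.
#' @export
generate_pink_noise <- function(n_samples, exponent = 1, srate = 500,
                                seed = 1L) {
  if (n_samples < 2) abort("`n_samples` must be >= 2.")
  if (exponent < 0) abort("`exponent` must be >= 0.")
  n <- as.integer(n_samples)
  with_seed(seed, {
    nf <- n %/% 2L
    f <- seq_len(nf) * srate / n
    scale <- f^(-exponent / 2)
    re <- rnorm(nf) * scale
    im <- rnorm(nf) * scale
    if (n %% 2L == 0L) im[nf] <- 0 # Nyquist bin must be real
    spec <- complex(real = re, imaginary = im)
    full <- complex(length.out = n)
    full[2:(nf + 1L)] <- spec
    full[n:(n - nf + 2L)] <- Conj(spec[seq_len(nf - 1L)])
    x <- Re(fft(full, inverse = TRUE)) / n
    x <- x - mean(x)
    x / sd(x)
  })
}

# Default smooth "frontal" / "parietal" mixing profiles: Gaussian bumps over
# the channel axis, centred at 30% and 70% of the array, unit norm.
default_mixing <- function(n_channels) {
  pos <- seq_len(n_channels)
  bump <- function(center) {
    w <- exp(-0.5 * ((pos - center) / (0.2 * n_channels))^2)
    w / sqrt(sum(w^2))
  }
  list(theta = bump(0.3 * (n_channels + 1)),
       alpha = bump(0.7 * (n_channels + 1)))
}

#' Render sensor-level trials from coupled phase oscillators
#'
#' Forward model: each trial is the sum of the two cosine sources projected
#' through their mixing vectors plus 1/f background noise scaled to the
#' requested source-to-background power ratio.
#'
#' @param ground_truth An [oscillator_ground_truth()] object, or `NULL` to
#'   build one from `spec`.
#' @param spec A [condition_spec()] giving trial structure and any parameter
#'   overrides.
#' @param n_channels Number of sensors (>= 2).
#' @param srate Sampling rate, Hz.
#' @param seed Integer seed (defaults to the ground truth's seed).
#' @return A list with `epochs` (an [trial_epochs()] object) and
#'   `ground_truth` (the parameters actually used, mixing vectors included).
#' @export
render_sensor_trials <- function(ground_truth = NULL, spec, n_channels = 8,
                                 srate = 500, seed = NULL) {
  if (n_channels < 2) abort("`n_channels` must be >= 2.")
  gt <- ground_truth %||% oscillator_ground_truth(
    omega_theta = spec$omega_theta, omega_alpha = spec$omega_alpha,
    epsilon = spec$epsilon,
    epsilon_t2a = spec$epsilon_t2a, epsilon_a2t = spec$epsilon_a2t,
    phase_noise_sd = spec$phase_noise_sd,
    amp_theta = spec$amp_theta, amp_alpha = spec$amp_alpha,
    noise_exponent = spec$noise_exponent, snr_db = spec$snr_db,
    amp_env_freq = spec$amp_env_freq, amp_env_depth = spec$amp_env_depth
  )
  mix <- default_mixing(n_channels)
  mt <- gt$mixing_theta %||% mix$theta
  ma <- gt$mixing_alpha %||% mix$alpha
  if (length(mt) != n_channels || length(ma) != n_channels) {
    abort("Mixing vectors must match `n_channels`.")
  }
  if (all(mt == 0) || all(ma == 0)) abort("Degenerate all-zero mixing vector.")
  gt$mixing_theta <- mt
  gt$mixing_alpha <- ma
  seed <- seed %||% gt$seed
  gt$seed <- as.integer(seed)

  n_trials <- spec$n_trials
  n_samp <- round(spec$trial_duration * srate)
  tvec <- (seq_len(n_samp) - 1) / srate
  env <- if (gt$amp_env_depth > 0) {
    1 + gt$amp_env_depth * sin(2 * pi * gt$amp_env_freq * tvec)
  } else {
    rep(1, n_samp)
  }

  with_seed(seed, {
    init_t <- runif(n_trials, -pi, pi)
    init_a <- runif(n_trials, -pi, pi)
    ph <- sim_phases_batch(gt$omega_theta, gt$omega_alpha,
                           gt$epsilon_a2t, gt$epsilon_t2a,
                           gt$phase_noise_sd, n_samp, 1 / srate,
                           init_t, init_a)
    # sources: n_samp x n_trials
    st <- gt$amp_theta * env * cos(ph$theta1)
    sa <- gt$amp_alpha * env * cos(ph$theta2)
    dat <- array(0, dim = c(n_trials, n_channels, n_samp))
    for (ch in seq_len(n_channels)) {
      dat[, ch, ] <- t(mt[ch] * st + ma[ch] * sa)
    }
    p_sig <- mean(dat^2)
    noise_scale <- if (p_sig > 0) sqrt(p_sig / 10^(gt$snr_db / 10)) else 1
    for (tr in seq_len(n_trials)) {
      for (ch in seq_len(n_channels)) {
        nz <- generate_pink_noise(n_samp, gt$noise_exponent, srate,
                                  seed = sample.int(2^31 - 2, 1))
        dat[tr, ch, ] <- dat[tr, ch, ] + noise_scale * nz
      }
    }
    list(
      epochs = trial_epochs(dat, srate, rep(spec$label, n_trials)),
      ground_truth = gt,
      phases = ph
    )
  })
}

#' Generate a multi-subject two-condition synthetic study
#'
#' Renders per-subject epoched data for a fixation and a delay condition,
#' with subject-level jitter of natural frequencies and coupling gain so
#' paired statistics have realistic between-subject variance. Per-subject
#' seeds are derived from `master_seed` by a splittable hash, so subject k's
#' data do not depend on how many subjects are generated.
#'
#' @param fixation,delay [condition_spec()] objects for the two conditions
#'   (equal `trial_duration` required so trials share a sample grid).
#' @param n_subjects Number of subjects (>= 2).
#' @param master_seed Integer master seed.
#' @param n_channels Number of sensors.
#' @param srate Sampling rate, Hz.
#' @param jitter_freq_sd Between-subject SD of natural frequencies, Hz.
#' @param jitter_eps_rel Relative half-range of the subject coupling-gain
#'   multiplier (uniform in `1 +/- jitter_eps_rel`).
#' @return An object of class `oc_study`: a list of subjects, each holding
#'   `epochs` (both conditions), per-condition `ground_truth`, and the
#'   subject seed.
#' @export
make_study_dataset <- function(fixation, delay, n_subjects = 26,
                               master_seed = 1L, n_channels = 8,
                               srate = 500,
                               jitter_freq_sd = 0.3, jitter_eps_rel = 0.2) {
  if (n_subjects < 2) abort("`n_subjects` must be >= 2 (paired tests undefined).")
  if (fixation$trial_duration != delay$trial_duration) {
    abort("Conditions must share `trial_duration`.")
  }
  subjects <- lapply(seq_len(n_subjects), function(s) {
    seed_s <- derive_seed(master_seed, s)
    jit <- with_seed(seed_s, {
      list(dft = rnorm(1, 0, jitter_freq_sd),
           dfa = rnorm(1, 0, jitter_freq_sd),
           em = runif(1, 1 - jitter_eps_rel, 1 + jitter_eps_rel))
    })
    apply_jit <- function(spec) {
      spec$omega_theta <- spec$omega_theta + jit$dft
      spec$omega_alpha <- spec$omega_alpha + jit$dfa
      spec$epsilon <- spec$epsilon * jit$em
      spec$epsilon_t2a <- spec$epsilon_t2a * jit$em
      spec$epsilon_a2t <- spec$epsilon_a2t * jit$em
      spec
    }
    fx <- apply_jit(fixation)
    dl <- apply_jit(delay)
    rf <- render_sensor_trials(NULL, fx, n_channels, srate,
                               seed = derive_seed(seed_s, 101))
    rd <- render_sensor_trials(NULL, dl, n_channels, srate,
                               seed = derive_seed(seed_s, 102))
    dat <- array(0, dim = c(fx$n_trials + dl$n_trials, n_channels,
                            dim(rf$epochs$data)[3]))
    dat[seq_len(fx$n_trials), , ] <- rf$epochs$data
    dat[fx$n_trials + seq_len(dl$n_trials), , ] <- rd$epochs$data
    epochs <- trial_epochs(dat, srate,
                           c(rf$epochs$condition, rd$epochs$condition))
    list(id = s, epochs = epochs,
         ground_truth = list(fixation = rf$ground_truth,
                             delay = rd$ground_truth),
         seed = seed_s)
  })
  structure(list(subjects = subjects, master_seed = as.integer(master_seed),
                 fixation = fixation, delay = delay),
            class = "oc_study")
}

#' @export
print.oc_study <- function(x, ...) {
  cat(sprintf("<oc_study> %d subjects, conditions: %s / %s\n",
              length(x$subjects), x$fixation$label, x$delay$label))
  invisible(x)
}
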