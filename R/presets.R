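#' Condition presets for the synthetic working-memory study
#'
#' `study_preset()` encodes the qualitative physiology the analysis is
#' designed to detect: relative to fixation, the working-memory delay has a
#' higher alpha natural frequency, a lower theta natural frequency (pushing
#' the alpha:theta ratio from ~1.2 toward ~2), a weaker phase-coupling gain
#' (hence larger detuning, lower phase locking and lower directed/shared
#' information), a larger theta amplitude and a smaller alpha amplitude.
#' `null_preset()` uses the fixation parameters for both conditions, so
#' every paired contrast has expectation zero.
#'
#' @param n_trials Trials per condition.
#' @param trial_duration Trial duration, s.
#' @param snr_db Source-to-background power ratio, dB.
#' @param phase_noise_sd Phase-diffusion SD, rad/sqrt(s).
#' @return A list with [condition_spec()] elements `fixation` and `delay`.
#' @export
study_preset <- function(n_trials = 96, trial_duration = 3, snr_db = 10,
                         phase_noise_sd = 1.5) {
  list(
    fixation = condition_spec(
      label = "fixation",
      omega_theta = 7.0, omega_alpha = 8.8, epsilon = 4,
      phase_noise_sd = phase_noise_sd,
      amp_theta = 1.0, amp_alpha = 1.4,
      snr_db = snr_db, n_trials = n_trials, trial_duration = trial_duration
    ),
    delay = condition_spec(
      label = "delay",
      omega_theta = 5.6, omega_alpha = 10.9, epsilon = 1.5,
      phase_noise_sd = phase_noise_sd,
      amp_theta = 1.3, amp_alpha = 1.0,
      snr_db = snr_db, n_trials = n_trials, trial_duration = trial_duration
    )
  )
}

#' @rdname study_preset
#' @export
null_preset <- function(n_trials = 96, trial_duration = 3, snr_db = 10,
                        phase_noise_sd = 1.5) {
  p <- study_preset(n_trials, trial_duration, snr_db, phase_noise_sd)
  d <- p$fixation
  d$label <- "delay"
  list(fixation = p$fixation, delay = d)
}
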