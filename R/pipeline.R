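#' Pipeline run configuration
#'
#' Bundles every tunable of the analysis chain with its default. The
#' configuration serializes losslessly to JSON and a hash of it is embedded
#' in the results bundle, so a bundle can always be traced to the exact
#' settings that produced it.
#'
#' @param seed Master seed for every source of randomness in the run.
#' @param n_subjects Number of synthetic subjects.
#' @param n_channels Number of sensors.
#' @param srate Sampling rate, Hz.
#' @param conditions A list with [condition_spec()] elements `fixation` and
#'   `delay` (e.g. from [study_preset()]).
#' @param bands Named list of analysis bands, Hz.
#' @param ssd SSD settings: flank width, transition, shrinkage, template
#'   threshold, whether to gate with the ground-truth mixing pattern.
#' @param sg Savitzky-Golay settings for instantaneous frequency.
#' @param plv Sliding-window PLV settings (ms).
#' @param prc Phase-response-curve settings.
#' @param stft Spectrogram settings for the ratio analysis.
#' @param it Information-theory settings (bins, lags, decimated rate).
#' @param stats FDR level and effect-size convention.
#' @param behavior Parameters of the simulated behavioral accuracy:
#'   `accuracy = intercept + plv_coef * z(PLV_delay) + N(0, noise_sd)`.
#' @param jitter Between-subject parameter jitter.
#' @return An object of class `oc_config`.
#' @export
oc_config <- function(seed = 1L, n_subjects = 26, n_channels = 8,
                      srate = 500,
                      conditions = study_preset(),
                      bands = list(theta = c(4, 8), alpha = c(8, 14)),
                      ssd = list(flank_width = 2, transition = 1,
                                 shrinkage = 0.05, template_threshold = 0.7,
                                 use_truth_template = TRUE),
                      sg = list(order = 3, window = 51),
                      plv = list(window_ms = 300, step_ms = 50, ratio_k = 1),
                      prc = list(n_bins = 24, smooth_window = 3,
                                 spline_penalty = NULL),
                      stft = list(window_s = 1, hop_s = 0.1,
                                  fmin = 1, fmax = 30, df = 0.1),
                      it = list(n_bins = 4, lags = 1:20, srate_it = 250),
                      stats = list(q = 0.05),
                      behavior = list(intercept = 0.75, plv_coef = -0.15,
                                      noise_sd = 0.05),
                      jitter = list(freq_sd = 0.3, eps_rel = 0.2)) {
  cfg <- list(seed = as.integer(seed), n_subjects = n_subjects,
              n_channels = n_channels, srate = srate,
              conditions = conditions, bands = bands, ssd = ssd, sg = sg,
              plv = plv, prc = prc, stft = stft, it = it, stats = stats,
              behavior = behavior, jitter = jitter)
  structure(cfg, class = "oc_config")
}

#' @export
print.oc_config <- function(x, ...) {
  cat(sprintf("<oc_config> seed %d, %d subjects, %d channels @ %g Hz (hash %s)\n",
              x$seed, x$n_subjects, x$n_channels, x$srate,
              substr(config_hash(x), 1, 8)))
  invisible(x)
}

#' Hash of a run configuration
#' @param config An `oc_config`.
#' @return Character hash.
#' @export
config_hash <- function(config) rlang::hash(unclass(config))

#' Analyze one subject's epoched recording
#'
#' Runs the full per-subject chain on a two-condition [trial_epochs()]
#' object: SSD extraction and component selection per band, zero-phase
#' band-pass filtering, analytic traces, sliding-window PLV, the
#' phase-response curve with detuning and coupling strength, transient
#' spectral-peak ratio occurrence, and information-theoretic connectivity.
#'
#' @param epochs An [trial_epochs()] with both condition labels.
#' @param config An [oc_config()].
#' @param templates Optional list with channel-weight templates `theta` and
#'   `alpha` for component selection (e.g. ground-truth mixing vectors);
#'   `NULL` selects by SNR alone.
#' @param subject Subject identifier carried into the outputs.
#' @return A list with tibbles `metrics` (one row per condition) and
#'   `ratio_occurrence` (long, per condition x ratio bin), plus the
#'   selected components and PRC objects.
#' @export
analyze_subject <- function(epochs, config = oc_config(), templates = NULL,
                            subject = 1L) {
  srate <- epochs$srate
  conds <- unique(epochs$condition)

  extract <- function(band_name, label) {
    band <- config$bands[[band_name]]
    filt <- compute_ssd(epochs, band,
                        flank_width = config$ssd$flank_width,
                        transition = config$ssd$transition,
                        shrinkage = config$ssd$shrinkage)
    select_component(filt, epochs,
                     template_pattern = templates[[band_name]],
                     threshold = config$ssd$template_threshold,
                     label = label)
  }
  comp_t <- extract("theta", "frontal_theta")
  comp_a <- extract("alpha", "parietal_alpha")

  filt_t <- bandpass_zero_phase(comp_t, config$bands$theta)
  filt_a <- bandpass_zero_phase(comp_a, config$bands$alpha)
  tr_t <- analytic_trace(filt_t, config$sg$order, config$sg$window)
  tr_a <- analytic_trace(filt_a, config$sg$order, config$sg$window)

  frames_t <- spectrogram_highres(comp_t, config$stft$window_s,
                                  config$stft$hop_s, config$stft$fmin,
                                  config$stft$fmax, config$stft$df)
  frames_a <- spectrogram_highres(comp_a, config$stft$window_s,
                                  config$stft$hop_s, config$stft$fmin,
                                  config$stft$fmax, config$stft$df)
  trend_t <- fit_aperiodic_trend(frames_t)
  trend_a <- fit_aperiodic_trend(frames_a)
  peaks_t <- detect_band_peaks(frames_t, config$bands$theta, trend_t)
  peaks_a <- detect_band_peaks(frames_a, config$bands$alpha, trend_a)

  metrics <- list()
  occ <- list()
  prcs <- list()
  for (cond in conds) {
    idx <- epochs$condition == cond
    tt <- subset_trials(tr_t, idx)
    ta <- subset_trials(tr_a, idx)
    plv <- compute_plv(tt, ta, config$plv$ratio_k,
                       config$plv$window_ms, config$plv$step_ms)
    prc <- estimate_prc(tt, ta,
                        smooth_window = config$prc$smooth_window,
                        spline_penalty = config$prc$spline_penalty,
                        n_bins = config$prc$n_bins)
    prcs[[cond]] <- prc
    fsel <- frames_t$condition == cond
    ro <- ratio_occurrence(peaks_a[fsel], peaks_t[fsel])
    occ[[cond]] <- dplyr::mutate(tibble::as_tibble(ro),
                                 subject = subject, condition = cond,
                                 .before = 1)
    it <- it_metrics(filt_t$series[idx, , drop = FALSE],
                     filt_a$series[idx, , drop = FALSE],
                     srate, valid = tr_t$valid & tr_a$valid,
                     n_bins = config$it$n_bins, lags = config$it$lags,
                     srate_it = config$it$srate_it)
    mean_ratio <- if (attr(ro, "n_frames_with_ratio") > 0) {
      sum(ro$ratio_bin * ro$percent) / 100
    } else {
      NA_real_
    }
    metrics[[cond]] <- tibble(
      subject = subject, condition = cond,
      plv = plv$condition_mean,
      detuning = prc$detuning,
      detuning_spline = prc$detuning_spline,
      coupling_strength = prc$coupling_strength,
      mi = it$mi, te_a2p = it$te_a2p, te_p2a = it$te_p2a,
      theta_freq = mean(tt$ifreq[, tt$valid]),
      alpha_freq = mean(ta$ifreq[, ta$valid]),
      theta_amp = mean(tt$amplitude[, tt$valid]),
      alpha_amp = mean(ta$amplitude[, ta$valid]),
      mean_ratio = mean_ratio,
      theta_snr = comp_t$snr, alpha_snr = comp_a$snr
    )
  }
  list(metrics = dplyr::bind_rows(metrics),
       ratio_occurrence = dplyr::bind_rows(occ),
       components = list(theta = comp_t, alpha = comp_a),
       prc = prcs)
}

# paired-contrast metrics, delay minus fixation
.oc_contrast_metrics <- c("plv", "detuning", "detuning_spline",
                          "coupling_strength", "mi", "te_a2p", "te_p2a",
                          "theta_freq", "alpha_freq", "theta_amp",
                          "alpha_amp", "mean_ratio")

#' Run the full synthetic study pipeline
#'
#' Simulates the study dataset, extracts components and computes every
#' metric per subject and condition, then performs the group-level layer:
#' paired t tests (delay minus fixation) with Cohen's d and FDR correction
#' over the metric family, per-bin ratio-occurrence comparisons, and the
#' BIC stepwise regression of simulated behavioral accuracy on the
#' delay-period metrics. Identical configuration and seed reproduce the
#' bundle exactly.
#'
#' @param config An [oc_config()].
#' @param progress Emit per-stage messages.
#' @return An object of class `oc_results`: tibbles `subjects`,
#'   `ratio_occurrence`, `group_tests`, `ratio_bin_tests`, `behavior`; the
#'   `regression` (`oc_stepwise`); `config` and `config_hash`.
#' @export
run_pipeline <- function(config = oc_config(), progress = TRUE) {
  say <- function(...) if (progress) message(sprintf(...))
  say("simulate: %d subjects, seed %d", config$n_subjects, config$seed)
  study <- make_study_dataset(config$conditions$fixation,
                              config$conditions$delay,
                              n_subjects = config$n_subjects,
                              master_seed = config$seed,
                              n_channels = config$n_channels,
                              srate = config$srate,
                              jitter_freq_sd = config$jitter$freq_sd,
                              jitter_eps_rel = config$jitter$eps_rel)
  res <- vector("list", config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    subj <- study$subjects[[s]]
    templates <- if (isTRUE(config$ssd$use_truth_template)) {
      list(theta = subj$ground_truth$fixation$mixing_theta,
           alpha = subj$ground_truth$fixation$mixing_alpha)
    } else {
      NULL
    }
    res[[s]] <- tryCatch(
      analyze_subject(subj$epochs, config, templates, subject = subj$id),
      error = function(e) {
        abort(sprintf("Subject %d failed: %s", subj$id, conditionMessage(e)),
              parent = e)
      })
    say("analyze: subject %d/%d done", s, config$n_subjects)
  }
  subjects <- purrr::list_rbind(purrr::map(res, "metrics"))
  occurrence <- purrr::list_rbind(purrr::map(res, "ratio_occurrence"))

  say("group statistics")
  wide <- subjects |>
    dplyr::select("subject", "condition",
                  dplyr::all_of(.oc_contrast_metrics)) |>
    tidyr::pivot_longer(dplyr::all_of(.oc_contrast_metrics),
                        names_to = "metric") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "value")
  group_tests <- wide |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(
      paired_ttest_with_d(.data$delay, .data$fixation),
      .groups = "drop"
    )
  group_tests$p_adj <- p.adjust(group_tests$p, method = "BH")

  ratio_bin_tests <- compare_ratio_bins(occurrence,
                                        conditions = c("delay", "fixation"),
                                        q = config$stats$q)

  say("behavior and stepwise regression")
  delay_metrics <- subjects |>
    dplyr::filter(.data$condition == "delay") |>
    dplyr::arrange(.data$subject)
  beh_seed <- derive_seed(config$seed, 9001)
  plv_z <- as.numeric(scale(delay_metrics$plv))
  accuracy <- with_seed(beh_seed, {
    config$behavior$intercept + config$behavior$plv_coef * plv_z +
      rnorm(nrow(delay_metrics), 0, config$behavior$noise_sd)
  })
  behavior <- tibble(subject = delay_metrics$subject, accuracy = accuracy)
  predictors <- delay_metrics |>
    dplyr::select("plv", "detuning", "coupling_strength", "mean_ratio",
                  "alpha_freq", "theta_freq", "te_a2p", "te_p2a", "mi")
  regression <- if (config$n_subjects > 3) {
    stepwise_bic(accuracy, predictors)
  } else {
    say("too few subjects for the stepwise stage; skipping regression")
    NULL
  }

  structure(list(
    subjects = subjects, ratio_occurrence = occurrence,
    group_tests = group_tests, ratio_bin_tests = ratio_bin_tests,
    behavior = behavior, regression = regression,
    config = config, config_hash = config_hash(config)
  ), class = "oc_results")
}

#' @export
print.oc_results <- function(x, ...) {
  cat(sprintf("<oc_results> %d subjects (config %s)\n",
              length(unique(x$subjects$subject)), substr(x$config_hash, 1, 8)))
  print(x$group_tests, n = Inf)
  invisible(x)
}

#' Write a results bundle to JSON
#'
#' Serializes the tabular results (with the configuration hash embedded) to
#' a machine-readable JSON file; identical configuration and seed produce a
#' byte-identical file.
#'
#' @param results An `oc_results`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
results_to_json <- function(results, path) {
  payload <- list(
    config_hash = results$config_hash,
    seed = results$config$seed,
    subjects = results$subjects,
    ratio_occurrence = results$ratio_occurrence,
    group_tests = results$group_tests,
    ratio_bin_tests = results$ratio_bin_tests,
    behavior = results$behavior,
    regression = if (!is.null(results$regression)) {
      list(selected = results$regression$selected,
           coefficients = results$regression$coefficients,
           bic = results$regression$bic,
           r2 = results$regression$r2)
    }
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
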