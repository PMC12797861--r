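#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a phase-response curve
#'
#' One row per phase bin with its occupancy, raw median frequency
#' difference and circularly smoothed value.
#'
#' @param x An `oc_prc`.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.oc_prc <- function(x, ...) {
  tibble(
    bin_center = x$bin_centers,
    n_obs = x$n_obs_per_bin,
    median_dfreq = x$bin_median_dfreq,
    smoothed = x$smoothed
  )
}

#' One-row summary of a phase-response curve
#'
#' @param x An `oc_prc`.
#' @param ... Unused.
#' @return A tibble with detuning (bin-median and spline conventions),
#'   coupling strength and bin coverage.
#' @exportS3Method generics::glance
glance.oc_prc <- function(x, ...) {
  tibble(
    detuning = x$detuning,
    detuning_spline = x$detuning_spline,
    coupling_strength = x$coupling_strength,
    n_bins = x$n_bins,
    n_bins_occupied = sum(x$n_obs_per_bin > 0),
    n_obs = sum(x$n_obs_per_bin)
  )
}

#' Tidy a stepwise regression fit
#'
#' @param x An `oc_stepwise`.
#' @param ... Unused.
#' @return A tibble of standardized coefficients with `se`, `t`, `p`.
#' @exportS3Method generics::tidy
tidy.oc_stepwise <- function(x, ...) x$coefficients

#' One-row summary of a stepwise regression fit
#'
#' @param x An `oc_stepwise`.
#' @param ... Unused.
#' @return A tibble with the selected predictors, BIC and R^2.
#' @exportS3Method generics::glance
glance.oc_stepwise <- function(x, ...) {
  tibble(
    n_selected = length(x$selected),
    selected = paste(x$selected, collapse = "+"),
    bic = x$bic,
    r2 = x$r2
  )
}

#' Tidy a phase-locking result
#'
#' @param x An `oc_plv`.
#' @param ... Unused.
#' @return A tibble with one row per trial.
#' @exportS3Method generics::tidy
tidy.oc_plv <- function(x, ...) {
  tibble(trial = seq_along(x$per_trial), plv = x$per_trial)
}
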