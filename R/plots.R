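#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_col
#'   geom_hline geom_tile labs scale_fill_viridis_c theme_minimal
#' @export
ggplot2::autoplot

#' Plot a phase-response curve
#'
#' Bin medians, the smoothed curve and the fitted spline, with the detuning
#' level drawn as a horizontal line; the peak-to-trough range of the spline
#' is the coupling strength.
#'
#' @param object An `oc_prc`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.oc_prc <- function(object, ...) {
  bins <- tidy(object)
  spl <- tibble(dphi = object$spline_grid, dfreq = object$spline_values)
  ggplot(bins, aes(x = .data$bin_center, y = .data$median_dfreq)) +
    geom_point(na.rm = TRUE, colour = "grey40") +
    geom_line(data = spl, aes(x = .data$dphi, y = .data$dfreq),
              colour = "firebrick", linewidth = 0.8) +
    geom_hline(yintercept = object$detuning, linetype = "dashed") +
    labs(x = "phase difference (rad)", y = "frequency difference (Hz)",
         title = sprintf("PRC: detuning %.2f Hz, coupling strength %.2f Hz",
                         object$detuning, object$coupling_strength)) +
    theme_minimal()
}

#' Plot a ratio-occurrence distribution
#'
#' @param object An `oc_ratio_occ` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.oc_ratio_occ <- function(object, ...) {
  ggplot(object, aes(x = .data$ratio_bin, y = .data$percent)) +
    geom_col(fill = "steelblue") +
    labs(x = "alpha:theta frequency ratio", y = "occurrence (%)") +
    theme_minimal()
}

#' Heatmap of phase locking over the coupling-by-detuning plane
#'
#' Renders the Arnold tongue measured by [arnold_tongue_grid()]: phase
#' locking grows with coupling gain and shrinks with absolute detuning.
#'
#' @param grid Tibble from [arnold_tongue_grid()].
#' @return A ggplot.
#' @export
plot_arnold_tongue <- function(grid) {
  ggplot(grid, aes(x = .data$detuning, y = .data$epsilon,
                   fill = .data$plv)) +
    geom_tile() +
    scale_fill_viridis_c(name = "PLV", limits = c(0, 1)) +
    labs(x = "detuning (Hz)", y = "coupling gain (rad/s)") +
    theme_minimal()
}

#' Paired per-subject metric plot across conditions
#'
#' @param results An `oc_results` bundle.
#' @param metric Metric column of `results$subjects` to draw.
#' @return A ggplot with one line per subject.
#' @export
plot_condition_metric <- function(results, metric = "plv") {
  ggplot(results$subjects,
         aes(x = .data$condition, y = .data[[metric]],
             group = .data$subject)) +
    geom_line(colour = "grey60") +
    geom_point() +
    labs(y = metric) +
    theme_minimal()
}
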