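#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point
#'   geom_errorbar facet_wrap facet_grid labs theme_minimal
#'   position_dodge geom_hline
#' @export
ggplot2::autoplot

#' Plot motion traces
#'
#' Displacement against time for every fraction, one panel per axis; traces
#' are drawn per fraction with light transparency so cohort-level structure
#' (drift, excursions) is visible.
#'
#' @param object A motion cohort.
#' @param max_fractions Cap on the number of fractions drawn (default 50).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot motion_cohort
#' @export
autoplot.motion_cohort <- function(object, max_fractions = 50, ...) {
  keep <- dplyr::distinct(object, .data$patient_id, .data$fraction_id) |>
    head(max_fractions)
  df <- dplyr::semi_join(tibble::as_tibble(object), keep,
                         by = c("patient_id", "fraction_id")) |>
    tidyr::pivot_longer(dplyr::all_of(unname(.axis_cols)),
                        names_to = "axis", values_to = "disp_mm")
  df$axis <- factor(names(.axis_cols)[match(df$axis, .axis_cols)],
                    levels = .axes)
  ggplot(df, aes(x = .data$time_s, y = .data$disp_mm,
                 group = interaction(.data$patient_id, .data$fraction_id))) +
    geom_line(alpha = 0.3) +
    facet_wrap(~axis, ncol = 1) +
    labs(x = "Time from monitoring start [s]", y = "Displacement [mm]") +
    theme_minimal()
}

#' Plot the time-resolved mean absolute displacement
#'
#' @param curve Output of [mean_abs_curve()].
#' @return A ggplot object.
#' @export
plot_mean_abs_curve <- function(curve) {
  ggplot(curve, aes(x = .data$time_bin_s, y = .data$mean_abs_mm,
                    colour = .data$axis)) +
    geom_line() +
    labs(x = "Time from monitoring start [s]",
         y = "Mean |displacement| [mm]", colour = "Axis") +
    theme_minimal()
}

#' Plot per-patient maxima
#'
#' Per-patient mean of the per-fraction maximum absolute displacements with
#' +-1 SD bars, by axis and technique.
#'
#' @param patient_summaries Output of [summarize_patients()].
#' @return A ggplot object.
#' @export
plot_patient_maxima <- function(patient_summaries) {
  ggplot(patient_summaries,
         aes(x = .data$patient_id, y = .data$mean_of_max_mm,
             colour = .data$technique)) +
    geom_point() +
    geom_errorbar(aes(ymin = pmax(.data$mean_of_max_mm - .data$sd_of_max_mm,
                                  0),
                      ymax = .data$mean_of_max_mm + .data$sd_of_max_mm),
                  width = 0.3) +
    facet_wrap(~axis, ncol = 1) +
    labs(x = "Patient", y = "Max |displacement| per fraction [mm]") +
    theme_minimal()
}

#' Plot variance components with confidence intervals
#'
#' @param object A `variance_components` table.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot variance_components
#' @export
autoplot.variance_components <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$axis, y = .data$estimate,
                 colour = .data$estimator)) +
    geom_point(position = position_dodge(width = 0.4)) +
    geom_errorbar(aes(ymin = .data$conf.low, ymax = .data$conf.high),
                  width = 0.2, position = position_dodge(width = 0.4),
                  na.rm = TRUE) +
    geom_hline(yintercept = 0, linetype = 3) +
    facet_wrap(~term, scales = "free_y") +
    labs(x = "Axis", y = "Estimate [mm]") +
    theme_minimal()
}
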