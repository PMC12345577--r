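# ggplot2 views of the main result types.

#' Plot weekday daily-activity trends by arm
#'
#' Arm-mean weekday daily totals over study day with per-arm linear trend
#' lines — the daily-activity trend view.
#'
#' @param daily Daily totals (from [daily_totals()] or
#'   [simulate_daily_totals()]).
#' @param weekdays_only Drop weekends first.
#' @return A ggplot object.
#' @export
plot_daily_activity <- function(daily, weekdays_only = TRUE) {
  if (weekdays_only) {
    if ("weekday" %in% names(daily)) daily <- daily[daily$weekday, ]
    else if ("date" %in% names(daily)) daily <- filter_weekdays(daily)
  }
  by_day <- daily |>
    dplyr::group_by(.data$arm, .data$study_day) |>
    dplyr::summarise(m = mean(.data$total), .groups = "drop")
  ggplot2::ggplot(by_day, ggplot2::aes(.data$study_day, .data$m,
                                       colour = .data$arm)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE) +
    ggplot2::labs(x = "Study day", y = "Daily activity (units)",
                  colour = "Arm",
                  title = "Weekday daily activity by arm") +
    ggplot2::theme_minimal()
}

#' Plot daytime composition change by arm
#'
#' Per-dog supplement-minus-baseline changes of the daytime composition
#' fractions, in percentage points.
#'
#' @param comp_deltas Output of [composition_phase_deltas()].
#' @return A ggplot object.
#' @export
plot_composition_deltas <- function(comp_deltas) {
  long <- comp_deltas |>
    tidyr::pivot_longer(dplyr::starts_with("d_"), names_to = "class",
                        names_prefix = "d_", values_to = "delta_pp")
  long$class <- factor(long$class, levels = c("sleep", "low", "moderate", "high"))
  ggplot2::ggplot(long, ggplot2::aes(.data$class, .data$delta_pp,
                                     fill = .data$arm)) +
    ggplot2::geom_boxplot(outlier.alpha = 0.4) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "Activity class", y = "Change (percentage points)",
                  fill = "Arm",
                  title = "Daytime (06:00–22:00) composition change from baseline") +
    ggplot2::theme_minimal()
}

#' Plot sleep-onset / wake drift
#'
#' Detected event times against study day with per-arm regression lines;
#' the slope is the drift in minutes/day.
#'
#' @param events Output of [detect_sleep_events()] with an `arm` column.
#' @param event `"onset"` or `"wake"`.
#' @param baseline_days Baseline length; marked with a vertical line.
#' @return A ggplot object.
#' @export
plot_drift <- function(events, event = c("onset", "wake"), baseline_days = 7) {
  event <- match.arg(event)
  col <- paste0(event, "_time")
  dat <- events[!is.na(events[[col]]), ]
  ggplot2::ggplot(dat, ggplot2::aes(.data$study_day, .data[[col]] / 60,
                                    colour = .data$arm)) +
    ggplot2::geom_point(alpha = 0.3) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x) +
    ggplot2::geom_vline(xintercept = baseline_days - 0.5, colour = "red",
                        linetype = 2) +
    ggplot2::labs(x = "Study day", y = sprintf("%s time (hour of day)", event),
                  colour = "Arm",
                  title = sprintf("%s-time drift over the study",
                                  if (event == "onset") "Sleep-onset" else "Wake")) +
    ggplot2::theme_minimal()
}

#' Plot post-departure settling by arm and phase
#'
#' @param settling Output of [settling_index()] with an `arm` column.
#' @return A ggplot object.
#' @export
plot_settling <- function(settling) {
  ggplot2::ggplot(settling, ggplot2::aes(.data$phase, .data$settling_pct,
                                         fill = .data$arm)) +
    ggplot2::geom_boxplot(outlier.alpha = 0.4) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "Phase", y = "Settling index (% change, hour 2 vs 1)",
                  fill = "Arm",
                  title = "Post-departure settling (08:00–10:00)") +
    ggplot2::theme_minimal()
}
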