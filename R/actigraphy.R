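# Sensor-side feature extraction: weekday filtering, daily totals, daytime
# activity composition, sleep onset / wake detection, drift regressions,
# morning activity, and the post-departure settling index.
#
# Conventions (documented because boundaries matter):
#  * "below threshold" is strict (< light), "exceeding" is non-strict
#    (>= light), mirroring the definitions of sleep onset and wake;
#  * onset search runs 19:00-23:59 and never crosses midnight; nights with
#    no qualifying window yield NA;
#  * a missing minute inside a candidate window disqualifies the window
#    (conservative: gaps never fabricate sleep).

#' Remove weekend samples from a trace or daily table
#'
#' Weekend activity runs systematically higher (owner availability), so all
#' trend and endpoint analyses operate on weekdays. Works on any tibble with
#' a `date` column; `study_day` indices are preserved.
#'
#' @param x Tibble with a `date` column (e.g. an `activity_trace` or the
#'   output of [daily_totals()]).
#' @return `x` without Saturday/Sunday rows. If nothing remains the result
#'   is empty and carries attribute `all_weekend = TRUE`.
#' @export
#' @examples
#' cfg <- trial_config(seed = 1)
#' daily <- simulate_daily_totals(cfg)
#' nrow(filter_weekdays(daily)) < nrow(daily)
filter_weekdays <- function(x) {
  stopifnot("date" %in% names(x))
  keep <- !(format(x$date, "%u") %in% c("6", "7"))
  out <- x[keep, ]
  if (nrow(out) == 0 && nrow(x) > 0) attr(out, "all_weekend") <- TRUE
  out
}

#' Daily activity totals from a minute trace
#'
#' Sums minute activity per dog and study day. Days with no samples are
#' absent (never reported as zero); partially observed days are flagged via
#' `n_minutes`.
#'
#' @param trace An `activity_trace` tibble (minute rows).
#' @return Tibble: `dog_id` (, `arm`), `study_day`, `date`, `weekday`,
#'   `phase`, `total`, `n_minutes`.
#' @export
daily_totals <- function(trace) {
  stopifnot(all(c("dog_id", "study_day", "activity") %in% names(trace)))
  grp <- intersect(c("dog_id", "arm", "study_day", "date", "phase"),
                   names(trace))
  out <- trace |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(total = sum(.data$activity),
                     n_minutes = dplyr::n(), .groups = "drop")
  if ("date" %in% names(out)) {
    out$weekday <- !(format(out$date, "%u") %in% c("6", "7"))
  }
  out
}

#' Daytime activity composition
#'
#' Classifies each minute of the daytime window (default 06:00-22:00) as
#' sleep (below the light threshold), low, moderate or high activity, and
#' returns per-dog, per-day fractions (summing to 1 over classified
#' minutes). Use [composition_phase_deltas()] for the
#' supplement-minus-baseline change in percentage points.
#'
#' @param trace An `activity_trace` tibble.
#' @param thresholds An [activity_thresholds()] object.
#' @param window Daytime window in minutes after midnight, default
#'   `c(360, 1320)` (06:00 inclusive to 22:00 exclusive).
#' @return Tibble: `dog_id` (, `arm`), `study_day`, `phase`, `f_sleep`,
#'   `f_low`, `f_moderate`, `f_high`, `n_minutes`.
#' @export
#' @examples
#' cfg <- trial_config(seed = 1, n_treatment = 1, n_placebo = 0)
#' comp <- activity_composition(simulate_trace(1, "treatment", cfg))
#' all(abs(rowSums(comp[, c("f_sleep", "f_low", "f_moderate", "f_high")]) - 1) < 1e-9)
activity_composition <- function(trace, thresholds = activity_thresholds(),
                                 window = c(360, 1320)) {
  stopifnot(inherits(thresholds, "activity_thresholds"),
            all(c("minute_of_day", "activity") %in% names(trace)))
  sub <- trace[trace$minute_of_day >= window[1] &
                 trace$minute_of_day < window[2], ]
  if (nrow(sub) == 0) {
    rlang::abort("Empty daytime window: no minutes to classify",
                 class = "actibarq_empty_window")
  }
  a <- sub$activity
  sub$class <- dplyr::case_when(
    a < thresholds$light ~ "sleep",
    a < thresholds$moderate ~ "low",
    a < thresholds$high ~ "moderate",
    TRUE ~ "high"
  )
  grp <- intersect(c("dog_id", "arm", "study_day", "date", "phase"),
                   names(sub))
  sub |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(
      f_sleep = mean(.data$class == "sleep"),
      f_low = mean(.data$class == "low"),
      f_moderate = mean(.data$class == "moderate"),
      f_high = mean(.data$class == "high"),
      n_minutes = dplyr::n(),
      .groups = "drop"
    )
}

#' Phase-level composition change
#'
#' Phase composition is the mean of daily compositions; the reported deltas
#' are supplement minus baseline, in percentage points.
#'
#' @param comp Output of [activity_composition()] (needs a `phase` column).
#' @param weekdays_only Drop weekend days first (requires `date`).
#' @return Tibble: `dog_id` (, `arm`), `d_sleep`, `d_low`, `d_moderate`,
#'   `d_high` (percentage points).
#' @export
composition_phase_deltas <- function(comp, weekdays_only = TRUE) {
  stopifnot("phase" %in% names(comp))
  if (weekdays_only && "date" %in% names(comp)) comp <- filter_weekdays(comp)
  grp <- intersect(c("dog_id", "arm"), names(comp))
  ph <- comp |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(grp, "phase")))) |>
    dplyr::summarise(dplyr::across(dplyr::starts_with("f_"), mean),
                     .groups = "drop")
  wide <- ph |>
    tidyr::pivot_wider(names_from = "phase",
                       values_from = dplyr::starts_with("f_"))
  need <- c("f_sleep_baseline", "f_sleep_supplement")
  if (!all(need %in% names(wide))) {
    rlang::abort("Need both baseline and supplement phases to compute deltas",
                 class = "actibarq_empty_window")
  }
  wide |>
    dplyr::transmute(
      dplyr::across(dplyr::all_of(grp)),
      d_sleep = 100 * (.data$f_sleep_supplement - .data$f_sleep_baseline),
      d_low = 100 * (.data$f_low_supplement - .data$f_low_baseline),
      d_moderate = 100 * (.data$f_moderate_supplement - .data$f_moderate_baseline),
      d_high = 100 * (.data$f_high_supplement - .data$f_high_baseline)
    )
}

# Earliest start t in [from, to] such that all `width` consecutive minutes
# satisfy the predicate. `x` is a full 1440-length day vector (NA = missing;
# NA disqualifies any window containing it). Runs in O(n) via run-length
# encoding of the predicate.
first_window <- function(ok, from, width) {
  ok[is.na(ok)] <- FALSE
  n <- length(ok)
  if (from + width > n) return(NA_integer_)
  ok[seq_len(from)] <- FALSE   # minutes before `from` (0-based) can't start
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- which(r$values & r$lengths >= width)
  if (!length(cand)) return(NA_integer_)
  as.integer(starts[cand[1]] - 1L)  # back to 0-based minute of day
}

day_vector <- function(day_rows) {
  x <- rep(NA_real_, 1440)
  x[day_rows$minute_of_day + 1L] <- day_rows$activity
  x
}

#' Detect sleep onset and wake time
#'
#' Sleep onset is the earliest minute at or after 19:00 starting a 15-minute
#' run in which every minute's activity is strictly below the light
#' threshold; the search stops at 23:59 (no midnight crossing), and nights
#' without a qualifying window return `NA`. Wake time mirrors it: the
#' earliest minute at or after 05:00 starting a 15-minute run at or above
#' the light threshold. Missing minutes disqualify a window.
#'
#' @param trace An `activity_trace` tibble.
#' @param thresholds An [activity_thresholds()] object.
#' @param window_min Run length in minutes (default 15).
#' @return Tibble: `dog_id` (, `arm`), `study_day` (, `date`, `phase`),
#'   `onset_time`, `wake_time` in minutes after midnight (`NA` when absent).
#' @export
#' @examples
#' cfg <- trial_config(seed = 1, n_treatment = 1, n_placebo = 0)
#' ev <- detect_sleep_events(simulate_trace(1, "treatment", cfg))
#' head(ev)
detect_sleep_events <- function(trace, thresholds = activity_thresholds(),
                                window_min = 15L) {
  stopifnot(inherits(thresholds, "activity_thresholds"))
  grp <- intersect(c("dog_id", "arm", "study_day", "date", "phase"),
                   names(trace))
  trace |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::group_modify(function(rows, key) {
      x <- day_vector(rows)
      tibble::tibble(
        onset_time = first_window(x < thresholds$light, 1140L, window_min),
        wake_time = first_window(x >= thresholds$light, 300L, window_min)
      )
    }) |>
    dplyr::ungroup()
}

#' Onset/wake drift per arm
#'
#' Pooled least-squares regression of detected event times (minutes after
#' midnight) on study day within each arm — the slope is the drift in
#' minutes/day; variability is the SD of the event times. The baseline phase
#' is excluded by default so the drift refers to the supplementation period.
#'
#' @param events Output of [detect_sleep_events()] with an `arm` column.
#' @param event `"onset"` or `"wake"`.
#' @param phase Phase(s) to include (default `"supplement"`).
#' @param min_events Minimum detected events per arm; fewer is refused.
#' @return Tibble per arm: `arm`, `event`, `slope_min_per_day`, `ci_lo`,
#'   `ci_hi`, `sd_minutes`, `n_events`.
#' @export
event_drift <- function(events, event = c("onset", "wake"),
                        phase = "supplement", min_events = 10L) {
  event <- match.arg(event)
  stopifnot("arm" %in% names(events))
  col <- paste0(event, "_time")
  dat <- events[!is.na(events[[col]]), ]
  if (!is.null(phase) && "phase" %in% names(dat)) {
    dat <- dat[dat$phase %in% phase, ]
  }
  dat |>
    dplyr::group_by(.data$arm) |>
    dplyr::group_modify(function(rows, key) {
      if (nrow(rows) < min_events) {
        rlang::abort(sprintf(
          "Arm `%s` has only %d detected %s events (minimum %d)",
          key$arm, nrow(rows), event, min_events
        ), class = "actibarq_insufficient_events")
      }
      fit <- stats::lm(rows[[col]] ~ rows$study_day)
      ci <- stats::confint(fit)[2, ]
      tibble::tibble(
        event = event,
        slope_min_per_day = unname(stats::coef(fit)[2]),
        ci_lo = ci[[1]], ci_hi = ci[[2]],
        sd_minutes = stats::sd(rows[[col]]),
        n_events = nrow(rows)
      )
    }) |>
    dplyr::ungroup()
}

#' Morning activity (06:00-08:00) by phase
#'
#' Per-dog mean minute activity in the interval from typical wake times to
#' caregiver departure, for each phase; the arm-level comparison of
#' supplement vs baseline uses the paired signed-rank path of
#' [compare_groups()].
#'
#' @param trace An `activity_trace` tibble.
#' @param window Minutes after midnight, default `c(360, 480)`.
#' @param weekdays_only Drop weekends first.
#' @return Tibble: `dog_id` (, `arm`), `phase`, `mean_activity`, `n_days`.
#' @export
morning_activity <- function(trace, window = c(360, 480), weekdays_only = TRUE) {
  sub <- trace[trace$minute_of_day >= window[1] &
                 trace$minute_of_day < window[2], ]
  if (weekdays_only && "date" %in% names(sub)) sub <- filter_weekdays(sub)
  grp <- intersect(c("dog_id", "arm", "phase"), names(sub))
  sub |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(grp, "study_day")))) |>
    dplyr::summarise(day_mean = mean(.data$activity), .groups = "drop") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(mean_activity = mean(.data$day_mean),
                     n_days = dplyr::n(), .groups = "drop")
}

#' Post-departure settling index
#'
#' Within the 08:00-10:00 window following the average caregiver departure
#' at 08:00, the per-day index is `100 * (mean activity in minutes 60-120
#' - mean in minutes 0-59) / mean in minutes 0-59`; more negative means the
#' dog settles faster. Days whose first-hour mean is zero are flagged and
#' excluded. The per-dog result averages the index over each phase's
#' weekdays.
#'
#' @param trace An `activity_trace` tibble.
#' @param depart_min Departure time, minutes after midnight (default 480).
#' @param weekdays_only Drop weekends first.
#' @return Tibble: `dog_id` (, `arm`), `phase`, `settling_pct`, `n_days`,
#'   `n_undefined` (days skipped for a zero first-hour mean).
#' @export
#' @examples
#' # hour 1 at 100, hour 2 at 82.2 -> -17.8
#' tr <- tibble::tibble(
#'   dog_id = "d1", study_day = 7, phase = "supplement",
#'   date = as.Date("2024-01-08"),
#'   minute_of_day = 480:599,
#'   activity = rep(c(100, 82.2), each = 60)
#' )
#' settling_index(tr)$settling_pct
settling_index <- function(trace, depart_min = 480L, weekdays_only = TRUE) {
  sub <- trace[trace$minute_of_day >= depart_min &
                 trace$minute_of_day < depart_min + 120L, ]
  if (weekdays_only && "date" %in% names(sub)) sub <- filter_weekdays(sub)
  if (nrow(sub) == 0) {
    rlang::abort("No samples in the post-departure window",
                 class = "actibarq_empty_window")
  }
  has_arm <- "arm" %in% names(sub)
  has_phase <- "phase" %in% names(sub)
  key <- paste(sub$dog_id, if (has_arm) sub$arm else "",
               if (has_phase) sub$phase else "", sub$study_day, sep = "\r")
  in_h1 <- sub$minute_of_day < depart_min + 60L
  s1 <- rowsum(sub$activity * in_h1, key)
  n1 <- rowsum(as.numeric(in_h1), key)
  s2 <- rowsum(sub$activity * !in_h1, key)
  n2 <- rowsum(as.numeric(!in_h1), key)
  keep <- n1[, 1] > 0 & n2[, 1] > 0
  m1 <- (s1[, 1] / n1[, 1])[keep]
  m2 <- (s2[, 1] / n2[, 1])[keep]
  undefined <- m1 <= 0
  index <- ifelse(undefined, NA_real_, 100 * (m2 - m1) / m1)
  parts <- do.call(rbind, strsplit(rownames(s1)[keep], "\r", fixed = TRUE))
  dogkey <- paste(parts[, 1], parts[, 2], parts[, 3], sep = "\r")
  agg_mean <- rowsum(ifelse(undefined, 0, index), dogkey) /
    pmax(1, rowsum(as.numeric(!undefined), dogkey))
  n_days <- rowsum(as.numeric(!undefined), dogkey)
  n_undef <- rowsum(as.numeric(undefined), dogkey)
  dparts <- do.call(rbind, strsplit(rownames(agg_mean), "\r", fixed = TRUE))
  out <- tibble::tibble(dog_id = dparts[, 1])
  if (has_arm) out$arm <- dparts[, 2]
  if (has_phase) out$phase <- dparts[, 3]
  out$settling_pct <- unname(ifelse(n_days[, 1] > 0, agg_mean[, 1], NA_real_))
  out$n_days <- as.integer(n_days[, 1])
  out$n_undefined <- as.integer(n_undef[, 1])
  out[order(out$dog_id), ]
}
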