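# Orchestration: dosing, cohort and adverse-event summaries, and the
# end-to-end analysis over a trial's four data streams.

#' Daily capsule dose from body weight
#'
#' One capsule per 25 lbs of body weight, rounded up; dogs below 25 lbs
#' receive the minimum dose of one capsule: `max(1, ceiling(weight / 25))`.
#'
#' @param weight_lbs Body weight in pounds (> 0; vectorized).
#' @return Integer capsules/day.
#' @export
#' @examples
#' dose_for_weight(c(10, 25, 60)) # 1, 1, 3
dose_for_weight <- function(weight_lbs) {
  if (!is.numeric(weight_lbs) || any(!is.finite(weight_lbs)) ||
      any(weight_lbs <= 0)) {
    rlang::abort("`weight_lbs` must be positive and finite",
                 class = "actibarq_pipeline_error")
  }
  as.integer(pmax(1, ceiling(weight_lbs / 25)))
}

#' Cohort composition summary
#'
#' Exact counts and percentages of sex, neuter status and diet, arm sizes,
#' and the scheduled dose count. Doses are counted as dog-days (dogs x
#' supplementation days); the scheduled capsule total (weight-adjusted) is
#' reported alongside.
#'
#' @param dogs `DogRecord` tibble (see [simulate_dogs()]).
#' @param supplement_days Supplementation length used for the dose count.
#' @return List with `n`, `arms`, `sex`, `neutered`, `diet`,
#'   `scheduled_doses` (dog-days), `scheduled_capsules`.
#' @export
#' @examples
#' cfg <- trial_config(seed = 1)
#' cohort_summary(simulate_dogs(cfg))$scheduled_doses # 40 * 28 = 1120
cohort_summary <- function(dogs, supplement_days = 28) {
  stopifnot(all(c("dog_id", "arm") %in% names(dogs)))
  if ("enrolled" %in% names(dogs)) dogs <- dogs[dogs$enrolled, ]
  n <- nrow(dogs)
  pct_tbl <- function(x) {
    tb <- table(x)
    counts <- as.integer(tb)
    pct <- 100 * counts / n
    tibble::tibble(level = names(tb), n = counts, percent = pct)
  }
  list(
    n = n,
    arms = pct_tbl(dogs$arm),
    sex = if ("sex" %in% names(dogs)) pct_tbl(dogs$sex) else NULL,
    neutered = if ("neutered" %in% names(dogs)) pct_tbl(dogs$neutered) else NULL,
    diet = if ("diet" %in% names(dogs)) pct_tbl(dogs$diet) else NULL,
    scheduled_doses = n * supplement_days,
    scheduled_capsules = if ("capsules_per_day" %in% names(dogs)) {
      sum(dogs$capsules_per_day) * supplement_days
    } else NULL
  )
}

#' Adverse-event and completion summary
#'
#' Collected-over-expected completion rate and event rates as percentages of
#' collected responses, with a per-day breakdown. Refuses to divide when no
#' survey was returned.
#'
#' @param surveys Survey tibble with `dog_id`, `day`, `responded`, `emesis`,
#'   `diarrhea`.
#' @return List with `n_expected`, `n_collected`, `completion_pct`,
#'   `emesis_n`, `emesis_pct`, `diarrhea_n`, `diarrhea_pct`, `by_day`.
#' @export
#' @examples
#' cfg <- trial_config(seed = 1)
#' s <- simulate_trial(cfg, traces = FALSE)$surveys
#' adverse_event_summary(s)$completion_pct
adverse_event_summary <- function(surveys) {
  stopifnot(all(c("dog_id", "day", "responded") %in% names(surveys)))
  n_expected <- nrow(surveys)
  resp <- surveys[surveys$responded, ]
  n_collected <- nrow(resp)
  if (n_collected == 0) {
    return(list(n_expected = n_expected, n_collected = 0,
                completion_pct = 0, emesis_n = NA_integer_,
                emesis_pct = NA_real_, diarrhea_n = NA_integer_,
                diarrhea_pct = NA_real_, by_day = NULL,
                flag = "no returned surveys"))
  }
  by_day <- resp |>
    dplyr::group_by(.data$day) |>
    dplyr::summarise(n_responses = dplyr::n(),
                     emesis = sum(.data$emesis),
                     diarrhea = sum(.data$diarrhea), .groups = "drop")
  list(
    n_expected = n_expected,
    n_collected = n_collected,
    completion_pct = 100 * n_collected / n_expected,
    emesis_n = sum(resp$emesis),
    emesis_pct = 100 * sum(resp$emesis) / n_collected,
    diarrhea_n = sum(resp$diarrhea),
    diarrhea_pct = 100 * sum(resp$diarrhea) / n_collected,
    by_day = by_day
  )
}

#' Run the full trial analysis
#'
#' The end-to-end pipeline over a trial's four data streams: cohort and
#' adverse-event summaries with exact association tests; C-BARQ domain
#' scores, the pooled General Anxiety composite, day-35 between-arm and
#' within-treatment paired endpoints, and item-change rankings per arm;
#' actigraphy features (weekday daily totals, per-arm OLS trends, the
#' random-intercept mixed model, daytime composition deltas, sleep
#' onset/wake drift, morning activity, settling index) with their endpoint
#' comparisons. Deterministic given identical inputs. Weekends are excluded
#' from all activity endpoints.
#'
#' @param trial A `synthetic_trial` (or a list with the same elements:
#'   `dogs`, `traces`, `cbarq`, `surveys`, `config`).
#' @param thresholds Activity thresholds (defaults to the config's).
#' @return A list of class `trial_report`.
#' @export
#' @examples
#' \donttest{
#' cfg <- trial_config(seed = 1, n_treatment = 4, n_placebo = 3)
#' rep <- run_trial_analysis(simulate_trial(cfg))
#' names(rep)
#' }
run_trial_analysis <- function(trial, thresholds = NULL) {
  cfg <- trial$config
  thresholds <- thresholds %||% cfg$thresholds
  if (is.null(trial$traces)) {
    rlang::abort("Trial has no minute traces; simulate with traces = TRUE",
                 class = "actibarq_pipeline_error")
  }
  both_arms <- length(unique(trial$dogs$arm)) == 2

  cohort <- cohort_summary(trial$dogs, supplement_days = cfg$supplement_days)
  adverse <- adverse_event_summary(trial$surveys)
  adverse_tests <- if (both_arms) {
    list(emesis = compare_adverse_events(trial$surveys, "emesis"),
         diarrhea = compare_adverse_events(trial$surveys, "diarrhea"))
  } else NULL

  scored <- score_cbarq(trial$cbarq)
  dscores <- dplyr::bind_rows(domain_scores(scored), general_anxiety_scores(scored))
  cbarq_endpoints <- if (both_arms) cbarq_endpoint_table(dscores) else NULL
  rankings <- lapply(stats::setNames(nm = unique(trial$dogs$arm)),
                     function(a) rank_item_changes(scored, arm = a, top_n = 10))

  daily <- daily_totals(trial$traces)
  trends <- group_trend(daily)
  mixed <- if (both_arms) fit_activity_model(daily) else NULL
  comp <- activity_composition(trial$traces, thresholds)
  comp_deltas <- composition_phase_deltas(comp)
  events <- detect_sleep_events(trial$traces, thresholds)
  events_wd <- filter_weekdays(events)
  drift <- tryCatch(
    dplyr::bind_rows(event_drift(events_wd, "onset"),
                     event_drift(events_wd, "wake")),
    actibarq_insufficient_events = function(e) NULL
  )
  morning <- morning_activity(trial$traces)
  settling <- settling_index(trial$traces)

  activity_endpoints <- if (both_arms) {
    activity_endpoint_table(comp_deltas, morning, settling)
  } else NULL

  structure(list(
    cohort = cohort,
    adverse = adverse,
    adverse_tests = adverse_tests,
    domain_scores = dscores,
    cbarq_endpoints = cbarq_endpoints,
    item_rankings = rankings,
    daily_totals = daily,
    trends = trends,
    mixed_model = mixed,
    composition_deltas = comp_deltas,
    drift = drift,
    morning = morning,
    settling = settling,
    activity_endpoints = activity_endpoints,
    provenance = list(seed = cfg$seed,
                      n_dogs = nrow(trial$dogs),
                      package_version = as.character(utils::packageVersion("actibarq")))
  ), class = "trial_report")
}

# Day-35 between-arm and within-treatment paired endpoints for each domain
# composite (including General Anxiety).
cbarq_endpoint_table <- function(dscores) {
  domains <- unique(dscores$domain)
  rows <- lapply(domains, function(dm) {
    d35 <- dscores[dscores$domain == dm & dscores$timepoint == "day35" &
                     !is.na(dscores$score), ]
    x <- d35$score[d35$arm == "placebo"]
    y <- d35$score[d35$arm == "treatment"]
    between <- tryCatch(
      compare_groups(x, y, endpoint = paste0(dm, " (day35, between-arm)")),
      actibarq_stats_error = function(e) NULL
    )
    tr <- dscores[dscores$domain == dm & dscores$arm == "treatment", ] |>
      tidyr::pivot_wider(id_cols = "dog_id", names_from = "timepoint",
                         values_from = "score") |>
      stats::na.omit()
    within <- if (nrow(tr) >= 3) {
      compare_groups(tr$day0, tr$day35, paired = TRUE,
                     endpoint = paste0(dm, " (treatment, day0 vs day35)"))
    } else NULL
    dplyr::bind_rows(
      if (!is.null(between)) tidy(between),
      if (!is.null(within)) tidy(within)
    )
  })
  dplyr::bind_rows(rows)
}

activity_endpoint_table <- function(comp_deltas, morning, settling) {
  rows <- list()
  cd <- comp_deltas[!is.na(comp_deltas$d_sleep), ]
  if (length(unique(cd$arm)) == 2) {
    rows$sleep_delta <- tidy(compare_groups(
      cd$d_sleep[cd$arm == "placebo"], cd$d_sleep[cd$arm == "treatment"],
      endpoint = "daytime sleep delta (pp, between-arm)"
    ))
  }
  st <- settling[settling$phase == "supplement" & is.finite(settling$settling_pct), ]
  if (length(unique(st$arm)) == 2) {
    rows$settling <- tidy(compare_groups(
      st$settling_pct[st$arm == "placebo"],
      st$settling_pct[st$arm == "treatment"],
      endpoint = "settling index (supplement, between-arm)"
    ))
  }
  mo <- morning |>
    tidyr::pivot_wider(id_cols = c("dog_id", "arm"), names_from = "phase",
                       values_from = "mean_activity") |>
    stats::na.omit()
  for (a in unique(mo$arm)) {
    sub <- mo[mo$arm == a, ]
    if (nrow(sub) >= 3) {
      rows[[paste0("morning_", a)]] <- tidy(compare_groups(
        sub$baseline, sub$supplement, paired = TRUE,
        endpoint = paste0("morning activity (", a, ", baseline vs supplement)")
      ))
    }
  }
  dplyr::bind_rows(rows)
}

#' @export
print.trial_report <- function(x, ...) {
  cat("<trial_report>\n")
  cat(sprintf("  cohort: %d dogs; %d scheduled doses\n",
              x$cohort$n, x$cohort$scheduled_doses))
  cat(sprintf("  surveys: %d/%d collected (%.1f%%); emesis %.1f%%, diarrhea %.1f%%\n",
              x$adverse$n_collected, x$adverse$n_expected,
              x$adverse$completion_pct, x$adverse$emesis_pct,
              x$adverse$diarrhea_pct))
  if (!is.null(x$mixed_model)) {
    ia <- x$mixed_model$coefficients
    ia <- ia[ia$term == x$mixed_model$interaction_term, ]
    cat(sprintf("  day x group interaction: %.2f u/day [%.2f, %.2f]\n",
                ia$estimate, ia$conf_low, ia$conf_high))
  }
  if (!is.null(x$cbarq_endpoints)) {
    cat(sprintf("  %d C-BARQ endpoints, %d activity endpoints computed\n",
                nrow(x$cbarq_endpoints),
                if (is.null(x$activity_endpoints)) 0L else nrow(x$activity_endpoints)))
  }
  invisible(x)
}

#' Write the report bundle as CSV tables
#'
#' Emits the report's tabular components (`domain_scores`,
#' `cbarq_endpoints`, `daily_totals`, `trends`, `composition_deltas`,
#' `drift`, `morning`, `settling`, `activity_endpoints`, item rankings) as
#' CSV files plus a human-readable `summary.txt`. Byte-identical for
#' identical inputs.
#'
#' @param report A `trial_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trial_report <- function(report, dir) {
  stopifnot(inherits(report, "trial_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(tbl, name) {
    if (!is.null(tbl) && nrow(tbl)) {
      utils::write.csv(tbl, file.path(dir, paste0(name, ".csv")),
                       row.names = FALSE)
    }
  }
  wr(report$domain_scores, "domain_scores")
  wr(report$cbarq_endpoints, "cbarq_endpoints")
  wr(report$daily_totals, "daily_totals")
  wr(report$trends, "trends")
  wr(report$composition_deltas, "composition_deltas")
  wr(report$drift, "drift")
  wr(report$morning, "morning_activity")
  wr(report$settling, "settling")
  wr(report$activity_endpoints, "activity_endpoints")
  for (a in names(report$item_rankings)) {
    wr(report$item_rankings[[a]], paste0("item_ranking_", a))
  }
  if (!is.null(report$mixed_model)) {
    wr(report$mixed_model$coefficients, "mixed_model_coefficients")
  }
  con <- file(file.path(dir, "summary.txt"), open = "wt")
  sink(con); on.exit({ sink(); close(con) }, add = TRUE)
  print(report)
  invisible(dir)
}
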