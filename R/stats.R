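# Inferential layer: assumption-gated two-sample / paired comparisons, the
# random-intercept mixed model for daily activity, per-arm OLS trends, the
# a priori power computation, and adverse-event association tests.

#' Assumption-gated two-sample or paired comparison
#'
#' Implements the trial's test-selection rule: Shapiro-Wilk normality on
#' each sample (on the paired differences when `paired = TRUE`) at
#' `alpha_gate`, plus Levene's test of variance homogeneity across unpaired
#' samples. If normality holds in both samples a t-test is used — Welch by
#' default regardless of the Levene outcome (the Levene result is recorded
#' for transparency) — otherwise the rank-based analogue: Wilcoxon rank-sum
#' (unpaired) or signed-rank (paired). All tests are two-sided.
#'
#' @param x,y Numeric samples (each n >= 3; equal lengths when paired).
#' @param paired Paired comparison (y - x differences)?
#' @param alpha_gate Significance level of the assumption gate (default 0.05).
#' @param endpoint Optional endpoint name carried into the result.
#' @param conf_level Confidence level of the effect CI.
#' @return An `endpoint_result` object (see [tidy.endpoint_result()]):
#'   per-sample summaries, effect estimate with CI, the test used, its
#'   statistic, degrees of freedom (Welch and classical n1+n2-2 for
#'   unpaired t), two-sided p, and the gate evidence that selected the test.
#' @export
#' @examples
#' set.seed(1)
#' r <- compare_groups(rnorm(20), rnorm(20, 1), endpoint = "demo")
#' r$test
#' tidy(r)
compare_groups <- function(x, y, paired = FALSE, alpha_gate = 0.05,
                           endpoint = NULL, conf_level = 0.95) {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  if (length(x) < 3 || length(y) < 3) {
    rlang::abort("Each sample needs at least 3 finite observations",
                 class = "actibarq_stats_error")
  }
  if (paired && length(x) != length(y)) {
    rlang::abort("Paired samples must have equal length",
                 class = "actibarq_stats_error")
  }
  degenerate <- stats::sd(x) == 0 && stats::sd(y) == 0
  if (paired) {
    d <- y - x
    sw_p <- if (stats::sd(d) > 0) stats::shapiro.test(d)$p.value else NA_real_
    gate <- tibble::tibble(check = "shapiro_diff", p = sw_p)
    normal <- !is.na(sw_p) && sw_p >= alpha_gate
  } else {
    sw_x <- if (stats::sd(x) > 0) stats::shapiro.test(x)$p.value else NA_real_
    sw_y <- if (stats::sd(y) > 0) stats::shapiro.test(y)$p.value else NA_real_
    lev_p <- if (!degenerate) {
      lev_dat <- data.frame(
        v = c(x, y),
        g = factor(rep(c("x", "y"), c(length(x), length(y))))
      )
      car::leveneTest(v ~ g, data = lev_dat)[1, "Pr(>F)"]
    } else NA_real_
    gate <- tibble::tibble(
      check = c("shapiro_x", "shapiro_y", "levene"),
      p = c(sw_x, sw_y, lev_p)
    )
    normal <- !is.na(sw_x) && !is.na(sw_y) &&
      sw_x >= alpha_gate && sw_y >= alpha_gate
  }

  if (degenerate && identical(mean(x), mean(y))) {
    test <- if (paired) "signed-rank" else "rank-sum"
    res <- list(estimate = 0, ci = c(0, 0), statistic = NA_real_,
                df = NA_real_, df_classical = NA_real_, p = 1)
    warning("Both samples have zero variance; degenerate comparison", call. = FALSE)
  } else if (normal) {
    if (paired) {
      ht <- stats::t.test(y, x, paired = TRUE, conf.level = conf_level)
      test <- "paired t"
      dfc <- length(x) - 1
    } else {
      ht <- stats::t.test(y, x, var.equal = FALSE, conf.level = conf_level)
      test <- "Welch t"
      dfc <- length(x) + length(y) - 2
    }
    res <- list(estimate = unname(if (paired) ht$estimate else mean(y) - mean(x)),
                ci = as.numeric(ht$conf.int),
                statistic = unname(ht$statistic),
                df = unname(ht$parameter), df_classical = dfc,
                p = ht$p.value)
  } else {
    ht <- suppressWarnings(
      stats::wilcox.test(y, x, paired = paired, conf.int = TRUE,
                         conf.level = conf_level, exact = FALSE)
    )
    test <- if (paired) "signed-rank" else "rank-sum"
    res <- list(estimate = unname(ht$estimate),
                ci = as.numeric(ht$conf.int),
                statistic = unname(ht$statistic),
                df = NA_real_, df_classical = NA_real_,
                p = ht$p.value)
  }

  structure(list(
    endpoint = endpoint %||% "endpoint",
    paired = paired,
    test = test,
    estimate = res$estimate,
    conf_low = res$ci[1], conf_high = res$ci[2], conf_level = conf_level,
    statistic = res$statistic, df = res$df, df_classical = res$df_classical,
    p_value = min(1, res$p),
    gate = gate, alpha_gate = alpha_gate,
    summary_x = sample_summary(x), summary_y = sample_summary(y),
    degenerate = degenerate
  ), class = "endpoint_result")
}

sample_summary <- function(v) {
  tibble::tibble(n = length(v), mean = mean(v), median = stats::median(v),
                 sd = stats::sd(v))
}

#' @export
print.endpoint_result <- function(x, ...) {
  cat(sprintf("<endpoint_result: %s>\n", x$endpoint))
  cat(sprintf("  test: %s%s\n", x$test, if (x$paired) " (paired)" else ""))
  cat(sprintf("  effect: %.4g [%.4g, %.4g] (%.0f%% CI), p = %.4g\n",
              x$estimate, x$conf_low, x$conf_high, 100 * x$conf_level,
              x$p_value))
  cat(sprintf("  n: %d vs %d\n", x$summary_x$n, x$summary_y$n))
  invisible(x)
}

#' Random-intercept mixed model for daily activity
#'
#' Fits `total ~ day * arm + (1 | dog_id)` by REML on the supplement-phase
#' weekday totals (the phase in which the treatment trend is modeled as
#' linear in day). The day-by-arm interaction is the headline contrast: the
#' treatment-relative change in daily activity, units/day. Wald confidence
#' intervals are reported. A singular random-effect fit triggers a warning
#' but still returns; non-convergence is an error carrying the optimizer
#' diagnostics.
#'
#' @param daily Daily-total tibble (from [daily_totals()] or
#'   [simulate_daily_totals()]) with `dog_id`, `arm`, `study_day`, `total`,
#'   and `phase`/`weekday` (or `date`) columns.
#' @param phase Phase to fit on (default `"supplement"`; `NULL` = all days).
#' @param weekdays_only Restrict to weekdays.
#' @param conf_level Confidence level of the Wald CIs.
#' @return An `activity_model` object; see [tidy.activity_model()].
#' @export
#' @examples
#' cfg <- trial_config(seed = 1, n_treatment = 6, n_placebo = 4)
#' fit <- fit_activity_model(simulate_daily_totals(cfg))
#' glance(fit)$interaction
fit_activity_model <- function(daily, phase = "supplement",
                               weekdays_only = TRUE, conf_level = 0.95) {
  stopifnot(all(c("dog_id", "arm", "study_day", "total") %in% names(daily)))
  dat <- daily
  if (!is.null(phase) && "phase" %in% names(dat)) dat <- dat[dat$phase %in% phase, ]
  if (weekdays_only) {
    if ("weekday" %in% names(dat)) {
      dat <- dat[dat$weekday, ]
    } else if ("date" %in% names(dat)) {
      dat <- filter_weekdays(dat)
    }
  }
  if (length(unique(dat$arm)) < 2) {
    rlang::abort("Mixed model needs both arms present",
                 class = "actibarq_stats_error")
  }
  narm <- table(unique(dat[, c("dog_id", "arm")])$arm)
  if (any(narm < 2)) {
    rlang::abort("Mixed model needs at least 2 dogs per arm",
                 class = "actibarq_stats_error")
  }
  ndays <- tapply(dat$study_day, dat$dog_id, function(d) length(unique(d)))
  if (any(ndays < 3)) {
    rlang::abort("Mixed model needs at least 3 days per dog",
                 class = "actibarq_stats_error")
  }
  dat$arm <- factor(dat$arm, levels = c("placebo", "treatment"))
  dat$day <- dat$study_day - min(dat$study_day)
  fit <- tryCatch(
    lme4::lmer(total ~ day * arm + (1 | dog_id), data = dat, REML = TRUE),
    error = function(e) {
      rlang::abort(paste0("Mixed model failed to converge: ",
                          conditionMessage(e)),
                   class = "actibarq_convergence_error")
    }
  )
  if (lme4::isSingular(fit)) {
    warning("Random-intercept variance is singular (estimated at zero)",
            call. = FALSE)
  }
  co <- summary(fit)$coefficients
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  coefs <- tibble::tibble(
    term = rownames(co),
    estimate = unname(co[, "Estimate"]),
    std_error = unname(co[, "Std. Error"]),
    conf_low = unname(co[, "Estimate"] - z * co[, "Std. Error"]),
    conf_high = unname(co[, "Estimate"] + z * co[, "Std. Error"])
  )
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(
    fit = fit,
    coefficients = coefs,
    interaction_term = "day:armtreatment",
    var_dog = vc$vcov[vc$grp == "dog_id"],
    var_residual = vc$vcov[vc$grp == "Residual"],
    n_dogs = length(unique(dat$dog_id)),
    n_observations = nrow(dat),
    singular = lme4::isSingular(fit),
    conf_level = conf_level
  ), class = "activity_model")
}

#' @export
print.activity_model <- function(x, ...) {
  cat("<activity_model: total ~ day * arm + (1 | dog_id)>\n")
  ia <- x$coefficients[x$coefficients$term == x$interaction_term, ]
  cat(sprintf("  day x group interaction: %.2f u/day [%.2f, %.2f]\n",
              ia$estimate, ia$conf_low, ia$conf_high))
  cat(sprintf("  %d dogs, %d observations; var(dog) = %.0f, var(resid) = %.0f\n",
              x$n_dogs, x$n_observations, x$var_dog, x$var_residual))
  invisible(x)
}

#' Per-arm daily-activity trend
#'
#' Ordinary least squares of the arm-mean weekday daily total on study day
#' — the simple-regression view of the activity trend, units/day.
#'
#' @inheritParams fit_activity_model
#' @param arm Arm to fit (default: each arm present).
#' @return Tibble per arm: `arm`, `slope`, `std_error`, `p_value`, `n_days`.
#' @export
group_trend <- function(daily, arm = NULL, phase = "supplement",
                        weekdays_only = TRUE) {
  dat <- daily
  if (!is.null(phase) && "phase" %in% names(dat)) dat <- dat[dat$phase %in% phase, ]
  if (weekdays_only) {
    if ("weekday" %in% names(dat)) {
      dat <- dat[dat$weekday, ]
    } else if ("date" %in% names(dat)) {
      dat <- filter_weekdays(dat)
    }
  }
  if (!is.null(arm)) dat <- dat[dat$arm %in% arm, ]
  dat |>
    dplyr::group_by(.data$arm) |>
    dplyr::group_modify(function(rows, key) {
      by_day <- rows |>
        dplyr::group_by(.data$study_day) |>
        dplyr::summarise(m = mean(.data$total), .groups = "drop")
      if (nrow(by_day) < 3) {
        rlang::abort("Trend fit needs at least 3 days",
                     class = "actibarq_stats_error")
      }
      fit <- stats::lm(m ~ study_day, data = by_day)
      s <- summary(fit)$coefficients
      tibble::tibble(slope = s[2, 1], std_error = s[2, 2],
                     p_value = s[2, 4], n_days = nrow(by_day))
    }) |>
    dplyr::ungroup()
}

#' Power of the two-sided two-sample t-test
#'
#' A priori power for a two-sided independent t-test at effect size
#' (Cohen's d) `d` with group sizes `n1`, `n2`, via the noncentral t
#' distribution: the noncentrality parameter is `d / sqrt(1/n1 + 1/n2)`
#' with `n1 + n2 - 2` degrees of freedom. At `d = 0` the power equals
#' `alpha` exactly.
#'
#' @param d Cohen's d (>= 0).
#' @param n1,n2 Group sizes (>= 2).
#' @param alpha Two-sided significance level in (0, 1).
#' @return Power (probability of rejection).
#' @export
#' @examples
#' power_two_sample_t(0.7, 28, 12)
power_two_sample_t <- function(d, n1, n2, alpha = 0.05) {
  if (!is_number(d) || d < 0) {
    rlang::abort("`d` must be a single non-negative number",
                 class = "actibarq_stats_error")
  }
  if (!is_count(n1) || !is_count(n2) || n1 < 2 || n2 < 2) {
    rlang::abort("`n1` and `n2` must be integers >= 2",
                 class = "actibarq_stats_error")
  }
  if (!is_number(alpha) || alpha <= 0 || alpha >= 1) {
    rlang::abort("`alpha` must be in (0, 1)", class = "actibarq_stats_error")
  }
  df <- n1 + n2 - 2
  ncp <- d / sqrt(1 / n1 + 1 / n2)
  tc <- stats::qt(1 - alpha / 2, df)
  stats::pt(tc, df, ncp = ncp, lower.tail = FALSE) +
    stats::pt(-tc, df, ncp = ncp, lower.tail = TRUE)
}

#' Adverse-event association between arms
#'
#' Counts events among returned surveys per arm and per timepoint, and
#' tests the pooled 2x2 table (event x arm) with Fisher's exact test.
#'
#' @param surveys Survey tibble (see [simulate_surveys()]) with `arm`,
#'   `responded` and the event flag column.
#' @param event `"emesis"` or `"diarrhea"`.
#' @return List with `by_arm` (counts/rates), `by_day` (per-timepoint
#'   counts), `table` (the pooled 2x2), `p_value`, `test`.
#' @export
compare_adverse_events <- function(surveys, event = c("emesis", "diarrhea")) {
  event <- match.arg(event)
  stopifnot(all(c("arm", "responded", event) %in% names(surveys)))
  resp <- surveys[surveys$responded, ]
  if (nrow(resp) == 0) {
    rlang::abort("No returned surveys to compare",
                 class = "actibarq_stats_error")
  }
  by_arm <- resp |>
    dplyr::group_by(.data$arm) |>
    dplyr::summarise(n_responses = dplyr::n(),
                     n_events = sum(.data[[event]]),
                     rate = n_events / n_responses,
                     .groups = "drop")
  by_day <- resp |>
    dplyr::group_by(.data$arm, .data$day) |>
    dplyr::summarise(n_events = sum(.data[[event]]),
                     n_responses = dplyr::n(), .groups = "drop")
  tab <- table(
    arm = factor(resp$arm, levels = c("placebo", "treatment")),
    event = factor(resp[[event]], levels = c(FALSE, TRUE))
  )
  ft <- stats::fisher.test(tab)
  list(event = event, by_arm = by_arm, by_day = by_day, table = tab,
       p_value = ft$p.value, test = "Fisher exact")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
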