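#' Trial configuration
#'
#' Build the single configuration object that drives both the synthetic-trial
#' generator and the analysis defaults. All tunable quantities of the study
#' design live here: arm sizes, phase lengths, the activity calibration
#' (daily totals in device units), the behavioral effects injected into the
#' synthetic arms, sleep-timing parameters, questionnaire effects, and
#' survey/adverse-event rates.
#'
#' Defaults encode the trial design this package targets: 28 treatment and
#' 12 placebo dogs, a 7-day baseline followed by 28 supplementation days,
#' weekday daily totals calibrated to 5900 activity units with a
#' between-dog SD of 1225, a treatment-arm settling improvement of -17.8%
#' versus -3.2% for placebo, daytime-sleep deltas of -3.6 vs -0.9
#' percentage points, arm activity slopes of -27.59 and +18.87 units/day,
#' and a 73% weekly survey response rate.
#'
#' @param n_treatment,n_placebo Dogs per arm (non-negative; at least one arm
#'   must be non-empty).
#' @param baseline_days,supplement_days Length of the no-intervention
#'   baseline and the supplementation phase, in days. Their sum is the study
#'   length and may not exceed 35.
#' @param seed Integer root seed. Every dog draws from its own substream of
#'   this seed, so adding a dog never perturbs the others.
#' @param start_date Calendar date of study day 0 (used for weekday
#'   filtering). Defaults to a Monday.
#' @param daily_activity_mean Mean weekday daily activity total, device units.
#' @param daily_activity_sd_between_dogs Between-dog SD of the daily total.
#' @param daily_activity_sd_within_dog Day-to-day SD within a dog.
#' @param treatment_activity_slope,placebo_activity_slope Linear daily-total
#'   trends (units/day) applied from the first supplementation day onward.
#' @param interaction_slope Optional treatment-minus-placebo slope
#'   (units/day). When supplied it overrides `treatment_activity_slope` as
#'   `placebo_activity_slope + interaction_slope`.
#' @param weekend_multiplier Multiplier (> 1) applied to weekend daily
#'   totals, making the weekday filter consequential.
#' @param settling_pct_treatment,settling_pct_placebo Expected post-departure
#'   settling index (percent change, hour 2 vs hour 1 of 08:00-10:00)
#'   during the supplementation phase, by arm.
#' @param settling_pct_baseline Settling index during baseline (both arms).
#' @param daytime_sleep_delta_treatment,daytime_sleep_delta_placebo Change in
#'   the daytime (06:00-22:00) sleep fraction from baseline to
#'   supplementation, in percentage points (negative = less daytime sleep).
#' @param daytime_sleep_base Baseline daytime sleep fraction (0-1 scale) of
#'   the 06:00-22:00 window.
#' @param morning_boost_pct_treatment,morning_boost_pct_placebo Percent
#'   increase of 06:00-08:00 activity levels during supplementation.
#' @param onset_mean,wake_mean Mean sleep onset / wake time, minutes after
#'   midnight. Defaults (22:30, 05:40) keep the sleep-wake boundary outside
#'   the daytime composition window.
#' @param onset_drift_treatment,onset_drift_placebo Sleep-onset drift in
#'   minutes/day from the first supplementation day.
#' @param wake_drift_treatment,wake_drift_placebo Wake-time drift, min/day.
#' @param onset_sd_treatment,onset_sd_placebo Night-to-night SD of onset and
#'   wake times, minutes, by arm.
#' @param onset_between_sd Between-dog SD of the mean onset/wake time.
#' @param arousal_rate Mean number of brief nighttime arousal bursts per
#'   night (Poisson); bursts last 1-3 minutes.
#' @param cbarq_effects Named numeric vector of latent-trait shifts added to
#'   treatment dogs at day 35, one entry per C-BARQ domain (see
#'   [cbarq_item_bank()] for domain names). Use [cbarq_effect_for_gap()] to
#'   translate a target domain-score gap into a latent shift.
#' @param cbarq_domain_means Named numeric vector of baseline latent domain
#'   means (single number recycled to all domains).
#' @param cbarq_trait_sd,cbarq_item_sd Between-dog latent trait SD and
#'   item-level residual SD of the ordinal response model.
#' @param na_prob Probability that any single C-BARQ item is answered
#'   "NA/Never Observed".
#' @param survey_response_prob Probability a scheduled weekly survey is
#'   returned.
#' @param emesis_prob_treatment,emesis_prob_placebo Per-survey emesis
#'   probability by arm.
#' @param diarrhea_prob_treatment,diarrhea_prob_placebo Per-survey diarrhea
#'   probability by arm.
#' @param minute_noise Logical; `FALSE` replaces all minute-level randomness
#'   by its expectation (useful for degenerate-noise checks).
#' @param thresholds An [activity_thresholds()] object used by the analysis
#'   defaults.
#'
#' @return A list of class `trial_config`.
#' @export
#' @examples
#' cfg <- trial_config(seed = 1)
#' cfg$n_treatment
trial_config <- function(n_treatment = 28,
                         n_placebo = 12,
                         baseline_days = 7,
                         supplement_days = 28,
                         seed = 20250804,
                         start_date = as.Date("2024-01-01"),
                         daily_activity_mean = 5900,
                         daily_activity_sd_between_dogs = 1225,
                         daily_activity_sd_within_dog = 400,
                         treatment_activity_slope = -27.59,
                         placebo_activity_slope = 18.87,
                         interaction_slope = NULL,
                         weekend_multiplier = 1.3,
                         settling_pct_treatment = -17.8,
                         settling_pct_placebo = -3.2,
                         settling_pct_baseline = 0,
                         daytime_sleep_delta_treatment = -3.6,
                         daytime_sleep_delta_placebo = -0.9,
                         daytime_sleep_base = 0.55,
                         morning_boost_pct_treatment = 12,
                         morning_boost_pct_placebo = 0,
                         onset_mean = 22.5 * 60,
                         wake_mean = 5 * 60 + 40,
                         onset_drift_treatment = 0,
                         onset_drift_placebo = -1.5,
                         wake_drift_treatment = 0,
                         wake_drift_placebo = 1.0,
                         onset_sd_treatment = 12,
                         onset_sd_placebo = 22,
                         onset_between_sd = 10,
                         arousal_rate = 2,
                         cbarq_effects = c(Aggression = 0),
                         cbarq_domain_means = 1.0,
                         cbarq_trait_sd = 0.5,
                         cbarq_item_sd = 0.7,
                         na_prob = 0.08,
                         survey_response_prob = 0.73,
                         emesis_prob_treatment = 0.06,
                         emesis_prob_placebo = 0.16,
                         diarrhea_prob_treatment = 0.164,
                         diarrhea_prob_placebo = 0.164,
                         minute_noise = TRUE,
                         thresholds = activity_thresholds()) {
  cfg <- as.list(environment())
  class(cfg) <- "trial_config"
  validate_trial_config(cfg)
}

#' @keywords internal
#' @noRd
validate_trial_config <- function(cfg) {
  chk <- function(ok, param, msg) {
    if (!isTRUE(ok)) {
      rlang::abort(
        sprintf("Invalid trial_config parameter `%s`: %s", param, msg),
        class = "actibarq_config_error"
      )
    }
  }
  chk(is_count0(cfg$n_treatment), "n_treatment", "must be a non-negative integer")
  chk(is_count0(cfg$n_placebo), "n_placebo", "must be a non-negative integer")
  chk(cfg$n_treatment + cfg$n_placebo > 0, "n_treatment",
      "at least one arm must contain dogs")
  chk(is_count(cfg$baseline_days), "baseline_days", "must be a positive integer")
  chk(is_count(cfg$supplement_days), "supplement_days", "must be a positive integer")
  chk(cfg$baseline_days + cfg$supplement_days <= 35,
      "supplement_days", "baseline + supplement length may not exceed 35 days")
  chk(is_number(cfg$seed) && cfg$seed == floor(cfg$seed), "seed",
      "must be an integer")
  for (p in c("na_prob", "survey_response_prob", "emesis_prob_treatment",
              "emesis_prob_placebo", "diarrhea_prob_treatment",
              "diarrhea_prob_placebo")) {
    chk(is_number(cfg[[p]]) && cfg[[p]] >= 0 && cfg[[p]] <= 1, p,
        "must be a probability in [0, 1]")
  }
  for (p in c("daily_activity_mean", "daily_activity_sd_between_dogs",
              "daily_activity_sd_within_dog", "onset_sd_treatment",
              "onset_sd_placebo", "onset_between_sd", "arousal_rate")) {
    chk(is_number(cfg[[p]]) && cfg[[p]] >= 0, p, "must be non-negative")
  }
  chk(is_number(cfg$weekend_multiplier) && cfg$weekend_multiplier >= 1,
      "weekend_multiplier", "must be >= 1")
  chk(is_number(cfg$daytime_sleep_base) &&
        cfg$daytime_sleep_base > 0 && cfg$daytime_sleep_base < 1,
      "daytime_sleep_base", "must be a fraction in (0, 1)")
  chk(is_number(cfg$onset_mean) && cfg$onset_mean >= 19 * 60,
      "onset_mean", "sleep onset must not precede 19:00")
  chk(is_number(cfg$wake_mean) && cfg$wake_mean >= 5 * 60,
      "wake_mean", "wake time must not precede 05:00")
  chk(inherits(cfg$thresholds, "activity_thresholds"), "thresholds",
      "must be an activity_thresholds() object")
  if (!is.null(cfg$interaction_slope)) {
    chk(is_number(cfg$interaction_slope), "interaction_slope",
        "must be a single number")
    cfg$treatment_activity_slope <-
      cfg$placebo_activity_slope + cfg$interaction_slope
  }
  cfg
}

#' Activity classification thresholds
#'
#' Cut points (device units per minute) separating sleep from light, light
#' from moderate, and moderate from high activity. The device vendor's own
#' rest/active/play thresholds are proprietary, so these are configurable;
#' the defaults define "sleep" as below 5 units/minute.
#'
#' @param light,moderate,high Strictly increasing positive cut points.
#' @return A list of class `activity_thresholds`.
#' @export
#' @examples
#' activity_thresholds()
activity_thresholds <- function(light = 5, moderate = 20, high = 60) {
  if (!(is_number(light) && is_number(moderate) && is_number(high)) ||
      !(0 < light && light < moderate && moderate < high)) {
    rlang::abort(
      "Invalid activity_thresholds: need 0 < light < moderate < high",
      class = "actibarq_config_error"
    )
  }
  structure(list(light = light, moderate = moderate, high = high),
            class = "activity_thresholds")
}

#' @export
print.trial_config <- function(x, ...) {
  cat("<trial_config>\n")
  cat(sprintf("  arms: %d treatment / %d placebo\n", x$n_treatment, x$n_placebo))
  cat(sprintf("  phases: %d baseline + %d supplement days (start %s)\n",
              x$baseline_days, x$supplement_days, format(x$start_date)))
  cat(sprintf("  activity: mean %.0f u/day (SD %.0f between, %.0f within)\n",
              x$daily_activity_mean, x$daily_activity_sd_between_dogs,
              x$daily_activity_sd_within_dog))
  cat(sprintf("  slopes: treatment %+.2f, placebo %+.2f u/day\n",
              x$treatment_activity_slope, x$placebo_activity_slope))
  cat(sprintf("  settling: %+.1f%% / %+.1f%%; sleep delta %+.1f / %+.1f pp\n",
              x$settling_pct_treatment, x$settling_pct_placebo,
              x$daytime_sleep_delta_treatment, x$daytime_sleep_delta_placebo))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
is_count <- function(x) is_number(x) && x > 0 && x == floor(x)
is_count0 <- function(x) is_number(x) && x >= 0 && x == floor(x)

# Per-dog, per-stream substream seed of the root seed. Kept below 2^31 so it
# is always a valid R integer.
stream_seed <- function(seed, dog_index, stream = c("trace", "cbarq", "survey", "dog")) {
  stream <- match.arg(stream)
  offs <- c(trace = 1L, cbarq = 2L, survey = 3L, dog = 4L)[[stream]]
  as.integer((abs(seed) + 104729 * dog_index + 7919 * offs) %% .Machine$integer.max)
}
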