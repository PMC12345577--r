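test_that("identical seeds give identical output; different seeds differ", {
  cfg <- tiny_config()
  t1 <- simulate_trace(1, "treatment", cfg)
  t2 <- simulate_trace(1, "treatment", cfg)
  expect_identical(t1, t2)

  trial_a <- simulate_trial(tiny_config(), traces = FALSE)
  trial_b <- simulate_trial(tiny_config(), traces = FALSE)
  expect_identical(trial_a$cbarq, trial_b$cbarq)
  expect_identical(trial_a$surveys, trial_b$surveys)

  other <- simulate_trace(1, "treatment", tiny_config(seed = 999))
  expect_false(identical(t1$activity, other$activity))
  expect_identical(names(t1), names(other))
})

test_that("adding a dog never perturbs existing dogs' streams", {
  small <- trial_config(seed = 5, n_treatment = 2, n_placebo = 1)
  large <- trial_config(seed = 5, n_treatment = 3, n_placebo = 1)
  expect_identical(simulate_trace(1, "treatment", small),
                   simulate_trace(1, "treatment", large))
  expect_identical(simulate_cbarq(2, "treatment", small),
                   simulate_cbarq(2, "treatment", large))
})

test_that("degenerate noise with flat slopes yields identical weekday totals", {
  cfg <- trial_config(
    seed = 3, n_treatment = 1, n_placebo = 0,
    daily_activity_sd_between_dogs = 0, daily_activity_sd_within_dog = 0,
    treatment_activity_slope = 0, placebo_activity_slope = 0,
    onset_sd_treatment = 0, onset_sd_placebo = 0, onset_between_sd = 0,
    settling_pct_treatment = 0, daytime_sleep_delta_treatment = 0,
    morning_boost_pct_treatment = 0, arousal_rate = 0, minute_noise = FALSE
  )
  tr <- simulate_trace(1, "treatment", cfg)
  wd <- filter_weekdays(daily_totals(tr))
  expect_equal(length(unique(round(wd$total, 6))), 1L)
  expect_equal(unique(round(wd$total, 6)), cfg$daily_activity_mean)
})

test_that("trace structure matches the study design", {
  cfg <- tiny_config()
  tr <- simulate_trace(1, "treatment", cfg)
  expect_equal(nrow(tr), 35 * 1440)
  expect_true(all(tr$activity >= 0))
  expect_equal(sort(unique(tr$study_day)), 0:34)
  expect_setequal(unique(tr$phase[tr$study_day < 7]), "baseline")
  expect_setequal(unique(tr$phase[tr$study_day >= 7]), "supplement")
  # timestamps strictly increasing at 1-minute cadence
  expect_true(all(diff(as.numeric(tr$datetime)) == 60))
})

test_that("weekend totals exceed weekday totals by construction", {
  cfg <- trial_config(seed = 21, n_treatment = 30, n_placebo = 0,
                      weekend_multiplier = 1.3)
  daily <- simulate_daily_totals(cfg)
  base <- daily[daily$phase == "baseline", ]
  expect_gt(mean(base$total[!base$weekday]), mean(base$total[base$weekday]))
  # weekday filtering therefore lowers the mean daily total
  expect_lt(mean(filter_weekdays(base)$total), mean(base$total))
})

test_that("weekday daily totals are calibrated to the configured mean", {
  cfg <- trial_config(seed = 33, n_treatment = 400, n_placebo = 0)
  daily <- simulate_daily_totals(cfg)
  base <- daily[daily$weekday & daily$phase == "baseline", ]
  expect_lt(abs(mean(base$total) / cfg$daily_activity_mean - 1), 0.02)
})

test_that("trace daily totals agree with the day-level generator's targets", {
  cfg <- trial_config(seed = 8, n_treatment = 12, n_placebo = 0)
  daily <- simulate_daily_totals(cfg)
  traced <- dplyr::bind_rows(
    lapply(1:12, function(i) daily_totals(simulate_trace(i, "treatment", cfg)))
  )
  m <- dplyr::inner_join(daily, traced, by = c("dog_id", "study_day"),
                         suffix = c("_target", "_trace"))
  # minute noise is mean-one: realized totals track targets closely
  expect_lt(abs(mean(m$total_trace - m$total_target)), 60)
  expect_gt(stats::cor(m$total_trace, m$total_target), 0.98)
})

test_that("default trial has the 28/12 arm split and full schema", {
  cfg <- trial_config(seed = 2)
  trial <- simulate_trial(cfg, traces = FALSE)
  expect_equal(nrow(trial$dogs), 40)
  expect_equal(sum(trial$dogs$arm == "treatment"), 28)
  expect_equal(sum(trial$dogs$arm == "placebo"), 12)
  expect_equal(nrow(trial$cbarq), 40 * 100 * 2)
  expect_equal(nrow(trial$surveys), 40 * 5)
  gt <- trial$ground_truth
  expect_equal(gt$effects$settling_pct_treatment, cfg$settling_pct_treatment)
  expect_equal(gt$effects$interaction_slope,
               cfg$treatment_activity_slope - cfg$placebo_activity_slope)
  expect_equal(nrow(gt$true_sleep), 40 * 35)
})

test_that("single-arm datasets are allowed but between-arm analyses refuse them", {
  cfg <- trial_config(seed = 4, n_treatment = 0, n_placebo = 3)
  trial <- simulate_trial(cfg, traces = FALSE)
  expect_equal(unique(trial$dogs$arm), "placebo")
  daily <- simulate_daily_totals(cfg)
  expect_error(fit_activity_model(daily), class = "actibarq_stats_error")
})

test_that("survey generation matches its Bernoulli design", {
  cfg_all <- trial_config(seed = 6, survey_response_prob = 1)
  s <- dplyr::bind_rows(lapply(1:40, function(i) {
    simulate_surveys(i, if (i <= 28) "treatment" else "placebo", cfg_all)
  }))
  expect_equal(nrow(s), 200)
  expect_true(all(s$responded))
  expect_equal(sort(unique(s$day)), c(7, 14, 21, 28, 35))

  cfg_none <- trial_config(seed = 6, emesis_prob_treatment = 0,
                           emesis_prob_placebo = 0)
  s0 <- dplyr::bind_rows(lapply(1:40, function(i) {
    simulate_surveys(i, if (i <= 28) "treatment" else "placebo", cfg_none)
  }))
  expect_equal(sum(s0$emesis, na.rm = TRUE), 0)
})

test_that("collected survey count matches the binomial expectation", {
  # 40 dogs x 5 surveys x 0.73 response = 146 expected
  collected <- vapply(1:600, function(r) {
    cfg <- trial_config(seed = 50000 + r)
    s <- dplyr::bind_rows(lapply(seq_len(40), function(i) {
      simulate_surveys(i, if (i <= 28) "treatment" else "placebo", cfg)
    }))
    sum(s$responded)
  }, numeric(1))
  expect_lt(abs(mean(collected) - 146), 1)
})

test_that("C-BARQ generator honors na_prob extremes and the null case", {
  cfg_na <- tiny_config(na_prob = 1)
  r <- simulate_cbarq(1, "treatment", cfg_na)
  expect_true(all(r$label == cbarq_na_label()))

  # no injected effect: day0 and day35 domain means agree in expectation
  diffs <- vapply(1:150, function(rep) {
    cfg <- trial_config(seed = 7000 + rep, n_treatment = 4, n_placebo = 0,
                        cbarq_effects = c(Aggression = 0), na_prob = 0)
    sc <- score_cbarq(dplyr::bind_rows(
      lapply(1:4, function(i) simulate_cbarq(i, "treatment", cfg))
    ))
    ds <- domain_scores(sc)
    agg <- ds[ds$domain == "Aggression", ]
    mean(agg$score[agg$timepoint == "day35"]) -
      mean(agg$score[agg$timepoint == "day0"])
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 0.05)
})

test_that("latent-shift inversion hits the requested score gap", {
  cfg <- trial_config(seed = 1)
  for (gap in c(0.2, 0.48)) {
    delta <- cbarq_effect_for_gap(gap, cfg)
    achieved <- expected_domain_score(1 + delta, cfg) -
      expected_domain_score(1, cfg)
    expect_equal(achieved, gap, tolerance = 1e-6)
  }
})
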