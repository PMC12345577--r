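test_that("weekday filter drops Saturdays/Sundays and flags all-weekend input", {
  tr <- make_trace(0:6, function(tod, d) rep(1, 1440))  # starts Monday
  wd <- filter_weekdays(tr)
  expect_equal(length(unique(wd$study_day)), 5L)
  expect_false(any(format(wd$date, "%u") %in% c("6", "7")))

  we <- tr[format(tr$date, "%u") %in% c("6", "7"), ]
  out <- filter_weekdays(we)
  expect_equal(nrow(out), 0L)
  expect_true(isTRUE(attr(out, "all_weekend")))
})

test_that("daily totals sum minutes and omit empty days", {
  tr <- make_trace(0:1, function(tod, d) rep(1, 1440))
  dt <- daily_totals(tr)
  expect_equal(dt$total, c(1440, 1440))

  # an absent day is absent from the result, not zero
  tr_gap <- tr[tr$study_day != 1, ]
  dt_gap <- daily_totals(tr_gap)
  expect_equal(dt_gap$study_day, 0)
})

test_that("composition classifies by thresholds and fractions sum to one", {
  tr0 <- make_trace(0, function(tod, d) rep(0, 1440))
  c0 <- activity_composition(tr0)
  expect_equal(c0$f_sleep, 1)

  # one minute in each class
  tr4 <- make_trace(0, function(tod, d) {
    x <- rep(-1, 1440); x[361:364] <- c(0, 10, 30, 100); x
  })
  tr4 <- tr4[tr4$minute_of_day %in% 360:363, ]
  c4 <- activity_composition(tr4)
  expect_equal(unlist(c4[, c("f_sleep", "f_low", "f_moderate", "f_high")],
                      use.names = FALSE),
               rep(0.25, 4))

  cfg <- tiny_config()
  comp <- activity_composition(simulate_trace(1, "treatment", cfg))
  sums <- rowSums(comp[, c("f_sleep", "f_low", "f_moderate", "f_high")])
  expect_true(all(abs(sums - 1) < 1e-9))

  expect_error(activity_composition(tr0[0, ]), class = "actibarq_empty_window")
})

test_that("raising the light threshold never decreases the sleep fraction", {
  cfg <- tiny_config()
  tr <- simulate_trace(2, "placebo", cfg)
  f <- vapply(c(2, 5, 10, 19), function(thr) {
    mean(activity_composition(tr, activity_thresholds(light = thr))$f_sleep)
  }, numeric(1))
  expect_true(all(diff(f) >= 0))
})

test_that("onset and wake detection honor window definitions and bursts", {
  th <- activity_thresholds()
  # quiet from 19:00 -> onset exactly 19:00
  tr <- make_trace(0, function(tod, d) ifelse(tod >= 1140, 0, 50))
  ev <- detect_sleep_events(tr, th)
  expect_equal(ev$onset_time, 1140L)

  # active until 21:30, then quiet -> onset 21:30
  tr2 <- make_trace(0, function(tod, d) ifelse(tod >= 1290, 0, 50))
  expect_equal(detect_sleep_events(tr2, th)$onset_time, 1290L)

  # 14 quiet minutes, a one-minute burst, then quiet: window must be unbroken
  tr3 <- make_trace(0, function(tod, d) {
    x <- ifelse(tod >= 1140, 0, 50); x[tod == 1154] <- 30; x
  })
  expect_equal(detect_sleep_events(tr3, th)$onset_time, 1155L)

  # wake mirrors: sustained activity from 05:00 -> 05:00; from 07:10 -> 07:10
  tr4 <- make_trace(0, function(tod, d) ifelse(tod >= 300, 50, 0))
  expect_equal(detect_sleep_events(tr4, th)$wake_time, 300L)
  tr5 <- make_trace(0, function(tod, d) ifelse(tod >= 430, 50, 0))
  expect_equal(detect_sleep_events(tr5, th)$wake_time, 430L)

  # boundary: exactly at threshold counts as awake (non-strict "exceeding")
  tr6 <- make_trace(0, function(tod, d) ifelse(tod >= 1140, th$light, 50))
  expect_true(is.na(detect_sleep_events(tr6, th)$onset_time))

  # nights with no qualifying pre-midnight window are absent, not an error
  tr7 <- make_trace(0, function(tod, d) rep(50, 1440))
  expect_true(is.na(detect_sleep_events(tr7, th)$onset_time))
})

test_that("missing minutes disqualify candidate windows", {
  tr <- make_trace(0, function(tod, d) ifelse(tod >= 1140, 0, 50))
  tr_gap <- tr[!(tr$minute_of_day %in% 1145:1147), ]
  ev <- detect_sleep_events(tr_gap)
  expect_equal(ev$onset_time, 1148L)
})

test_that("detection equals the brute-force oracle and is translation-equivariant", {
  set.seed(404)
  th <- activity_thresholds()
  for (i in 1:60) {
    x <- pmax(0, stats::rnorm(1440, mean = sample(c(3, 5, 8), 1), sd = 4))
    tr <- make_trace(0, function(tod, d) x)
    ev <- detect_sleep_events(tr, th)
    expect_identical(ev$onset_time, brute_onset(x))
    expect_identical(ev$wake_time, brute_wake(x))
  }
  # shifting the pattern by k minutes shifts detections by k (within bounds)
  base <- c(rep(50, 1200), rep(0, 240))
  for (k in c(5, 30)) {
    shifted <- c(rep(50, 1200 + k), rep(0, 240 - k))
    t_base <- detect_sleep_events(make_trace(0, function(tod, d) base), th)
    t_shift <- detect_sleep_events(make_trace(0, function(tod, d) shifted), th)
    expect_equal(t_shift$onset_time, t_base$onset_time + k)
  }
})

test_that("drift regression recovers constant and linear onset schedules", {
  mk_events <- function(f) {
    tibble::tibble(
      dog_id = "d1", arm = "placebo", study_day = 7:34,
      phase = "supplement",
      onset_time = f(7:34), wake_time = 350
    )
  }
  cons <- event_drift(mk_events(function(d) rep(1200, length(d))), "onset")
  expect_equal(cons$slope_min_per_day, 0, tolerance = 1e-10)
  expect_equal(cons$sd_minutes, 0)

  lin <- event_drift(mk_events(function(d) 1200 + 2 * d), "onset")
  expect_equal(lin$slope_min_per_day, 2, tolerance = 1e-10)

  few <- mk_events(function(d) 1200 + d)[1:5, ]
  expect_error(event_drift(few, "onset"),
               class = "actibarq_insufficient_events")
})

test_that("placebo onset drift is recovered from generated traces", {
  cfg <- trial_config(seed = 31, n_treatment = 0, n_placebo = 12,
                      onset_drift_placebo = -1.5)
  ev <- dplyr::bind_rows(lapply(1:12, function(i) {
    detect_sleep_events(simulate_trace(i, "placebo", cfg))
  }))
  dr <- event_drift(filter_weekdays(ev), "onset")
  expect_equal(dr$slope_min_per_day, -1.5, tolerance = 0.3)
})

test_that("settling index computes the documented arithmetic", {
  # hour 1 at 100, hour 2 at 82.2 -> exactly -17.8
  tr <- make_trace(7, function(tod, d) {
    x <- rep(0, 1440); x[481:540] <- 100; x[541:600] <- 82.2; x
  })
  s <- settling_index(tr)
  expect_equal(s$settling_pct, -17.8, tolerance = 1e-10)

  # flat trace -> 0
  tr_flat <- make_trace(7, function(tod, d) rep(30, 1440))
  expect_equal(settling_index(tr_flat)$settling_pct, 0)

  # scale invariance: multiplying activity by c > 0 leaves the index unchanged
  tr2 <- tr
  tr2$activity <- tr2$activity * 3.7
  expect_equal(settling_index(tr2)$settling_pct, s$settling_pct)

  # zero first-hour mean is flagged, never divided through
  tr0 <- make_trace(7, function(tod, d) {
    x <- rep(0, 1440); x[541:600] <- 10; x
  })
  s0 <- settling_index(tr0)
  expect_equal(s0$n_undefined, 1L)
  expect_true(is.na(s0$settling_pct) | s0$n_days == 0)
})

test_that("morning activity doubles when supplement mornings double", {
  tr <- dplyr::bind_rows(
    make_trace(0:6, function(tod, d) ifelse(tod >= 360 & tod < 480, 10, 1)),
    make_trace(7:13, function(tod, d) ifelse(tod >= 360 & tod < 480, 20, 1))
  )
  mo <- morning_activity(tr)
  base <- mo$mean_activity[mo$phase == "baseline"]
  supp <- mo$mean_activity[mo$phase == "supplement"]
  expect_equal(supp / base, 2)

  # identical phases give zero paired differences
  tr_same <- make_trace(0:13, function(tod, d) ifelse(tod < 480, 5, 1))
  mo2 <- morning_activity(tr_same)
  expect_equal(diff(mo2$mean_activity), 0)
})
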