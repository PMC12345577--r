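bank <- cbarq_item_bank()

test_that("item bank is structurally faithful", {
  expect_gte(nrow(bank), 100)
  expect_setequal(unique(bank$domain), cbarq_domains())
  expect_equal(anyDuplicated(bank$item_id), 0L)
  expect_true(all(vapply(bank$labels, length, integer(1)) == 5))
})

test_that("scoring maps labels monotonically with positive traits high", {
  expect_equal(score_item("No aggression", "agg_01", bank), 5L)
  expect_equal(score_item("Serious aggression", "agg_01", bank), 1L)
  expect_equal(score_item("Moderate aggression", "agg_01", bank), 3L)
  expect_true(is.na(score_item(cbarq_na_label(), "agg_01", bank)))
  expect_error(score_item("Not a label", "agg_01", bank), "agg_01")
  expect_error(score_item("No aggression", "nope_01", bank), "nope_01")
})

test_that("domain scores average non-missing items and flag empty domains", {
  resp <- tibble::tibble(
    dog_id = "d1", timepoint = "day0",
    item_id = c("agg_01", "agg_02", "agg_03"),
    label = c("No aggression", "Mild aggression", "Moderate aggression")
  )
  ds <- domain_scores(score_cbarq(resp, bank))
  expect_equal(ds$score, mean(c(5, 4, 3)))
  expect_equal(ds$n_items_used, 3L)

  resp2 <- resp
  resp2$label <- c("No aggression", cbarq_na_label(), cbarq_na_label())
  ds2 <- domain_scores(score_cbarq(resp2, bank))
  expect_equal(ds2$score, 5)
  expect_equal(ds2$n_items_used, 1L)

  resp3 <- resp
  resp3$label <- rep(cbarq_na_label(), 3)
  ds3 <- domain_scores(score_cbarq(resp3, bank))
  expect_true(is.na(ds3$score))
  expect_equal(ds3$n_items_used, 0L)
})

test_that("general anxiety pools items rather than averaging domain means", {
  resp <- tibble::tibble(
    dog_id = "d1", timepoint = "day0",
    item_id = c("fear_01", "fear_02", "sep_01"),
    label = c("Mild fear", "Mild fear", "Severe fear")
  )
  ga <- general_anxiety_scores(score_cbarq(resp, bank))
  expect_equal(ga$score, (4 + 4 + 2) / 3)   # pooled, not (4 + 2) / 2
  expect_equal(ga$domain, "General Anxiety")

  # composite lies between the two contributing domain means
  sc <- score_cbarq(resp, bank)
  dm <- domain_scores(sc)
  expect_true(ga$score >= min(dm$score) && ga$score <= max(dm$score))

  # identical domain means -> composite equals them
  resp_eq <- tibble::tibble(
    dog_id = "d1", timepoint = "day0",
    item_id = c("fear_01", "sep_01"),
    label = c("Moderate fear", "Moderate fear")
  )
  expect_equal(general_anxiety_scores(score_cbarq(resp_eq, bank))$score, 3)
})

test_that("scoring is order-preserving: a more positive answer never lowers a score", {
  cfg <- tiny_config(na_prob = 0.2)
  for (s in 1:5) {
    cfg_s <- tiny_config(seed = 100 + s, na_prob = 0.2)
    resp <- simulate_cbarq(1, "treatment", cfg_s, timepoint = "day0")
    sc <- score_cbarq(resp, bank)
    base <- domain_scores(sc)
    # pick a scored (non-NA) item and promote it one step
    idx <- which(!is.na(sc$score) & sc$score < 5)[1]
    row <- match(sc$item_id[idx], bank$item_id)
    resp2 <- resp
    resp2$label[idx] <- bank$labels[[row]][sc$score[idx] + 1L]
    bumped <- domain_scores(score_cbarq(resp2, bank))
    cmp <- dplyr::inner_join(base, bumped, by = "domain",
                             suffix = c("_a", "_b"))
    expect_true(all(cmp$score_b >= cmp$score_a, na.rm = TRUE))
  }
})

test_that("domain scores are invariant to item order and all-NA padding", {
  cfg <- tiny_config(na_prob = 0.1)
  resp <- simulate_cbarq(1, "treatment", cfg, timepoint = "day0")
  sc1 <- domain_scores(score_cbarq(resp, bank))
  shuffled <- resp[sample(nrow(resp)), ]
  sc2 <- domain_scores(score_cbarq(shuffled, bank))
  expect_equal(dplyr::arrange(sc1, domain), dplyr::arrange(sc2, domain))

  padded <- dplyr::bind_rows(
    resp[resp$label != cbarq_na_label(), ],
    dplyr::mutate(resp[resp$label != cbarq_na_label(), ],
                  label = cbarq_na_label()) |>
      dplyr::slice_head(n = 5)
  )
  # adding all-NA duplicate responses cannot change any domain mean
  sc3 <- domain_scores(score_cbarq(padded, bank))
  sc1_nona <- domain_scores(score_cbarq(resp[resp$label != cbarq_na_label(), ],
                                        bank))
  expect_equal(dplyr::arrange(sc1_nona, domain)$score,
               dplyr::arrange(sc3, domain)$score)
})

test_that("item change ranking orders by absolute mean paired change", {
  base <- tibble::tibble(
    dog_id = "d1", timepoint = "day0",
    item_id = c("agg_01", "agg_02"),
    label = c("Moderate aggression", "Moderate aggression")
  )
  d35 <- tibble::tibble(
    dog_id = "d1", timepoint = "day35",
    item_id = c("agg_01", "agg_02"),
    label = c("No aggression", "Moderate aggression")
  )
  rk <- rank_item_changes(score_cbarq(dplyr::bind_rows(base, d35), bank))
  expect_equal(rk$item_id[1], "agg_01")
  expect_equal(rk$mean_change[1], 2)   # 3 -> 5
  expect_equal(rk$mean_change[rk$item_id == "agg_02"], 0)

  # no change anywhere -> all zeros, ties broken lexicographically
  rk0 <- rank_item_changes(score_cbarq(dplyr::bind_rows(
    base, dplyr::mutate(base, timepoint = "day35")
  ), bank))
  expect_true(all(rk0$mean_change == 0))
  expect_equal(rk0$item_id, sort(rk0$item_id))
})

test_that("aggression-targeted effect concentrates top-10 changes in that domain", {
  cfg0 <- trial_config(seed = 1)
  delta <- cbarq_effect_for_gap(0.48, cfg0)
  n_agg <- vapply(1:9, function(s) {
    cfg <- trial_config(seed = 8000 + s, cbarq_effects = c(Aggression = delta))
    trial <- simulate_trial(cfg, traces = FALSE)
    top <- rank_item_changes(score_cbarq(trial$cbarq, bank),
                             arm = "treatment", top_n = 10)
    sum(top$domain == "Aggression")
  }, numeric(1))
  expect_gte(stats::median(n_agg), 7)
})

test_that("raw-export convention stores NA as 0 and restores it at load", {
  resp <- tibble::tibble(
    dog_id = "d1", timepoint = "day0",
    item_id = c("agg_01", "agg_02"),
    label = c("No aggression", cbarq_na_label())
  )
  sc <- score_cbarq(resp, bank)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cbarq_scores(sc, path)
  raw <- utils::read.csv(path)
  expect_equal(raw$score, c(5, 0))   # 0 on disk
  back <- read_cbarq_scores(path)
  expect_equal(back$score, c(5L, NA_integer_))   # explicit NA in memory
})
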