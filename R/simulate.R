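# Synthetic-trial generator.
#
# The generator is constructed so that every configured effect is the exact
# expectation of the downstream estimator that measures it:
#  * hour 2 of the post-departure window is generated conditional on the
#    realized hour-1 mean, so the per-day settling index has expectation
#    exactly `settling_pct_*`;
#  * every non-quiescent daytime minute is generated at or above the light
#    threshold (threshold + positive excess), so the daytime sleep fraction
#    equals the quiescent probability and the configured sleep delta is
#    recovered without threshold-crossing leakage;
#  * the per-minute day profile is scaled so its expected sum equals the
#    day's target total, which carries the arm's linear trend from the first
#    supplementation day onward.

DAY_MIN <- 1440L
MORN_START <- 360L   # 06:00
DEPART <- 480L       # 08:00, average caregiver departure
H2_START <- 540L
H2_END <- 600L
EVE_START <- 1140L   # 19:00
DAYTIME_END <- 1320L # 22:00
LN_SDLOG <- 0.9      # minute-level multiplicative noise (mean-one lognormal)
SETTLE_AMP <- 2      # fixed hour-1 excess above the light threshold
SENT_SPACE <- 10L    # evening sentinel spacing, anchored at onset - 1
WAKE_RAMP <- 15L     # forced-active minutes from wake, so wake detection is exact
# nap-eligible minutes of the 06:00-22:00 window: morning (120) + midday
# (540) + evening non-sentinel (180 - 18); naps elsewhere are structural
N_NAP_NOMINAL <- 120 + 540 + 162

#' @keywords internal
#' @noRd
mean_one_lnorm <- function(n, sdlog = LN_SDLOG) {
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

arm_par <- function(cfg, base, arm) {
  cfg[[paste0(base, "_", arm)]]
}

# Day-level parameters for one dog, shared by simulate_trace() and
# simulate_daily_totals() so both views of a dog agree. All random draws
# come from the dog's own "trace" substream, in a fixed order.
.dog_day_params <- function(dog_index, arm, cfg) {
  set.seed(stream_seed(cfg$seed, dog_index, "trace"))
  n_days <- cfg$baseline_days + cfg$supplement_days
  d <- seq_len(n_days) - 1L
  t_supp <- pmax(0, d - cfg$baseline_days)        # 0 during baseline
  supp <- d >= cfg$baseline_days

  mu <- stats::rnorm(1, cfg$daily_activity_mean, cfg$daily_activity_sd_between_dogs)
  onset_mu <- stats::rnorm(1, cfg$onset_mean, cfg$onset_between_sd)
  wake_mu <- stats::rnorm(1, cfg$wake_mean, 0.8 * cfg$onset_between_sd)

  onset_sd <- arm_par(cfg, "onset_sd", arm)
  onset <- onset_mu + arm_par(cfg, "onset_drift", arm) * t_supp +
    stats::rnorm(n_days, 0, onset_sd)
  wake <- wake_mu + arm_par(cfg, "wake_drift", arm) * t_supp +
    stats::rnorm(n_days, 0, 0.6 * onset_sd)
  onset <- as.integer(round(pmin(pmax(onset, EVE_START + 25), 1430)))
  wake <- as.integer(round(pmin(pmax(wake, 310), 445)))

  date <- cfg$start_date + d
  weekend <- format(date, "%u") %in% c("6", "7")
  slope <- cfg[[paste0(arm, "_activity_slope")]]
  total <- mu + slope * t_supp +
    stats::rnorm(n_days, 0, cfg$daily_activity_sd_within_dog)
  total <- total * ifelse(weekend, cfg$weekend_multiplier, 1)
  total <- pmax(total, 100)

  # quiescent (nap) probability: calibrated so the daytime sleep fraction
  # of the 06:00-22:00 window equals daytime_sleep_base at baseline and
  # moves by the configured delta (percentage points) during
  # supplementation; only nap-eligible minutes can be quiescent
  q_base <- cfg$daytime_sleep_base * (DAYTIME_END - MORN_START) / N_NAP_NOMINAL
  dq <- (arm_par(cfg, "daytime_sleep_delta", arm) / 100) *
    (DAYTIME_END - MORN_START) / N_NAP_NOMINAL
  q <- pmin(pmax(q_base + dq * supp, 0.02), 0.95)

  settle <- ifelse(supp, arm_par(cfg, "settling_pct", arm), cfg$settling_pct_baseline)
  r <- 1 + settle / 100
  boost <- 1 + (arm_par(cfg, "morning_boost_pct", arm) / 100) * supp

  list(
    mu = mu, onset_mu = onset_mu, wake_mu = wake_mu,
    study_day = d, date = date, weekend = weekend, supp = supp,
    onset = onset, wake = wake, total = total, q = q, r = r, boost = boost
  )
}

# Evening sentinel minutes: forced-active markers every SENT_SPACE minutes
# through [19:00, onset), anchored at onset - 1 so no 15-minute all-quiet
# window can occur before the true sleep onset (detection is exact).
sentinel_pos <- function(onset) {
  if (onset - 1 < EVE_START) return(integer(0))
  seq.int(onset - 1L, EVE_START, by = -SENT_SPACE)
}

# Expected-sum budget of the day profile: E[sum of minutes] = F + C * B,
# linear in the burst-excess scale B, solved per day so expected minute
# sums equal the day's target total. B is floored at 0.2: days whose target
# falls below the structural floor (night + threshold-level active minutes)
# slightly overshoot it.
.day_budget <- function(p, cfg) {
  n_days <- length(p$onset)
  f <- numeric(n_days)
  cc <- numeric(n_days)
  burst_e <- if (cfg$minute_noise) cfg$arousal_rate * 2 * 25 else 0
  for (d in seq_len(n_days)) {
    onset <- p$onset[d]; wake <- p$wake[d]
    q <- p$q[d]; r <- p$r[d]; boost <- p$boost[d]
    sp <- sentinel_pos(onset)
    n_s1 <- sum(sp < DAYTIME_END)
    n_s2 <- length(sp) - n_s1
    n_night <- wake + (DAY_MIN - onset)
    n_strip <- max(0L, MORN_START - wake)
    # first 15 post-wake minutes are forced active (wake detection support);
    # n_pw is the part that spills past 06:00 into the morning window
    n_pw <- max(0L, wake + WAKE_RAMP - max(MORN_START, wake))
    n_em <- (DEPART - MORN_START) - max(0L, wake - MORN_START) - n_pw
    n_e1q <- (min(onset, DAYTIME_END) - EVE_START) - n_s1
    n_e2q <- max(0L, onset - DAYTIME_END) - n_s2
    n_elig <- n_em + (EVE_START - H2_END) + n_e1q
    f[d] <- 0.5 * n_night + burst_e +
      5 * (n_strip + n_pw) +
      n_elig * (1.5 * q + 5 * (1 - q)) +
      60 * (5 + SETTLE_AMP) * (1 + r) +
      5 * (n_s1 + n_s2) + 1 * n_e2q
    cc[d] <- 0.8 * (n_strip + n_pw) +
      (1 - q) * (n_em * boost + (EVE_START - H2_END) + n_e1q) +
      n_s1 + 0.8 * n_s2
  }
  list(f = f, c = cc, b = pmax(0.2, (p$total - f) / cc))
}

#' Simulate one dog's minute-resolution activity trace
#'
#' Generates a full study of minute-level activity (1440 samples/day) with
#' the circadian structure the analysis targets: a quiet night between sleep
#' onset and wake (with brief Poisson arousal bursts), a 06:00-08:00 morning
#' window, an elevated post-departure hour followed by a settling hour
#' (08:00-10:00), nap-interspersed daytime, and an active evening until
#' sleep onset. Weekday daily totals are drawn around the configured mean
#' with the arm's linear trend from the first supplementation day; weekends
#' are inflated by the weekend multiplier.
#'
#' @param dog_index 1-based index of the dog (selects its random substream).
#' @param arm `"treatment"` or `"placebo"`.
#' @param config A [trial_config()].
#' @param dog_id Identifier stored in the output (default derived from
#'   `dog_index`).
#' @return A tibble of class `activity_trace` with columns `dog_id`, `arm`,
#'   `study_day`, `date`, `minute_of_day`, `datetime`, `phase`, `activity`.
#' @export
#' @examples
#' cfg <- trial_config(seed = 1, n_treatment = 1, n_placebo = 0)
#' tr <- simulate_trace(1, "treatment", cfg)
#' nrow(tr) # 35 * 1440
simulate_trace <- function(dog_index, arm = c("treatment", "placebo"), config,
                           dog_id = sprintf("dog_%03d", dog_index)) {
  arm <- match.arg(arm)
  stopifnot(inherits(config, "trial_config"))
  p <- .dog_day_params(dog_index, arm, config)
  bud <- .day_budget(p, config)
  n_days <- length(p$study_day)
  n <- n_days * DAY_MIN

  tod <- rep.int(seq_len(DAY_MIN) - 1L, n_days)
  day_i <- rep(seq_len(n_days), each = DAY_MIN)
  onset_v <- p$onset[day_i]
  wake_v <- p$wake[day_i]
  b_v <- bud$b[day_i]
  q_v <- p$q[day_i]
  boost_v <- p$boost[day_i]

  night <- tod < wake_v | tod >= onset_v
  h1 <- tod >= DEPART & tod < H2_START
  h2 <- tod >= H2_START & tod < H2_END
  # evening sentinel minutes, anchored at each day's onset
  sent <- logical(n)
  for (d in seq_len(n_days)) {
    sent[(d - 1L) * DAY_MIN + sentinel_pos(p$onset[d]) + 1L] <- TRUE
  }
  sent1 <- sent & tod < DAYTIME_END
  sent2 <- sent & tod >= DAYTIME_END
  # forced-active ramp covering the first WAKE_RAMP minutes after wake
  ramp <- !night & tod < wake_v + WAKE_RAMP
  # nap-eligible minutes: morning, midday, and non-sentinel early evening
  elig <- !night & !sent & !ramp &
    ((tod >= MORN_START & tod < DEPART) |
       (tod >= H2_END & tod < EVE_START) |
       (tod >= EVE_START & tod < DAYTIME_END))
  strip <- !night & !ramp & tod < MORN_START   # wake before 06:00 minus ramp
  winddown <- !night & !sent & tod >= DAYTIME_END  # quiet late evening

  x <- numeric(n)
  if (config$minute_noise) {
    x[night] <- stats::runif(sum(night), 0, 1)
    ne <- sum(elig)
    quiesc <- stats::runif(ne) < q_v[elig]
    bf <- 1 + (boost_v[elig] - 1) * (tod[elig] < DEPART)
    ev <- numeric(ne)
    ev[quiesc] <- stats::runif(sum(quiesc), 0, 3)
    ev[!quiesc] <- 5 + b_v[elig][!quiesc] * bf[!quiesc] *
      mean_one_lnorm(sum(!quiesc))
    x[elig] <- ev
    strip_ramp <- strip | ramp
    x[strip_ramp] <- 5 + 0.8 * b_v[strip_ramp] * mean_one_lnorm(sum(strip_ramp))
    x[sent1] <- 5 + b_v[sent1] * mean_one_lnorm(sum(sent1))
    x[sent2] <- 5 + 0.8 * b_v[sent2] * mean_one_lnorm(sum(sent2))
    x[winddown] <- stats::runif(sum(winddown), 0, 2)
    x[h1] <- 5 + SETTLE_AMP * mean_one_lnorm(sum(h1))
    # hour 2 is pinned to the realized hour-1 mean so the per-day settling
    # index has expectation exactly the configured settling percent
    m1 <- colMeans(matrix(x[h1], nrow = H2_START - DEPART))
    e2 <- pmax(0.05, m1 * p$r - 5)
    x[h2] <- 5 + rep(e2, each = H2_END - H2_START) * mean_one_lnorm(sum(h2))
    # brief nighttime arousal bursts: they keep onset/wake detection honest
    n_b <- stats::rpois(n_days, config$arousal_rate)
    for (d in which(n_b > 0)) {
      night_pos <- c(seq_len(p$wake[d]) - 1L, seq.int(p$onset[d], DAY_MIN - 1L))
      for (k in seq_len(n_b[d])) {
        len <- sample.int(3L, 1L)
        start <- night_pos[sample.int(length(night_pos), 1L)]
        pos <- (d - 1L) * DAY_MIN + (start + seq_len(len) - 1L) %% DAY_MIN + 1L
        x[pos] <- 5 + stats::rlnorm(len, log(20) - 0.125, 0.5)
      }
    }
  } else {
    x[night] <- 0.5
    bf <- 1 + (boost_v[elig] - 1) * (tod[elig] < DEPART)
    x[elig] <- q_v[elig] * 1.5 + (1 - q_v[elig]) * (5 + b_v[elig] * bf)
    strip_ramp <- strip | ramp
    x[strip_ramp] <- 5 + 0.8 * b_v[strip_ramp]
    x[sent1] <- 5 + b_v[sent1]
    x[sent2] <- 5 + 0.8 * b_v[sent2]
    x[winddown] <- 1
    x[h1] <- 5 + SETTLE_AMP
    x[h2] <- (5 + SETTLE_AMP) * p$r[day_i[h2]]
  }

  phase_d <- c("baseline", "supplement")[p$supp + 1L]
  origin <- as.numeric(as.POSIXct(config$start_date, tz = "UTC"))
  # rows are in strict minute order, so the timestamp is a plain sequence
  datetime <- origin + 60 * (seq_len(n) - 1)
  class(datetime) <- c("POSIXct", "POSIXt")
  attr(datetime, "tzone") <- "UTC"
  out <- structure(
    list(
      dog_id = rep.int(dog_id, n),
      arm = rep.int(arm, n),
      study_day = day_i - 1L,
      date = p$date[day_i],
      minute_of_day = tod,
      datetime = datetime,
      phase = phase_d[day_i],
      activity = x
    ),
    class = c("activity_trace", "tbl_df", "tbl", "data.frame"),
    row.names = c(NA_integer_, -n)
  )
  out
}

#' Simulate daily activity totals for a whole cohort
#'
#' The fast day-level view of the generator: the same per-dog, per-day
#' target totals used by [simulate_trace()] (identical random substreams),
#' without materializing minute-level samples. Suitable for mixed-model and
#' trend recovery studies at many replicates.
#'
#' @param config A [trial_config()].
#' @return A tibble with `dog_id`, `arm`, `study_day`, `date`, `weekday`,
#'   `phase`, `total`.
#' @export
#' @examples
#' cfg <- trial_config(seed = 1)
#' head(simulate_daily_totals(cfg))
simulate_daily_totals <- function(config) {
  stopifnot(inherits(config, "trial_config"))
  dogs <- trial_arms(config)
  purrr::map2_dfr(dogs$dog_index, dogs$arm, function(i, arm) {
    p <- .dog_day_params(i, arm, config)
    tibble::tibble(
      dog_id = sprintf("dog_%03d", i),
      arm = arm,
      study_day = p$study_day,
      date = p$date,
      weekday = !p$weekend,
      phase = ifelse(p$supp, "supplement", "baseline"),
      total = p$total
    )
  })
}

trial_arms <- function(config) {
  tibble::tibble(
    dog_index = seq_len(config$n_treatment + config$n_placebo),
    arm = rep(c("treatment", "placebo"),
              c(config$n_treatment, config$n_placebo))
  )
}

#' Simulate a dog's C-BARQ responses
#'
#' Ordinal responses from a latent-propensity model: each dog carries a
#' latent trait per behavioral domain; an item response adds item-level
#' noise and is cut into the item's five ordered labels at fixed cut points
#' (-1.5, -0.5, 0.5, 1.5). Treatment dogs receive the configured latent
#' shifts (`cbarq_effects`) at day 35. Each item is independently replaced
#' by the "NA/Never Observed" label with probability `na_prob`. Latent
#' traits are shared between the two timepoints, so day-0/day-35 pairs are
#' correlated within dog.
#'
#' @inheritParams simulate_trace
#' @param timepoint `"day0"`, `"day35"`, or `"both"`.
#' @param bank Item bank from [cbarq_item_bank()].
#' @return Tibble with `dog_id`, `arm`, `timepoint`, `item_id`, `domain`,
#'   `label`.
#' @export
#' @examples
#' cfg <- trial_config(seed = 1)
#' head(simulate_cbarq(1, "treatment", cfg))
simulate_cbarq <- function(dog_index, arm = c("treatment", "placebo"), config,
                           timepoint = c("both", "day0", "day35"),
                           bank = cbarq_item_bank(),
                           dog_id = sprintf("dog_%03d", dog_index)) {
  arm <- match.arg(arm)
  timepoint <- match.arg(timepoint)
  stopifnot(inherits(config, "trial_config"))
  set.seed(stream_seed(config$seed, dog_index, "cbarq"))

  domains <- cbarq_domains()
  mu <- rep_len(cfg_domain_means(config), length(domains))
  names(mu) <- domains
  theta <- stats::rnorm(length(domains), mu, config$cbarq_trait_sd)
  names(theta) <- domains

  eff <- rep(0, length(domains))
  names(eff) <- domains
  if (arm == "treatment" && length(config$cbarq_effects)) {
    bad <- setdiff(names(config$cbarq_effects), domains)
    if (length(bad)) {
      rlang::abort(sprintf("Unknown C-BARQ domain in cbarq_effects: %s",
                           paste(bad, collapse = ", ")),
                   class = "actibarq_config_error")
    }
    eff[names(config$cbarq_effects)] <- config$cbarq_effects
  }

  one_tp <- function(tp) {
    th <- theta + if (tp == "day35") eff else 0
    z <- th[bank$domain] + stats::rnorm(nrow(bank), 0, config$cbarq_item_sd)
    score <- 1L + findInterval(z, c(-1.5, -0.5, 0.5, 1.5))
    lab <- mapply(function(l, s) l[[s]], bank$labels, score)
    na <- stats::runif(nrow(bank)) < config$na_prob
    lab[na] <- cbarq_na_label()
    tibble::tibble(dog_id = dog_id, arm = arm, timepoint = tp,
                   item_id = bank$item_id, domain = bank$domain, label = lab)
  }
  out <- dplyr::bind_rows(one_tp("day0"), one_tp("day35"))
  if (timepoint != "both") out <- out[out$timepoint == timepoint, ]
  out
}

cfg_domain_means <- function(config) {
  m <- config$cbarq_domain_means
  if (!is.null(names(m)) && length(m) > 1) {
    out <- rep(1.0, 7)
    names(out) <- cbarq_domains()
    out[names(m)] <- m
    out
  } else {
    rep_len(unname(m), 7)
  }
}

#' Latent shift producing a target domain-score gap
#'
#' Inverts the ordinal response model: finds the latent-trait shift that
#' moves the expected 1-5 domain score by `gap` points, given the
#' configuration's trait/item SDs, cut points and baseline domain mean.
#' Useful for calibrating `cbarq_effects` to a target between-arm mean
#' difference on the score scale.
#'
#' @param gap Target change in expected domain score (points on 1-5 scale).
#' @param config A [trial_config()].
#' @param domain Domain whose baseline mean anchors the inversion.
#' @return The latent shift (numeric scalar).
#' @export
#' @examples
#' cbarq_effect_for_gap(0.48, trial_config(seed = 1))
cbarq_effect_for_gap <- function(gap, config, domain = "Aggression") {
  mu0 <- cfg_domain_means(config)
  names(mu0) <- cbarq_domains()
  mu0 <- mu0[[domain]]
  f <- function(d) expected_domain_score(mu0 + d, config) -
    expected_domain_score(mu0, config) - gap
  stats::uniroot(f, c(-6, 6), tol = 1e-10)$root
}

#' Expected 1-5 domain score under the latent model
#'
#' @param mu Latent domain mean.
#' @param config A [trial_config()] (supplies trait and item SDs).
#' @return Expected mean item score.
#' @export
expected_domain_score <- function(mu, config) {
  s <- sqrt(config$cbarq_trait_sd^2 + config$cbarq_item_sd^2)
  1 + sum(stats::pnorm((mu - c(-1.5, -0.5, 0.5, 1.5)) / s))
}

#' Simulate weekly adverse-event surveys for one dog
#'
#' Surveys are scheduled at study days 7, 14, 21, 28 and 35; each is
#' returned independently with the configured response probability, and a
#' returned survey carries Bernoulli emesis/diarrhea flags at arm-specific
#' rates plus a 1-7 stool-quality score (higher = looser; shifted upward
#' when diarrhea is flagged).
#'
#' @inheritParams simulate_trace
#' @return Tibble with `dog_id`, `arm`, `day`, `responded`, `emesis`,
#'   `diarrhea`, `stool_score` (flags and score `NA` when not returned).
#' @export
simulate_surveys <- function(dog_index, arm = c("treatment", "placebo"), config,
                             dog_id = sprintf("dog_%03d", dog_index)) {
  arm <- match.arg(arm)
  stopifnot(inherits(config, "trial_config"))
  set.seed(stream_seed(config$seed, dog_index, "survey"))
  days <- c(7L, 14L, 21L, 28L, 35L)
  n <- length(days)
  responded <- stats::runif(n) < config$survey_response_prob
  emesis <- stats::runif(n) < arm_par(config, "emesis_prob", arm)
  diarrhea <- stats::runif(n) < arm_par(config, "diarrhea_prob", arm)
  stool <- pmin(pmax(round(stats::rnorm(n, 3.5 + 1.5 * diarrhea, 0.8)), 1), 7)
  tibble::tibble(
    dog_id = dog_id, arm = arm, day = days, responded = responded,
    emesis = ifelse(responded, emesis, NA),
    diarrhea = ifelse(responded, diarrhea, NA),
    stool_score = ifelse(responded, stool, NA_real_)
  )
}

#' Simulate enrollment metadata
#'
#' Weight, breed, sex, neuter status and diet drawn to match the cohort
#' composition the analysis summarizes (67.5% male, 87.5% neutered, 55%
#' standard dry diet); per-dog capsule dose follows the per-25-lbs rule.
#'
#' @param config A [trial_config()].
#' @return Tibble of `DogRecord`s: `dog_id`, `dog_index`, `arm`, `weight_lbs`,
#'   `breed`, `sex`, `neutered`, `diet`, `age_years`, `enrolled`,
#'   `capsules_per_day`.
#' @export
simulate_dogs <- function(config) {
  stopifnot(inherits(config, "trial_config"))
  arms <- trial_arms(config)
  breeds <- c("Mixed breed", "Labrador Retriever", "German Shepherd",
              "Golden Retriever", "Poodle", "Beagle", "Dachshund",
              "Border Collie", "Australian Shepherd", "Boxer")
  purrr::map2_dfr(arms$dog_index, arms$arm, function(i, arm) {
    set.seed(stream_seed(config$seed, i, "dog"))
    weight <- round(stats::rlnorm(1, log(40), 0.5), 1)
    tibble::tibble(
      dog_id = sprintf("dog_%03d", i),
      dog_index = i,
      arm = arm,
      weight_lbs = weight,
      breed = sample(breeds, 1, prob = c(0.3, rep(0.7 / 9, 9))),
      sex = sample(c("male", "female"), 1, prob = c(0.675, 0.325)),
      neutered = stats::runif(1) < 0.875,
      diet = sample(c("dry", "raw", "fresh", "air-dried", "mixed"), 1,
                    prob = c(0.55, 0.12, 0.12, 0.09, 0.12)),
      age_years = round(pmin(pmax(stats::rlnorm(1, log(4.6), 0.45), 1), 12), 1),
      enrolled = TRUE,
      capsules_per_day = dose_for_weight(weight)
    )
  })
}

#' Simulate a complete trial
#'
#' Generates all four data streams (metadata, minute traces, C-BARQ
#' responses at both timepoints, weekly surveys) plus a ground-truth record
#' of every injected effect and each dog's latent circadian parameters.
#' Deterministic given the configuration seed; each dog occupies its own
#' random substream, so adding dogs never perturbs existing ones.
#'
#' @param config A [trial_config()].
#' @param traces Logical; set `FALSE` to skip minute-trace generation (the
#'   slow stream) when only day-level data are needed.
#' @return A list of class `synthetic_trial` with elements `dogs`, `traces`,
#'   `cbarq`, `surveys`, `ground_truth`, `config`.
#' @export
#' @examples
#' cfg <- trial_config(seed = 1, n_treatment = 2, n_placebo = 1)
#' trial <- simulate_trial(cfg)
#' names(trial)
simulate_trial <- function(config, traces = TRUE) {
  stopifnot(inherits(config, "trial_config"))
  dogs <- simulate_dogs(config)
  bank <- cbarq_item_bank()
  trace_tbl <- NULL
  if (traces) {
    trace_tbl <- purrr::map2_dfr(dogs$dog_index, dogs$arm,
                                 ~ simulate_trace(.x, .y, config))
  }
  cbarq <- purrr::map2_dfr(dogs$dog_index, dogs$arm,
                           ~ simulate_cbarq(.x, .y, config, bank = bank))
  surveys <- purrr::map2_dfr(dogs$dog_index, dogs$arm,
                             ~ simulate_surveys(.x, .y, config))
  truth_sleep <- purrr::map2_dfr(dogs$dog_index, dogs$arm, function(i, arm) {
    p <- .dog_day_params(i, arm, config)
    tibble::tibble(dog_id = sprintf("dog_%03d", i), arm = arm,
                   study_day = p$study_day,
                   true_onset = p$onset, true_wake = p$wake,
                   true_total = p$total)
  })
  dog_latent <- purrr::map2_dfr(dogs$dog_index, dogs$arm, function(i, arm) {
    p <- .dog_day_params(i, arm, config)
    tibble::tibble(dog_id = sprintf("dog_%03d", i), arm = arm,
                   daily_mean = p$mu, onset_mean = p$onset_mu,
                   wake_mean = p$wake_mu)
  })
  structure(list(
    dogs = dogs,
    traces = trace_tbl,
    cbarq = cbarq,
    surveys = surveys,
    ground_truth = list(
      effects = list(
        treatment_activity_slope = config$treatment_activity_slope,
        placebo_activity_slope = config$placebo_activity_slope,
        interaction_slope = config$treatment_activity_slope -
          config$placebo_activity_slope,
        settling_pct_treatment = config$settling_pct_treatment,
        settling_pct_placebo = config$settling_pct_placebo,
        daytime_sleep_delta_treatment = config$daytime_sleep_delta_treatment,
        daytime_sleep_delta_placebo = config$daytime_sleep_delta_placebo,
        onset_drift_treatment = config$onset_drift_treatment,
        onset_drift_placebo = config$onset_drift_placebo,
        cbarq_effects = config$cbarq_effects
      ),
      dog_latent = dog_latent,
      true_sleep = truth_sleep
    ),
    config = config
  ), class = "synthetic_trial")
}

#' @export
print.synthetic_trial <- function(x, ...) {
  cat("<synthetic_trial>\n")
  cat(sprintf("  %d dogs (%d treatment / %d placebo), %d study days\n",
              nrow(x$dogs), sum(x$dogs$arm == "treatment"),
              sum(x$dogs$arm == "placebo"),
              x$config$baseline_days + x$config$supplement_days))
  cat(sprintf("  traces: %s; cbarq rows: %d; survey rows: %d\n",
              if (is.null(x$traces)) "not generated"
              else format(nrow(x$traces), big.mark = ","),
              nrow(x$cbarq), nrow(x$surveys)))
  invisible(x)
}
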