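---
title: "Methods: synthetic canine behavior trials and their analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic canine behavior trials and their analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`actibarq` implements the full analysis of a decentralized, randomized,
placebo-controlled canine probiotic behavior trial that pairs two data
streams: minute-resolution collar actigraphy and the C-BARQ owner
questionnaire, plus participant metadata and weekly adverse-event surveys.
Because raw data of such trials are typically not released, the package is
built around a synthetic-trial generator whose injected effects are
recorded as ground truth, so every estimator in the pipeline can be
validated by parameter recovery rather than by fixture files.

# The study design being modeled

Forty home-based dogs are randomized 28:12 to a daily probiotic supplement
or a maltodextrin placebo. A 7-day baseline precedes 28 supplementation
days (study days 0–34; the supplement phase is days 7–34). The C-BARQ is
administered at day 0 and day 35; activity is recorded continuously at
1-minute resolution; adverse-event surveys are scheduled at days 7, 14,
21, 28 and 35. Dosing is one capsule per 25 lbs of body weight, rounded
up, with a one-capsule minimum.

# C-BARQ scoring

Each of the 100 items carries five ordered response labels plus
"NA/Never Observed". Scoring assigns 5 to the most positive label (e.g.
"No aggression") down to 1 for the most negative ("Serious aggression").
Not-observed responses are stored as 0 in raw exports — the field's
convention — but converted to an explicit missing marker at load, so a 0
can never deflate a domain mean. Domain composites are per-dog means of
the non-missing item scores; a dog with no usable item in a domain is
flagged as undefined rather than scored 0.

The *General Anxiety* composite pools the Fear & Anxiety and Separation
Anxiety items at the item level. Pooling (rather than averaging the two
domain means) weights each answered item equally, which mitigates the
sparsity caused by item-specific "NA/Never Observed" answers; the
composite always lies between the two contributing domain means. Item
wording of the published instrument is licensed, so the bank shipped here
is structurally faithful (item counts per domain, 5-point labels, the NA
option) without reproducing the text; all scoring logic is unaffected.

Item-level change analysis ranks items by the absolute mean signed change
between day 0 and day 35 among dogs answering at both timepoints, with
lexicographic tie-breaks for determinism. Signed changes in either
direction count toward "largest change", since both arms' largest shifts
can point in mixed directions.

# Actigraphy features

All activity endpoints exclude weekends: owner presence systematically
inflates weekend activity, and the generator reproduces this with a
weekend multiplier (default 1.3) so the filter is consequential in tests.

* **Daily totals** — per-day minute sums; absent days stay absent rather
  than becoming zeros.
* **Daytime composition** — each minute of 06:00–22:00 is classified as
  sleep (strictly below the light threshold), low, moderate or high
  activity. The device vendor's own thresholds are proprietary, so the
  cut points are configurable (defaults 5 / 20 / 60 units/min). Phase
  composition is the mean of daily compositions; deltas are supplement
  minus baseline in percentage points.
* **Sleep onset** — the earliest minute at or after 19:00 beginning a
  15-minute run entirely below the light threshold. **Wake** mirrors it:
  the earliest minute at or after 05:00 beginning a 15-minute run at or
  above the threshold. Boundary conventions are strict "below" and
  non-strict "at or above"; a missing minute disqualifies a candidate
  window (gaps never fabricate sleep); the onset search does not cross
  midnight, and a night without a qualifying window yields an absent
  event rather than an error.
* **Drift** — pooled least-squares regression of detected event times on
  study day within each arm (baseline days excluded by default), in
  minutes/day; variability is the SD of event times. Pooling across dogs
  was chosen over averaging per-dog slopes; with a common drift and
  balanced detection both are consistent, and pooling is stabler at 12
  dogs per arm. The implementation refuses arms with fewer than a
  configurable minimum of events.
* **Morning activity** — per-dog mean 06:00–08:00 activity per phase,
  compared baseline vs supplement with the paired signed-rank path.
* **Settling index** — within 08:00–10:00 after the 08:00 average
  caregiver departure, `100 × (mean(60–120 min) − mean(0–59 min)) /
  mean(0–59 min)` per day, averaged over each phase's weekdays. More
  negative means faster settling. Days with a zero first-hour mean are
  flagged and excluded, never divided through. The index is invariant to
  rescaling activity by any positive constant.

# The synthetic-trial generator

The generator is the package's test bed: it produces all four data
streams with the statistical structure the analysis assumes, and records
every injected effect. Its central design rule is that **each configured
effect is the exact expectation of the downstream estimator that measures
it**, so recovery tests are unbiased by construction and tolerance
reflects only Monte-Carlo noise:

* *Day targets.* Each dog draws a mean daily total (default 5900 units,
  between-dog SD 1225, matching the reported weekday calibration of
  roughly 5900 ± 1200); days add the arm's linear trend from the first
  supplement day (defaults −27.59 and +18.87 units/day; an explicit
  day×group interaction can override the treatment slope), day-to-day
  noise (SD 400), and the weekend multiplier.
* *Day profile.* Minutes are laid out as: a quiet night (uniform floor
  below the light threshold) between sleep onset (mean 22:30) and wake
  (mean 05:40); a forced-active 15-minute post-wake ramp; nap-interspersed
  daytime; an elevated post-departure hour followed by the settling hour;
  an evening with "sentinel" active minutes every 10 minutes anchored at
  onset − 1; and a quiet late-evening wind-down. The per-day profile is
  scaled so its expected minute sum equals the day's target total (the
  scale is floored, so dog-days far below the structural floor slightly
  overshoot; the day-level generator used for trend recovery is exact).
* *Exact settling.* Hour 2 of the post-departure window is generated
  conditional on the realized hour-1 mean with mean-one multiplicative
  noise, so the per-day settling index has expectation exactly the
  configured arm percentage (−17.8 treatment, −3.2 placebo during
  supplementation; 0 at baseline).
* *Exact sleep deltas.* Every non-quiescent daytime minute is generated
  at or above the light threshold, so the daytime sleep fraction equals
  the nap probability exactly; that probability shifts between phases by
  the configured delta (−3.6 pp treatment, −0.9 pp placebo) rescaled to
  the nap-eligible share of the 06:00–22:00 window. The baseline daytime
  sleep fraction defaults to 55%, a realistic level for home-alone
  companion dogs.
* *Exact detection.* Onset and wake means sit outside the composition
  window, the post-wake ramp guarantees a 15-minute active run at wake,
  and the onset-anchored evening sentinels guarantee that no qualifying
  quiet window precedes the true onset — so detected events equal the
  latent ones up to the brief Poisson arousal bursts (mean 2/night, 1–3
  minutes) that deliberately keep detection non-trivial.
* *Sleep timing.* Onset/wake times drift linearly from the first
  supplement day (placebo defaults −1.5 min/day onset, +1.0 min/day
  wake; treatment 0) with arm-specific night-to-night SDs (12 vs 22
  minutes), reproducing the reported pattern of tighter, stabler sleep
  under treatment. Because the placebo drifts cross the 06:00 and 22:00
  window edges late in the study, the placebo sleep delta is mildly
  contaminated by boundary minutes; the treatment arm (zero drift) is
  exact, and only the treatment delta is used as a recovery target.
* *C-BARQ.* A latent-propensity model: each dog has a normal latent trait
  per domain (SD 0.5) shared across timepoints; items add N(0, 0.7)
  noise and are cut at fixed points (−1.5, −0.5, 0.5, 1.5) into the five
  labels. Treatment dogs receive configured latent shifts at day 35.
  `cbarq_effect_for_gap()` inverts the model analytically so effects can
  be specified on the observable 1–5 score scale (e.g. a +0.48
  aggression gap). Items are independently replaced by "NA/Never
  Observed" with probability 0.08 — missing completely at random, so
  domain means stay unbiased.
* *Surveys.* Each scheduled survey is returned with probability 0.73
  (matching the reported 73% completion), with arm-specific Bernoulli
  emesis/diarrhea flags and a 1–7 stool score.
* *Reproducibility.* Every dog draws from its own substream of the root
  seed, separately for traces, questionnaires and surveys; identical
  configurations are bit-identical, and adding a dog never perturbs the
  others. A `minute_noise = FALSE` mode replaces minute-level randomness
  by its expectation, giving exactly equal weekday totals under
  zero-noise configurations — useful for bookkeeping tests.

What the generator does **not** emulate: weather and season, owner
schedule variability (departure is fixed at 08:00, configurable), device
non-wear and transmission gaps (the analysis handles gaps; the generator
does not produce them by default), breed- or age-dependent activity
structure, and any physiological mechanism linking the supplement to
behavior — effects are injected phenomenologically. Passing recovery
tests therefore demonstrates that the estimators are faithful to their
definitions under the assumed data structure, not that the pipeline is
robust to every artifact of real collar data.

# Endpoint statistics

`compare_groups()` encodes the trial's test-selection rule: Shapiro–Wilk
normality on each sample (on paired differences when paired) at a 0.05
gate, plus Levene's test across unpaired samples. When normality holds, a
t-test is used — Welch by default regardless of the Levene outcome, since
unequal variances cost little when variances happen to be equal; the
Levene p-value is still recorded in the gate evidence. Any normality
failure falls back to the rank-sum (unpaired) or signed-rank (paired)
test. All tests are two-sided; effect CIs come from the t interval or the
Hodges–Lehmann interval. For unpaired t results both the Welch and the
classical n1+n2−2 degrees of freedom are reported, since published
captions mix the two conventions. No multiplicity correction is applied,
mirroring the trial's analysis; the report states how many endpoints were
tested.

The daily-activity model is `total ~ day * arm + (1 | dog_id)` fitted by
REML (lme4) on supplement-phase weekday totals. The generator applies
arm trends from the first supplement day onward, so the supplement phase
is exactly the window where the model's linearity assumption holds;
fitting across the baseline hinge would attenuate the slope toward zero.
The day×group interaction is the headline contrast, with Wald CIs. A
singular random-intercept fit warns but returns; non-convergence is an
error carrying the optimizer message. `group_trend()` gives the
simple-regression view: OLS of arm-mean weekday totals on study day.

`power_two_sample_t()` computes a priori power of the two-sided
independent t-test from the noncentral t distribution (ncp
`d/sqrt(1/n1+1/n2)`, df `n1+n2−2`). It is validated against a vectorized
Monte-Carlo oracle (100 000 replicates per grid cell) to ±0.01. At the
trial's 28/12 split and d = 0.7 it reports ≈ 0.50 — the value the
computation supports, which the test suite asserts against its own
oracle rather than any external figure.

Adverse events use Fisher's exact test on the pooled 2×2 arm-by-event
table of returned surveys, with per-timepoint breakdowns. Scheduled doses
are counted as dog-days (40 × 28 = 1120); capsule totals are reported
alongside.

# Numerical choices and degenerate inputs

* Assumption gates skip Shapiro–Wilk on zero-variance samples; two
  zero-variance identical samples short-circuit to a degenerate null
  result with a warning.
* Zero first-hour means in the settling window, empty composition
  windows, all-weekend traces, and domains with no usable items are all
  flagged explicitly rather than silently coerced to 0.
* Item-ranking ties break lexicographically; event-time regressions
  refuse arms below a minimum event count (default 10).
* Times are local clock minutes; no daylight-saving correction is
  applied (a 35-day window can cross a change; the fixed UTC-like
  timeline of the generator never does).

# Problem sizes used in validation

The recovery studies run at the trial's own design sizes: settling
recovery uses 500 replicate trials of 28/12 dogs; the daytime-sleep
delta uses 200 simulated treatment dogs; mixed-model and trend recovery
use 200 replicates of day-level cohorts; C-BARQ gap recovery uses 500
replicate trials; the detector is checked against a brute-force window
scan on 1000 random traces; the assumption gate's type-I error uses
10 000 null replicates; and the power computation is checked on a
12-cell grid at 100 000 Monte-Carlo replicates per cell.

# Known limitations

* The generator's day profile is piecewise-stationary; real dogs show
  richer autocorrelation and bout structure within segments.
* The placebo-arm daytime-sleep delta is slightly biased by sleep-window
  boundary crossing under drift (see above); treatment-arm recovery is
  exact.
* Very low-activity dog-days (several SDs below the mean) are floored by
  the minute-profile budget; their trace totals overshoot the target,
  which mildly attenuates trace-derived (not day-level) trends.
* The ordinal model uses fixed, equidistant cut points; real C-BARQ items
  differ in difficulty and discrimination.
* The mixed model assumes a common residual variance across arms and
  days.
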