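# actibarq

Analysis toolkit for decentralized, randomized, placebo-controlled canine
behavior trials that combine two measurement streams: minute-resolution
collar actigraphy (FitBark-style activity counts) and the C-BARQ owner
questionnaire, alongside enrollment metadata and weekly adverse-event
surveys. It is written for biostatisticians and veterinary-behavior
researchers who need the full path from raw trial streams to endpoint
statistics — and, because such trial data are rarely released, it ships a
synthetic-trial generator with recorded ground truth so every estimator
can be validated by parameter recovery.

## What it computes

**Questionnaire side.** Ordinal C-BARQ scoring (most positive label = 5,
"NA/Never Observed" excluded as explicit missing), per-dog domain
composites for the seven behavioral domains, a pooled *General Anxiety*
composite (Fear & Anxiety ∪ Separation Anxiety items), and item-level
change rankings between day 0 and day 35.

**Sensor side.** Weekday filtering, daily activity totals, daytime
(06:00–22:00) activity composition against configurable thresholds,
sleep-onset detection (first 15-minute run below the light threshold
after 19:00), wake detection (first 15-minute run at/above threshold
after 05:00), onset/wake drift regressions (min/day), morning
(06:00–08:00) activity, and the post-departure settling index

```
settling = 100 × (mean activity 60–120 min − mean activity 0–59 min) / mean activity 0–59 min
```

over the 08:00–10:00 window after caregiver departure.

**Inference.** Assumption-gated comparisons (Shapiro–Wilk + Levene gate;
Welch t when normality holds, Wilcoxon rank-sum / signed-rank otherwise),
the random-intercept mixed model for daily activity

```
total_ij = β0 + β1·day_j + β2·treatment_i + β3·(day_j × treatment_i) + b_i + ε_ij,  b_i ~ N(0, σ²_dog)
```

whose day×group coefficient β3 (units/day) is the headline contrast,
per-arm OLS activity trends, noncentral-t a priori power for the
two-sample t-test, Fisher-exact adverse-event comparisons, and cohort /
dosing summaries (one capsule per 25 lbs, minimum one).

## Worked example

Simulate a full trial at the design's default conditions (28 treatment /
12 placebo dogs, 7 baseline + 28 supplement days) with a +0.48-point
aggression effect injected on the score scale, then run the whole
pipeline:

```r
library(actibarq)

cfg <- trial_config(
  seed = 20250804,
  cbarq_effects = c(Aggression = cbarq_effect_for_gap(0.48, trial_config(seed = 1)))
)
trial  <- simulate_trial(cfg)
report <- run_trial_analysis(trial)
report
#> <trial_report>
#>   cohort: 40 dogs; 1120 scheduled doses
#>   surveys: 151/200 collected (75.5%); emesis 7.9%, diarrhea 18.5%
#>   day x group interaction: -43.13 u/day [-51.62, -34.64]
#>   16 C-BARQ endpoints, 4 activity endpoints computed
```

The day-35 between-arm aggression endpoint recovers the injected effect
(0.48 was injected; 0.40 [0.16, 0.64] estimated in this single
realization), chosen by the gate as a Welch t-test:

```r
tidy_row <- report$cbarq_endpoints[
  report$cbarq_endpoints$endpoint == "Aggression (day35, between-arm)", ]
tidy_row[, c("test", "estimate", "conf_low", "conf_high", "p_value")]
#>   test    estimate conf_low conf_high p_value
#> 1 Welch t     0.400    0.163     0.637 0.00186
```

The settling index recovers the generator's arm parameters (−17.8% /
−3.2%), and the per-arm weekday trends sit near the configured
−27.59 / +18.87 units/day:

```r
dplyr::summarise(dplyr::group_by(
  subset(report$settling, phase == "supplement"), arm),
  mean_settling = mean(settling_pct))
#>   arm       mean_settling
#> 1 placebo           -2.99
#> 2 treatment        -17.9

report$trends
#>   arm        slope std_error  p_value n_days
#> 1 placebo    15.3      4.87   5.67e-3     20
#> 2 treatment -27.8      2.56   2.40e-9     20
```

More negative settling means calmer dogs after the owner leaves; the
interaction of −43 units/day in this realization says treatment dogs
shed daily activity relative to placebo over the supplement phase (the
truth for this configuration is −27.59 − 18.87 = −46.5).

Plot helpers (`plot_daily_activity()`, `plot_composition_deltas()`,
`plot_drift()`, `plot_settling()`) give ggplot2 views of each result
table, and `tidy()` / `glance()` methods cover the fitted objects.

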