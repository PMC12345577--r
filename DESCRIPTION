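Package: actibarq
Title: Actigraphy and C-BARQ Analysis for Decentralized Canine Behavior Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for analyzing decentralized, placebo-controlled canine
    behavior trials that pair minute-resolution collar actigraphy with the
    C-BARQ owner questionnaire. Provides ordinal C-BARQ scoring and domain
    composites (including a pooled General Anxiety measure), wearable
    feature extraction (weekday filtering, daily totals, daytime activity
    composition, sleep onset and wake detection, onset and wake drift,
    morning activity, and a post-departure settling index),
    assumption-gated endpoint statistics, a random-intercept mixed model
    for daily activity, an a priori power calculation, and a fully
    parameterized synthetic-trial generator with recorded ground truth so
    every estimator can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    dplyr,
    generics,
    ggplot2,
    lme4,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
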