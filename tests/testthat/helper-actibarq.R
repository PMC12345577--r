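# Shared fixtures and independent oracles for the test suite.

# A small, fast configuration for unit tests.
tiny_config <- function(seed = 123, ...) {
  trial_config(n_treatment = 2, n_placebo = 2, seed = seed, ...)
}

# Build a minute-trace tibble by hand from a per-day activity function.
# days: 0-based study days; f(minute_of_day, day) -> activity.
make_trace <- function(days, f, dog_id = "d1", start_date = as.Date("2024-01-01")) {
  rows <- lapply(days, function(d) {
    tod <- 0:1439
    tibble::tibble(
      dog_id = dog_id,
      study_day = d,
      date = start_date + d,
      minute_of_day = tod,
      phase = if (d < 7) "baseline" else "supplement",
      activity = f(tod, d)
    )
  })
  dplyr::bind_rows(rows)
}

# Brute-force window-scan oracle for onset/wake detection: O(n * w) check of
# every candidate window, independent of the rle-based implementation.
brute_first_window <- function(x, from, width, pred) {
  for (t in from:(length(x) - width)) {
    w <- x[(t + 1):(t + width)]
    if (!any(is.na(w)) && all(pred(w))) return(as.integer(t))
  }
  NA_integer_
}

brute_onset <- function(x, thr = 5, from = 1140L, width = 15L) {
  brute_first_window(x, from, width, function(w) w < thr)
}

brute_wake <- function(x, thr = 5, from = 300L, width = 15L) {
  brute_first_window(x, from, width, function(w) w >= thr)
}
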