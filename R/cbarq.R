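# C-BARQ scoring: ordinal labels -> 1..5 scores, domain composites, the
# pooled General Anxiety measure, and item-level change rankings.

#' Score a single C-BARQ response label
#'
#' Positive traits get higher values: the most positive label of an item
#' scores 5 ("No aggression" = 5) and the most negative scores 1 ("Serious
#' aggression" = 1), strictly monotone in between. The "NA/Never Observed"
#' label returns `NA` and is excluded from every downstream statistic (raw
#' exports encode it as 0; see [read_cbarq_scores()]).
#'
#' @param label Response label.
#' @param item An `item_id` present in `bank`.
#' @param bank Item bank from [cbarq_item_bank()].
#' @return Integer 1-5, or `NA_integer_` for the not-observed label.
#' @export
#' @examples
#' bank <- cbarq_item_bank()
#' score_item("No aggression", "agg_01", bank)      # 5
#' score_item("Serious aggression", "agg_01", bank) # 1
score_item <- function(label, item, bank = cbarq_item_bank()) {
  row <- match(item, bank$item_id)
  if (is.na(row)) {
    rlang::abort(sprintf("Unknown C-BARQ item `%s`", item),
                 class = "actibarq_cbarq_error")
  }
  if (label == cbarq_na_label()) return(NA_integer_)
  s <- match(label, bank$labels[[row]])
  if (is.na(s)) {
    rlang::abort(
      sprintf("Unknown label `%s` for item `%s`", label, item),
      class = "actibarq_cbarq_error"
    )
  }
  as.integer(s)
}

#' Score a table of C-BARQ responses
#'
#' Vectorized scoring of a response table (as produced by
#' [simulate_cbarq()] or read from the questionnaire CSV dialect). Adds an
#' integer `score` column (1-5, `NA` for not-observed responses).
#'
#' @param responses Tibble with at least `item_id` and `label`.
#' @param bank Item bank from [cbarq_item_bank()].
#' @return `responses` with `domain` (from the bank) and `score` columns.
#' @export
score_cbarq <- function(responses, bank = cbarq_item_bank()) {
  stopifnot(all(c("item_id", "label") %in% names(responses)))
  row <- match(responses$item_id, bank$item_id)
  if (anyNA(row)) {
    rlang::abort(sprintf("Unknown C-BARQ item `%s`",
                         responses$item_id[which(is.na(row))[1]]),
                 class = "actibarq_cbarq_error")
  }
  score <- integer(nrow(responses))
  for (i in seq_along(score)) {
    lab <- responses$label[[i]]
    if (lab == cbarq_na_label()) {
      score[i] <- NA_integer_
    } else {
      s <- match(lab, bank$labels[[row[i]]])
      if (is.na(s)) {
        rlang::abort(
          sprintf("Unknown label `%s` for item `%s`", lab, responses$item_id[i]),
          class = "actibarq_cbarq_error"
        )
      }
      score[i] <- s
    }
  }
  out <- responses
  out$domain <- bank$domain[row]
  out$score <- score
  out
}

#' Per-dog domain scores
#'
#' Mean of the non-missing item scores within each behavioral domain, per
#' dog and timepoint — the domain composite compared between arms. Dogs with
#' no usable item in a domain get `NA` with `n_items_used = 0` (flagged,
#' never silently zero).
#'
#' @param scored Output of [score_cbarq()] (needs `dog_id`, `timepoint`,
#'   `domain`, `score`; `arm` carried through when present).
#' @return Tibble: `dog_id` (, `arm`), `timepoint`, `domain`, `score`,
#'   `n_items_used`.
#' @export
#' @examples
#' cfg <- trial_config(seed = 1)
#' resp <- simulate_cbarq(1, "treatment", cfg)
#' domain_scores(score_cbarq(resp))
domain_scores <- function(scored) {
  stopifnot(all(c("dog_id", "timepoint", "domain", "score") %in% names(scored)))
  grp <- intersect(c("dog_id", "arm", "timepoint", "domain"), names(scored))
  scored |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(
      n_items_used = sum(!is.na(.data$score)),
      score = dplyr::if_else(n_items_used > 0,
                             mean(.data$score, na.rm = TRUE), NA_real_),
      .groups = "drop"
    ) |>
    dplyr::relocate("score", .before = "n_items_used")
}

#' Pooled General Anxiety composite
#'
#' Pools the Fear & Anxiety and Separation Anxiety item scores at the item
#' level (not a mean of the two domain means) into a single per-dog
#' composite, mitigating item-specific "NA/Never Observed" sparsity.
#'
#' @inheritParams domain_scores
#' @return Tibble like [domain_scores()] with `domain = "General Anxiety"`.
#' @export
general_anxiety_scores <- function(scored) {
  pooled <- scored |>
    dplyr::filter(.data$domain %in% c("Fear & Anxiety", "Separation Anxiety")) |>
    dplyr::mutate(domain = "General Anxiety")
  domain_scores(pooled)
}

#' Rank items by mean paired change
#'
#' For one arm, computes each item's mean signed day-35-minus-day-0 score
#' change over the dogs with a non-missing response at both timepoints, and
#' ranks items by absolute mean change (ties broken by `item_id` for
#' determinism). Items with no paired dog are omitted (and reported in the
#' `dropped_items` attribute).
#'
#' @param scored Output of [score_cbarq()] covering both timepoints.
#' @param arm Optional arm filter (requires an `arm` column).
#' @param top_n Optionally keep only the first `top_n` ranked items.
#' @return Tibble: `rank`, `item_id`, `domain`, `mean_change`, `n_pairs`.
#' @export
#' @examples
#' cfg <- trial_config(seed = 1, n_treatment = 4, n_placebo = 2)
#' trial <- simulate_trial(cfg, traces = FALSE)
#' scored <- score_cbarq(trial$cbarq)
#' head(rank_item_changes(scored, arm = "treatment"), 3)
rank_item_changes <- function(scored, arm = NULL, top_n = NULL) {
  stopifnot(all(c("dog_id", "timepoint", "item_id", "score") %in% names(scored)))
  if (!is.null(arm)) {
    stopifnot("arm" %in% names(scored))
    scored <- scored[scored$arm == arm, ]
  }
  wide <- scored |>
    dplyr::select("dog_id", "item_id", "domain", "timepoint", "score") |>
    tidyr::pivot_wider(names_from = "timepoint", values_from = "score")
  if (!all(c("day0", "day35") %in% names(wide))) {
    rlang::abort("Need responses at both day0 and day35 to rank item changes",
                 class = "actibarq_cbarq_error")
  }
  per_item <- wide |>
    dplyr::filter(!is.na(.data$day0) & !is.na(.data$day35)) |>
    dplyr::group_by(.data$item_id, .data$domain) |>
    dplyr::summarise(mean_change = mean(.data$day35 - .data$day0),
                     n_pairs = dplyr::n(), .groups = "drop")
  dropped <- setdiff(unique(scored$item_id), per_item$item_id)
  out <- per_item |>
    dplyr::arrange(dplyr::desc(abs(.data$mean_change)), .data$item_id) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::relocate("rank")
  if (!is.null(top_n)) out <- dplyr::slice_head(out, n = top_n)
  attr(out, "dropped_items") <- dropped
  out
}

#' Write / read per-dog C-BARQ score tables in the raw-export convention
#'
#' Raw questionnaire exports store "NA/Never Observed" responses as a score
#' of 0. `write_cbarq_scores()` follows that convention on disk;
#' `read_cbarq_scores()` converts 0 back into an explicit `NA` at load, so
#' the 0 can never contaminate a domain mean.
#'
#' @param scored Output of [score_cbarq()].
#' @param path CSV path.
#' @return `read_cbarq_scores()` returns the scored tibble with `NA`
#'   markers; `write_cbarq_scores()` returns `path` invisibly.
#' @export
write_cbarq_scores <- function(scored, path) {
  out <- scored
  out$score <- ifelse(is.na(out$score), 0L, out$score)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cbarq_scores
#' @export
read_cbarq_scores <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  raw$score <- ifelse(raw$score == 0, NA_integer_, as.integer(raw$score))
  tibble::as_tibble(raw)
}
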