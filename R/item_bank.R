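#' C-BARQ domain names
#'
#' The seven behavioral domains of the questionnaire, in canonical order.
#' @return Character vector of length 7.
#' @export
cbarq_domains <- function() {
  c("Training & Obedience", "Aggression", "Fear & Anxiety",
    "Separation Anxiety", "Excitability", "Attention-Seeking",
    "Miscellaneous")
}

# Ordered response labels per domain, most negative trait first. The
# published questionnaire's item wording is licensed, so the bank is
# structurally faithful (item counts, 5-point ordinal labels plus a
# never-observed option) rather than verbatim.
domain_labels <- function(domain) {
  switch(domain,
    "Aggression" = c("Serious aggression", "Aggression", "Moderate aggression",
                     "Mild aggression", "No aggression"),
    "Fear & Anxiety" = ,
    "Separation Anxiety" = c("Extreme fear", "Severe fear", "Moderate fear",
                             "Mild fear", "No fear"),
    "Training & Obedience" = c("Never obeys", "Rarely obeys", "Sometimes obeys",
                               "Usually obeys", "Always obeys"),
    c("Always", "Usually", "Sometimes", "Rarely", "Never")
  )
}

#' The not-observed response label
#'
#' Raw questionnaire exports encode this response as a score of 0; it is
#' converted to an explicit missing marker at load so it can never
#' contaminate a domain mean.
#' @return A string.
#' @export
cbarq_na_label <- function() "NA/Never Observed"

#' Build the C-BARQ item bank
#'
#' A structurally faithful 100-item bank: each item belongs to exactly one
#' of the seven behavioral domains and carries five ordered response labels
#' (most negative trait first) plus the "NA/Never Observed" option. Default
#' per-domain item counts follow the published instrument's structure.
#'
#' @param counts Named integer vector of items per domain; names must be
#'   exactly [cbarq_domains()].
#' @return A tibble with columns `item_id`, `domain`, and `labels`
#'   (list-column of the 5 ordered scored labels).
#' @export
#' @examples
#' bank <- cbarq_item_bank()
#' nrow(bank)
#' table(bank$domain)
cbarq_item_bank <- function(counts = c(
                              "Training & Obedience" = 8,
                              "Aggression" = 27,
                              "Fear & Anxiety" = 18,
                              "Separation Anxiety" = 8,
                              "Excitability" = 6,
                              "Attention-Seeking" = 6,
                              "Miscellaneous" = 27
                            )) {
  if (!setequal(names(counts), cbarq_domains()) ||
      any(counts < 1) || any(counts != floor(counts))) {
    rlang::abort(
      "`counts` must give a positive integer item count for each of the 7 C-BARQ domains",
      class = "actibarq_config_error"
    )
  }
  counts <- counts[cbarq_domains()]
  domain <- rep(names(counts), counts)
  item_id <- sprintf("%s_%02d", abbreviate_domain(domain),
                     unlist(lapply(counts, seq_len), use.names = FALSE))
  tibble::tibble(
    item_id = item_id,
    domain = domain,
    labels = lapply(domain, domain_labels)
  )
}

abbreviate_domain <- function(domain) {
  c("Training & Obedience" = "trn", "Aggression" = "agg",
    "Fear & Anxiety" = "fear", "Separation Anxiety" = "sep",
    "Excitability" = "exc", "Attention-Seeking" = "att",
    "Miscellaneous" = "misc")[domain]
}
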