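# Need estimation: caseload envelopes x need fractions -> people in need.
#
# decedents_in_need(c)    = deaths(c) x decedent_need_fraction(c)
# nondecedents_in_need(c) = prevalent_cases(c) x nondecedent_need_fraction(c)
#
# Fractional persons are retained internally; rounding happens only at the
# reporting boundary. Countries without data are excluded, never imputed.

#' Estimate people in need of palliative care
#'
#' Multiplies each country's cause-specific decedent deaths and non-decedent
#' prevalent cases by the per-condition need fractions.
#'
#' @param scenario a `pc_scenario`.
#' @param countries optional character vector restricting the estimate; by
#'   default all data-available countries. Requesting a country flagged as
#'   having no data raises a classed `pc_no_data_error`.
#' @return tibble of class `pc_need` with columns `country`, `condition`,
#'   `decedents_in_need`, `nondecedents_in_need`.
#' @export
estimate_need <- function(scenario, countries = NULL) {
  cn <- scenario$countries
  if (is.null(countries)) {
    countries <- cn$country[cn$data_available]
  } else {
    unknown <- setdiff(countries, cn$country)
    if (length(unknown) > 0) {
      pc_validation_error(sprintf("unknown country: %s",
                                  paste(unknown, collapse = ", ")))
    }
    nodata <- intersect(countries, cn$country[!cn$data_available])
    if (length(nodata) > 0) {
      pc_no_data_error(sprintf("no data available for: %s",
                               paste(nodata, collapse = ", ")))
    }
  }

  need <- scenario$caseload %>%
    filter(.data$country %in% countries) %>%
    inner_join(
      scenario$conditions %>%
        select("code", "decedent_need_fraction", "nondecedent_need_fraction"),
      by = c("condition" = "code")
    ) %>%
    mutate(
      decedents_in_need = .data$decedent_deaths * .data$decedent_need_fraction,
      nondecedents_in_need =
        .data$nondecedent_cases * .data$nondecedent_need_fraction
    ) %>%
    select("country", "condition", "decedents_in_need",
           "nondecedents_in_need")
  class(need) <- c("pc_need", class(need))
  need
}

#' Per-country need totals
#'
#' @param need a `pc_need` tibble from [estimate_need()].
#' @return tibble with `country`, `decedent_total`, `nondecedent_total`,
#'   `grand_total` (persons, unrounded).
#' @export
need_totals <- function(need) {
  need %>%
    group_by(.data$country) %>%
    summarise(
      decedent_total = sum(.data$decedents_in_need),
      nondecedent_total = sum(.data$nondecedents_in_need),
      .groups = "drop"
    ) %>%
    mutate(grand_total = .data$decedent_total + .data$nondecedent_total)
}

#' Percentage of need generated by each condition
#'
#' share(c) = 100 x (decedents_in_need(c) + nondecedents_in_need(c)) /
#' grand_total; per-country shares sum to 100.
#'
#' @param need a `pc_need` tibble.
#' @return tibble with `country`, `condition`, `share` (percent). A country
#'   with zero total need raises a classed `pc_zero_need_error`.
#' @export
condition_shares <- function(need) {
  totals <- need_totals(need)
  zero <- totals$country[totals$grand_total <= 0]
  if (length(zero) > 0) {
    pc_zero_need_error(sprintf(
      "zero palliative-care need; shares undefined for: %s",
      paste(zero, collapse = ", ")))
  }
  need %>%
    left_join(totals, by = "country") %>%
    mutate(share = 100 * (.data$decedents_in_need +
                            .data$nondecedents_in_need) / .data$grand_total) %>%
    select("country", "condition", "share")
}

#' Regional aggregate of need estimates
#'
#' Elementwise sum over countries (data-unavailable countries never enter a
#' `pc_need`, so they contribute nothing).
#'
#' @param need a `pc_need` tibble covering one or more countries.
#' @return list with `per_condition` (tibble: `condition`,
#'   `decedents_in_need`, `nondecedents_in_need`) and `totals` (one-row
#'   tibble: `decedent_total`, `nondecedent_total`, `grand_total`).
#' @export
regional_totals <- function(need) {
  if (is.null(need) || nrow(need) == 0) {
    pc_validation_error("cannot aggregate an empty set of need estimates")
  }
  per_condition <- need %>%
    group_by(.data$condition) %>%
    summarise(
      decedents_in_need = sum(.data$decedents_in_need),
      nondecedents_in_need = sum(.data$nondecedents_in_need),
      .groups = "drop"
    )
  totals <- tibble(
    decedent_total = sum(per_condition$decedents_in_need),
    nondecedent_total = sum(per_condition$nondecedents_in_need)
  ) %>%
    mutate(grand_total = .data$decedent_total + .data$nondecedent_total)
  list(per_condition = per_condition, totals = totals)
}
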