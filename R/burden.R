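# Symptom-day burden: upper ("at-most") and lower ("at-least") bounds.
#
# A symptom-day is one day on which one person experiences one
# moderate-or-severe symptom. For N(c,m) people in need with condition c and
# status m (decedent / non-decedent):
#
#   at-most  = sum over all symptoms s of N(c,m) * prevalence(c,s,m) *
#              duration(c,s,m)   -- every symptom's days counted
#   at-least = N(c,m) * prevalence(c,s*,m) * duration(c,s*,m), where s* is
#              the symptom of longest duration for (c,m) -- only the longest
#              symptom counted
#
# The two bounds coincide exactly when each (condition, status) carries at
# most one symptom. The lower bound is prevalence-weighted by default
# (config `at_least_weighting = "prevalence"`); set `"unit"` to assume the
# longest symptom affects everyone in need. Ties on duration break toward the
# higher prevalence, then the lexicographically first symptom label.

need_long <- function(need) {
  need %>%
    pivot_longer(c("decedents_in_need", "nondecedents_in_need"),
                 names_to = "status", values_to = "n") %>%
    mutate(status = ifelse(.data$status == "decedents_in_need",
                           "decedent", "nondecedent"))
}

check_coverage <- function(long, coefficients) {
  needed <- long %>%
    filter(.data$n > 0) %>%
    distinct(.data$condition, .data$status)
  missing <- needed %>%
    anti_join(distinct(coefficients, .data$condition, .data$status),
              by = c("condition", "status"))
  if (nrow(missing) > 0) {
    pc_validation_error(sprintf(
      "no symptom coefficients for needed (condition, status): %s",
      paste(sprintf("(%s, %s)", missing$condition, missing$status),
            collapse = ", ")))
  }
}

#' Upper bound on symptom-days ("at-most")
#'
#' @param need a `pc_need` tibble from [estimate_need()].
#' @param coefficients symptom coefficient table (see
#'   [make_default_coefficients()]).
#' @param require_coverage if `TRUE` (default) a (condition, status) with
#'   people in need but no coefficient rows raises a `pc_validation_error`;
#'   if `FALSE` such combinations contribute zero days.
#' @return list with `totals` (tibble: `country`, `at_most_days`) and
#'   `per_symptom` (tibble: `country`, `symptom`, `days`; the at-most
#'   accounting grouped by symptom).
#' @export
at_most_days <- function(need, coefficients, require_coverage = TRUE) {
  long <- need_long(need)
  if (require_coverage) check_coverage(long, coefficients)
  cells <- long %>%
    inner_join(coefficients, by = c("condition", "status"),
               relationship = "many-to-many") %>%
    mutate(days = .data$n * .data$prevalence * .data$duration_days)
  per_symptom <- cells %>%
    group_by(.data$country, .data$symptom) %>%
    summarise(days = sum(.data$days), .groups = "drop")
  totals <- per_symptom %>%
    group_by(.data$country) %>%
    summarise(at_most_days = sum(.data$days), .groups = "drop")
  # countries whose every cell is zero or uncovered still appear
  all_countries <- distinct(need, .data$country)
  list(
    totals = all_countries %>%
      left_join(totals, by = "country") %>%
      mutate(at_most_days = dplyr::coalesce(.data$at_most_days, 0)),
    per_symptom = per_symptom
  )
}

#' Lower bound on symptom-days ("at-least")
#'
#' Counts, for each (condition, status), only the symptom of longest
#' duration.
#'
#' @inheritParams at_most_days
#' @param weighting `"prevalence"` (default) weights the longest symptom's
#'   days by its prevalence; `"unit"` assumes it affects everyone in need.
#' @return tibble with `country`, `at_least_days`.
#' @export
at_least_days <- function(need, coefficients, weighting = "prevalence",
                          require_coverage = TRUE) {
  if (!weighting %in% c("prevalence", "unit")) {
    pc_validation_error("weighting must be 'prevalence' or 'unit'")
  }
  long <- need_long(need)
  if (require_coverage) check_coverage(long, coefficients)
  longest <- coefficients %>%
    arrange(.data$condition, .data$status, -.data$duration_days,
            -.data$prevalence, .data$symptom) %>%
    group_by(.data$condition, .data$status) %>%
    filter(row_number() == 1) %>%
    ungroup()
  contrib <- long %>%
    inner_join(longest, by = c("condition", "status")) %>%
    mutate(days = if (weighting == "prevalence") {
      .data$n * .data$prevalence * .data$duration_days
    } else {
      .data$n * .data$duration_days
    })
  distinct(need, .data$country) %>%
    left_join(
      contrib %>% group_by(.data$country) %>%
        summarise(at_least_days = sum(.data$days), .groups = "drop"),
      by = "country"
    ) %>%
    mutate(at_least_days = dplyr::coalesce(.data$at_least_days, 0))
}

#' Symptom-day burden bounds per country
#'
#' Convenience wrapper computing both bounds and the per-symptom breakdown.
#'
#' @inheritParams at_least_days
#' @return object of class `pc_burden`: list with `totals` (tibble:
#'   `country`, `at_least_days`, `at_most_days`) and `per_symptom` (tibble:
#'   `country`, `symptom`, `days`).
#' @export
symptom_burden <- function(need, coefficients, weighting = "prevalence",
                           require_coverage = TRUE) {
  upper <- at_most_days(need, coefficients, require_coverage)
  lower <- at_least_days(need, coefficients, weighting, require_coverage)
  structure(
    list(
      totals = lower %>% inner_join(upper$totals, by = "country"),
      per_symptom = upper$per_symptom
    ),
    class = "pc_burden"
  )
}

#' Percentage of symptom-days attributable to each symptom
#'
#' Shares are computed under the at-most accounting; per-country shares sum
#' to 100.
#'
#' @param burden a `pc_burden` from [symptom_burden()].
#' @return tibble with `country`, `symptom`, `share` (percent). A country
#'   with zero at-most days raises a classed `pc_zero_burden_error`.
#' @export
symptom_shares <- function(burden) {
  zero <- burden$totals$country[burden$totals$at_most_days <= 0]
  if (length(zero) > 0) {
    pc_zero_burden_error(sprintf(
      "zero symptom-day burden; shares undefined for: %s",
      paste(zero, collapse = ", ")))
  }
  burden$per_symptom %>%
    left_join(burden$totals, by = "country") %>%
    mutate(share = 100 * .data$days / .data$at_most_days) %>%
    select("country", "symptom", "share")
}
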