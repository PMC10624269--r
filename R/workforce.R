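# Workforce model: patients in need -> encounter-days at five care levels ->
# FTEs for ten staff categories, absolute and per 100,000 population.
#
# inpatient_days(level)  = sum N(c,m) x inpatient_days_per_patient(c,m,level)
# outpatient_visits(...) and home_visits analogous (home visits only at home).
# FTE(cat, level) = staff hours at that level / annual FTE hours.

#' Encounter totals per care level
#'
#' @param need a `pc_need` tibble (typically one country, but any set works;
#'   totals are summed over the countries present).
#' @param coefficients encounter coefficient table (see
#'   [build_encounter_coefficients()]).
#' @return tibble with `country`, `level`, `inpatient_days`,
#'   `outpatient_visits`, `home_visits`. A (condition, status) with people in
#'   need but no coefficient rows raises a `pc_validation_error`.
#' @export
encounter_totals <- function(need, coefficients) {
  long <- need_long(need)
  needed <- long %>% filter(.data$n > 0) %>%
    distinct(.data$condition, .data$status)
  missing <- needed %>%
    anti_join(distinct(coefficients, .data$condition, .data$status),
              by = c("condition", "status"))
  if (nrow(missing) > 0) {
    pc_validation_error(sprintf(
      "no encounter coefficients for needed (condition, status): %s",
      paste(sprintf("(%s, %s)", missing$condition, missing$status),
            collapse = ", ")))
  }
  grid <- crossing(distinct(need, .data$country), level = pc_care_levels())
  long %>%
    inner_join(coefficients, by = c("condition", "status"),
               relationship = "many-to-many") %>%
    mutate(
      inpatient_days = .data$n * .data$inpatient_days_per_patient,
      outpatient_visits = .data$n * .data$outpatient_visits_per_patient,
      home_visits = .data$n * .data$home_visits_per_patient
    ) %>%
    group_by(.data$country, .data$level) %>%
    summarise(across(c("inpatient_days", "outpatient_visits", "home_visits"),
                     sum), .groups = "drop") %>%
    full_join(grid, by = c("country", "level")) %>%
    mutate(across(c("inpatient_days", "outpatient_visits", "home_visits"),
                  ~ dplyr::coalesce(.x, 0))) %>%
    arrange(.data$country, match(.data$level, pc_care_levels()))
}

#' Staff full-time equivalents per category and care level
#'
#' FTE(cat, level) = (inpatient_days(level) x hours_per_inpatient_day +
#' outpatient_visits(level) x hours_per_outpatient_visit + home_visits x
#' hours_per_home_visit) / annual_fte_hours.
#'
#' @param encounters tibble from [encounter_totals()].
#' @param norms staffing norm table (see [default_staffing_norms()]); must
#'   cover every category x level.
#' @return tibble with `country`, `staff_category`, `level`, `fte`.
#' @export
staff_fte <- function(encounters, norms) {
  if (any(norms$annual_fte_hours <= 0)) {
    pc_validation_error("staffing_norms: 'annual_fte_hours' must be > 0")
  }
  missing <- crossing(staff_category = pc_staff_categories(),
                      level = pc_care_levels()) %>%
    anti_join(norms, by = c("staff_category", "level"))
  if (nrow(missing) > 0) {
    pc_validation_error(sprintf(
      "staffing_norms: missing %d category x level row(s), e.g. (%s, %s)",
      nrow(missing), missing$staff_category[1], missing$level[1]))
  }
  encounters %>%
    inner_join(norms, by = "level", relationship = "many-to-many") %>%
    mutate(fte = (.data$inpatient_days * .data$hours_per_inpatient_day +
                    .data$outpatient_visits * .data$hours_per_outpatient_visit +
                    .data$home_visits * .data$hours_per_home_visit) /
             .data$annual_fte_hours) %>%
    select("country", "staff_category", "level", "fte") %>%
    arrange(.data$country, match(.data$staff_category, pc_staff_categories()),
            match(.data$level, pc_care_levels()))
}

#' Staff density per 100,000 population
#'
#' @param total_fte FTE count (any non-negative numeric vector).
#' @param population persons (> 0).
#' @return FTEs per 100,000 population, unrounded (reports round to 2
#'   decimals, half up). Non-positive population raises a
#'   `pc_validation_error`.
#' @export
fte_per_100k <- function(total_fte, population) {
  if (any(is.na(population)) || any(population <= 0)) {
    pc_validation_error("population must be > 0")
  }
  100000 * total_fte / population
}

#' Full workforce estimate for selected countries
#'
#' Chains [estimate_need()], [encounter_totals()], [staff_fte()], and
#' [fte_per_100k()] for each requested country.
#'
#' @param scenario a `pc_scenario`.
#' @param countries countries to model; defaults to all data-available ones.
#' @param need optional precomputed `pc_need`.
#' @return object of class `pc_workforce`: list with
#'   `patients` (country, decedent_total, nondecedent_total, grand_total),
#'   `encounters` (per country and level), `fte_by_level`,
#'   `fte` (country, staff_category, total_fte, fte_per_100k), and
#'   `population` (country, population).
#' @export
workforce_estimate <- function(scenario, countries = NULL,
                               need = estimate_need(scenario, countries)) {
  enc <- encounter_totals(need, scenario$encounter_coefficients)
  by_level <- staff_fte(enc, scenario$staffing_norms)
  pop <- scenario$countries %>%
    semi_join(distinct(need, .data$country), by = "country") %>%
    select("country", "population")
  fte <- by_level %>%
    group_by(.data$country, .data$staff_category) %>%
    summarise(total_fte = sum(.data$fte), .groups = "drop") %>%
    inner_join(pop, by = "country") %>%
    mutate(fte_per_100k = fte_per_100k(.data$total_fte, .data$population)) %>%
    select("country", "staff_category", "total_fte", "fte_per_100k")
  structure(
    list(
      patients = need_totals(need),
      encounters = enc,
      fte_by_level = by_level,
      fte = fte,
      population = pop
    ),
    class = "pc_workforce"
  )
}

#' Range of staff density across countries
#'
#' Minimum and maximum FTEs per 100,000 population for one staff category,
#' rounded to one decimal (half up) as in headline summaries.
#'
#' @param workforce a `pc_workforce`, or a tibble with `staff_category` and
#'   `fte_per_100k` columns.
#' @param category one of [pc_staff_categories()].
#' @return named numeric vector `c(min = ..., max = ...)`.
#' @export
workforce_summary_range <- function(workforce, category) {
  fte <- if (inherits(workforce, "pc_workforce")) workforce$fte else workforce
  vals <- fte$fte_per_100k[fte$staff_category == category]
  if (length(vals) == 0) {
    pc_validation_error(sprintf(
      "no per-100k values for staff category '%s'", category))
  }
  c(min = round_half_up(min(vals), 1), max = round_half_up(max(vals), 1))
}
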