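# Opioid access: distributed-opioid oral morphine equivalents (DOME).
#
# DOME is the quantity of strong opioids other than methadone distributed in
# a country, converted to oral morphine milligrams with an equianalgesic
# table. It serves as a surrogate for palliative-care accessibility: DOME per
# patient in need, and DOME as a percentage of the modelled requirement — the
# quantity needed to adequately treat all patients in need who have moderate
# or severe pain or refractory terminal dyspnea.

#' Convert an opioid supply table to DOME
#'
#' dome = sum of quantity_mg x ome_multiplier over non-methadone records;
#' methadone records are excluded by definition of the measure.
#'
#' @param supply tibble with `country`, `opioid`, `route_class`,
#'   `quantity_mg`.
#' @param table equianalgesic table (see [default_equianalgesic()]).
#' @return tibble with `country`, `dome_mg`. A non-methadone product missing
#'   from the table raises a `pc_validation_error` naming it.
#' @export
to_ome <- function(supply, table) {
  joined <- supply %>%
    left_join(table, by = c("opioid", "route_class"))
  unknown <- joined %>% filter(is.na(.data$ome_multiplier))
  if (nrow(unknown) > 0) {
    pc_validation_error(sprintf(
      "no equianalgesic factor for: %s",
      paste(unique(sprintf("%s (%s)", unknown$opioid, unknown$route_class)),
            collapse = ", ")))
  }
  joined %>%
    mutate(ome = ifelse(.data$is_methadone, 0,
                        .data$quantity_mg * .data$ome_multiplier)) %>%
    group_by(.data$country) %>%
    summarise(dome_mg = sum(.data$ome), .groups = "drop")
}

#' DOME per patient in need
#'
#' @param dome_mg milligrams of oral morphine equivalents (scalar).
#' @param grand_total patients in need (scalar, > 0).
#' @return mg per patient. Zero patients raises a `pc_zero_need_error`.
#' @export
dome_per_patient <- function(dome_mg, grand_total) {
  if (grand_total <= 0) {
    pc_zero_need_error("DOME per patient undefined: no patients in need")
  }
  dome_mg / grand_total
}

#' Modelled opioid requirement in oral morphine equivalents
#'
#' required = sum over (condition, status) of N(c,m) x pain_prev x pain_days
#' x pain_daily_dose plus, for decedents only, N x dyspnea_prev x
#' dyspnea_days x dyspnea_daily_dose. Pain and terminal-dyspnea prevalence and
#' duration are taken from the symptom coefficient rows for `"pain"` and
#' `"dyspnea"`. With `requirement_population = "decedents"` the pain term too
#' is restricted to decedents.
#'
#' @param need a `pc_need` tibble.
#' @param coefficients symptom coefficient table.
#' @param params requirement parameters (see [default_requirement_params()]).
#' @return tibble with `country`, `required_mg`.
#' @export
required_ome <- function(need, coefficients, params) {
  long <- need_long(need)
  pain <- coefficients %>%
    filter(.data$symptom == "pain") %>%
    select("condition", "status", pain_prev = "prevalence",
           pain_days = "duration_days")
  dysp <- coefficients %>%
    filter(.data$symptom == "dyspnea", .data$status == "decedent") %>%
    select("condition", "status", dysp_prev = "prevalence",
           dysp_days = "duration_days")

  if (identical(params$requirement_population, "decedents")) {
    long_pain <- long %>% filter(.data$status == "decedent")
  } else {
    long_pain <- long
  }

  pain_term <- long_pain %>%
    inner_join(pain, by = c("condition", "status")) %>%
    mutate(mg = .data$n * .data$pain_prev * .data$pain_days *
             params$pain_daily_dose_mg)
  dysp_term <- long %>%
    inner_join(dysp, by = c("condition", "status")) %>%
    mutate(mg = .data$n * .data$dysp_prev * .data$dysp_days *
             params$dyspnea_daily_dose_mg)

  distinct(need, .data$country) %>%
    left_join(
      bind_rows(pain_term, dysp_term) %>%
        group_by(.data$country) %>%
        summarise(required_mg = sum(.data$mg), .groups = "drop"),
      by = "country"
    ) %>%
    mutate(required_mg = dplyr::coalesce(.data$required_mg, 0))
}

#' Percentage of modelled opioid need met by DOME
#'
#' @param dome_mg DOME (scalar mg).
#' @param required_mg modelled requirement (scalar mg, > 0).
#' @return percent, uncapped (values above 100 indicate supply exceeding the
#'   modelled palliative requirement). Zero requirement raises a classed
#'   `pc_zero_requirement_error`.
#' @export
percent_need_met <- function(dome_mg, required_mg) {
  if (required_mg <= 0) {
    pc_zero_requirement_error("percent of need met undefined: requirement is zero")
  }
  100 * dome_mg / required_mg
}

#' Country-level opioid access metrics
#'
#' Runs the full DOME accounting for every country in `need`: DOME, DOME per
#' patient in need, modelled requirement, and percent of need met. Countries
#' with zero patients or zero requirement receive `NA` in the affected ratio
#' (the scalar operations [dome_per_patient()] and [percent_need_met()] raise
#' errors instead, for callers that want strictness).
#'
#' @param scenario a `pc_scenario`.
#' @param need a `pc_need` tibble; defaults to [estimate_need()] on the
#'   scenario.
#' @return tibble with `country`, `dome_mg`, `dome_per_patient_mg`,
#'   `required_mg`, `percent_met`.
#' @export
opioid_access <- function(scenario, need = estimate_need(scenario)) {
  dome <- to_ome(scenario$opioid_supply, scenario$equianalgesic)
  totals <- need_totals(need)
  req <- required_ome(need, scenario$symptom_coefficients, scenario$config)
  totals %>%
    left_join(dome, by = "country") %>%
    mutate(dome_mg = dplyr::coalesce(.data$dome_mg, 0)) %>%
    left_join(req, by = "country") %>%
    mutate(
      dome_per_patient_mg = ifelse(.data$grand_total > 0,
                                   .data$dome_mg / .data$grand_total, NA_real_),
      percent_met = ifelse(.data$required_mg > 0,
                           100 * .data$dome_mg / .data$required_mg, NA_real_)
    ) %>%
    select("country", "dome_mg", "dome_per_patient_mg", "required_mg",
           "percent_met")
}
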