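# Default parameter tables for the serious-illness suffering framework.
#
# The framework covers the 20 ICD-10 serious-illness conditions that most
# commonly generate moderate-or-severe physical or psychological suffering,
# 15 symptom types (11 physical, 4 psychological), five care levels, and ten
# staff categories. Cells whose values are reported in the published regional
# analysis are marked source = "reported" (prevalence) and carried exactly;
# every other cell is a documented placeholder ("assumed") that users can
# replace with the full Lancet-Commission-style appendix coefficients.

#' The 20 serious-illness conditions with default palliative-care need fractions
#'
#' @description
#' Returns the condition framework: one row per condition with the default
#' fraction of decedents (people who died of the condition in the reference
#' year) and of non-decedents (people living with the condition that year) in
#' need of palliative care. Need fractions are planning assumptions in
#' `[0, 1]`; several conditions (e.g. poisoning, haemorrhagic fevers) generate
#' need only among decedents.
#'
#' @return tibble with columns `code`, `name`, `decedent_need_fraction`,
#'   `nondecedent_need_fraction`.
#' @export
pc_conditions <- function() {
  tibble::tribble(
    ~code,     ~name,                              ~decedent_need_fraction, ~nondecedent_need_fraction,
    "MAL",     "malignant neoplasms",              0.80, 0.30,
    "HIV",     "HIV/AIDS",                         0.90, 0.40,
    "TB",      "tuberculosis",                     0.75, 0.20,
    "STROKE",  "cerebrovascular disease",          0.60, 0.25,
    "DEM",     "dementia",                         0.90, 0.60,
    "CIHD",    "chronic ischaemic heart disease",  0.50, 0.15,
    "NIHD",    "non-ischaemic heart disease",      0.55, 0.15,
    "LUNG",    "chronic lung disease",             0.70, 0.35,
    "LIVER",   "liver disease",                    0.60, 0.20,
    "RENAL",   "renal failure",                    0.60, 0.25,
    "CNSI",    "inflammatory CNS disease",         0.70, 0.30,
    "CNSD",    "degenerative CNS disease",         0.80, 0.50,
    "INJ",     "injuries",                         0.45, 0.10,
    "POIS",    "poisoning",                        0.40, 0.00,
    "MSK",     "musculoskeletal disorders",        0.35, 0.25,
    "CONG",    "congenital malformations",         0.65, 0.35,
    "PREM",    "prematurity and birth trauma",     0.70, 0.20,
    "HEMF",    "haemorrhagic fevers",              0.80, 0.00,
    "PEM",     "protein-energy malnutrition",      0.60, 0.30,
    "ATH",     "atherosclerosis",                  0.45, 0.10
  )
}

#' The 15 symptom types (11 physical, 4 psychological)
#'
#' @return tibble with columns `symptom`, `class` (`"physical"` or
#'   `"psychological"`).
#' @export
pc_symptoms <- function() {
  tibble(
    symptom = c(
      "pain", "dyspnea", "fatigue", "weakness", "nausea_or_vomiting",
      "diarrhea", "constipation", "dry_mouth", "pruritus", "wounds",
      "anorexia",
      "anxiety_or_worry", "depressed_mood", "confusion_or_delirium",
      "dementia_symptoms"
    ),
    class = c(rep("physical", 11), rep("psychological", 4))
  )
}

# base decedent prevalence / duration per symptom (placeholder defaults);
# non-decedent cells scale these down since the framework gives no
# non-decedent durations
symptom_base_table <- function() {
  tibble::tribble(
    ~symptom,                ~prevalence, ~duration_days,
    "pain",                  0.55, 70,
    "dyspnea",               0.30, 25,
    "fatigue",               0.65, 90,
    "weakness",              0.60, 85,
    "nausea_or_vomiting",    0.30, 20,
    "diarrhea",              0.20, 15,
    "constipation",          0.25, 25,
    "dry_mouth",             0.30, 20,
    "pruritus",              0.10, 15,
    "wounds",                0.10, 30,
    "anorexia",              0.35, 40,
    "anxiety_or_worry",      0.50, 60,
    "depressed_mood",        0.45, 55,
    "confusion_or_delirium", 0.30, 15,
    "dementia_symptoms",     0.05, 30
  )
}

#' Default condition-by-symptom prevalence/duration coefficients
#'
#' @description
#' Builds the full coefficient table: 20 conditions x 15 symptoms x 2 statuses
#' (decedent / non-decedent). Every prevalence reported for the framework is
#' honored exactly:
#'
#' * cancer decedents: moderate-or-severe pain prevalence 0.80 for an average
#'   of 90 days (three months);
#' * decedent dyspnea prevalence: chronic lung disease 1.00, heart disease
#'   0.775 (midpoint of the reported 75--80% range, applied to both ischaemic
#'   and non-ischaemic heart disease), HIV/AIDS 0.70, liver disease 0.50,
#'   prematurity/birth trauma 0.50.
#'
#' All other cells are documented placeholders (`source = "assumed"`);
#' cells mixing a reported prevalence with an assumed duration are marked
#' `"mixed"`. Non-decedent prevalences default to 0.6x and durations to 0.5x
#' the decedent cell, flagged as assumptions.
#'
#' @return tibble with columns `condition`, `symptom`, `status`, `prevalence`,
#'   `duration_days`, `source`.
#' @export
make_default_coefficients <- function() {
  base <- symptom_base_table()
  dec <- crossing(condition = pc_conditions()$code, base) %>%
    mutate(status = "decedent", source = "assumed")

  # reported cells (prevalence exact; durations reported only for cancer pain)
  dec <- dec %>%
    mutate(
      prevalence = case_when(
        condition == "MAL" & symptom == "pain" ~ 0.80,
        condition == "LUNG" & symptom == "dyspnea" ~ 1.00,
        condition %in% c("CIHD", "NIHD") & symptom == "dyspnea" ~ 0.775,
        condition == "HIV" & symptom == "dyspnea" ~ 0.70,
        condition == "LIVER" & symptom == "dyspnea" ~ 0.50,
        condition == "PREM" & symptom == "dyspnea" ~ 0.50,
        TRUE ~ .data$prevalence
      ),
      duration_days = case_when(
        condition == "MAL" & symptom == "pain" ~ 90,
        TRUE ~ .data$duration_days
      ),
      source = case_when(
        condition == "MAL" & symptom == "pain" ~ "reported",
        condition == "LUNG" & symptom == "dyspnea" ~ "mixed",
        condition %in% c("CIHD", "NIHD") & symptom == "dyspnea" ~ "mixed",
        condition == "HIV" & symptom == "dyspnea" ~ "mixed",
        condition == "LIVER" & symptom == "dyspnea" ~ "mixed",
        condition == "PREM" & symptom == "dyspnea" ~ "mixed",
        TRUE ~ "assumed"
      )
    )

  nondec <- dec %>%
    mutate(
      status = "nondecedent",
      prevalence = .data$prevalence * 0.6,
      duration_days = .data$duration_days * 0.5,
      source = "assumed"
    )

  bind_rows(dec, nondec) %>%
    select("condition", "symptom", "status", "prevalence", "duration_days",
           "source") %>%
    arrange(.data$condition, .data$status, .data$symptom)
}

#' Default equianalgesic dosing table
#'
#' Milligrams of oral morphine equivalent to one milligram of each opioid
#' product/route. Methadone rows are flagged and excluded from DOME by
#' [to_ome()] (its long, variable half-life makes simple equianalgesic
#' conversion unreliable, and the DOME access surrogate excludes it by
#' definition). All multipliers are overridable scenario inputs.
#'
#' @return tibble with columns `opioid`, `route_class`, `ome_multiplier`,
#'   `is_methadone`.
#' @export
default_equianalgesic <- function() {
  tibble::tribble(
    ~opioid,         ~route_class,   ~ome_multiplier, ~is_methadone,
    "morphine",      "oral",         1.0,   FALSE,
    "oxycodone",     "oral",         1.5,   FALSE,
    "hydromorphone", "oral",         4.0,   FALSE,
    "morphine",      "parenteral",   3.0,   FALSE,
    "fentanyl",      "transdermal",  100.0, FALSE,
    "methadone",     "oral",         4.0,   TRUE
  )
}

#' Default opioid requirement parameters
#'
#' Daily oral-morphine-equivalent doses used to model the opioid quantity
#' required to adequately treat all patients in need who have moderate or
#' severe pain or refractory terminal dyspnea. Doses are planning assumptions:
#' 67.5 mg/day for pain (midpoint-style basic effective dose) and 10 mg/day
#' for terminal dyspnea. `requirement_population` controls whether pain-days of
#' non-decedents count toward the requirement (`"all"`, the default) or only
#' decedents (`"decedents"`); terminal dyspnea is always decedents-only.
#' `procedural_fraction` is a sensitivity hook for the share of distributed
#' opioid consumed by surgical/procedural use (0 = no correction, the default
#' accounting).
#'
#' @return named list of requirement parameters.
#' @export
default_requirement_params <- function() {
  list(
    pain_daily_dose_mg = 67.5,
    dyspnea_daily_dose_mg = 10,
    requirement_population = "all",
    procedural_fraction = 0
  )
}

#' Default staffing norms
#'
#' Hours of each staff category's time consumed per inpatient day, outpatient
#' visit, and home visit, by care level, plus annual full-time-equivalent
#' hours (default 1650, a standard full-time planning figure). Community
#' health workers work only through home visits; all other categories work
#' through facility encounters. Values are planning defaults chosen to yield
#' staffing densities of the order seen in essential-package palliative care
#' costing: a few doctor FTEs and several nurse and community-health-worker
#' FTEs per 100,000 population, scaling with the share of the population in
#' need.
#'
#' @param annual_fte_hours hours per FTE-year (default 1650).
#' @return tibble with columns `staff_category`, `level`,
#'   `hours_per_inpatient_day`, `hours_per_outpatient_visit`,
#'   `hours_per_home_visit`, `annual_fte_hours`.
#' @export
default_staffing_norms <- function(annual_fte_hours = 1650) {
  per_cat <- tibble::tribble(
    ~staff_category,                ~hours_per_inpatient_day, ~hours_per_outpatient_visit, ~hours_per_home_visit,
    "doctor",                        0.50, 0.30, 0.00,
    "nurse",                         1.20, 0.50, 0.00,
    "social_worker",                 0.30, 0.30, 0.00,
    "spiritual_counsellor",          0.10, 0.03, 0.00,
    "psychologist_or_psychiatrist",  0.06, 0.03, 0.00,
    "physical_therapist",            0.02, 0.01, 0.00,
    "pharmacist",                    0.12, 0.08, 0.00,
    "community_health_worker",       0.00, 0.00, 1.25,
    "clinical_support",              0.010, 0.004, 0.00,
    "nonclinical_support",           0.10, 0.06, 0.00
  )
  crossing(level = pc_care_levels(), per_cat) %>%
    mutate(
      # home visits happen only at the home level; facility hours only at
      # facility levels
      hours_per_inpatient_day =
        ifelse(.data$level == "home", 0, .data$hours_per_inpatient_day),
      hours_per_outpatient_visit =
        ifelse(.data$level == "home", 0, .data$hours_per_outpatient_visit),
      hours_per_home_visit =
        ifelse(.data$level == "home", .data$hours_per_home_visit, 0),
      annual_fte_hours = annual_fte_hours
    ) %>%
    select("staff_category", "level", "hours_per_inpatient_day",
           "hours_per_outpatient_visit", "hours_per_home_visit",
           "annual_fte_hours") %>%
    arrange(match(.data$staff_category, pc_staff_categories()),
            match(.data$level, pc_care_levels()))
}

#' Default allocation of encounters across care levels, by income group
#'
#' The share of a country's inpatient days and outpatient visits delivered at
#' each facility level (referral, provincial, district hospitals and community
#' health centers); home visits occur only at the home level. The profile
#' follows the facility mix of published essential-package workforce
#' estimates: inpatient care concentrated in hospitals with a small community
#' health center share, outpatient care weighted toward district facilities
#' and community health centers. The same profile is used for every income
#' group by default; the table is an explicit, editable scenario input.
#'
#' @return tibble with columns `income_group`, `level`, `inpatient_share`,
#'   `outpatient_share`.
#' @export
default_level_allocation <- function() {
  facility <- tibble::tribble(
    ~level,                    ~inpatient_share, ~outpatient_share,
    "referral_hospital",        0.40, 0.18,
    "provincial_hospital",      0.27, 0.15,
    "district_hospital",        0.32, 0.33,
    "community_health_center",  0.01, 0.34,
    "home",                     0.00, 0.00
  )
  crossing(income_group = pc_income_groups(), facility) %>%
    select("income_group", "level", "inpatient_share", "outpatient_share")
}

# per-status facility/home utilisation per patient in need (planning defaults)
encounter_base_rates <- function() {
  tibble::tribble(
    ~status,       ~inpatient_days_total, ~outpatient_visits_total, ~home_visits_total,
    "decedent",    12, 8, 30,
    "nondecedent",  3, 10, 15
  )
}

#' Build encounter coefficients from base utilisation and a level allocation
#'
#' Expands per-patient totals of inpatient days, outpatient visits, and home
#' visits (by condition and decedent status) into per-level coefficients using
#' a level-allocation profile.
#'
#' @param conditions character vector of condition codes.
#' @param allocation one income group's rows of [default_level_allocation()].
#' @param base_rates per-status utilisation totals; defaults to the package's
#'   planning rates.
#' @return tibble with columns `condition`, `status`, `level`,
#'   `inpatient_days_per_patient`, `outpatient_visits_per_patient`,
#'   `home_visits_per_patient`.
#' @export
build_encounter_coefficients <- function(conditions,
                                         allocation,
                                         base_rates = encounter_base_rates()) {
  stopifnot_columns(allocation, c("level", "inpatient_share",
                                  "outpatient_share"), "level_allocation")
  crossing(condition = conditions, base_rates, allocation) %>%
    mutate(
      inpatient_days_per_patient =
        .data$inpatient_days_total * .data$inpatient_share,
      outpatient_visits_per_patient =
        .data$outpatient_visits_total * .data$outpatient_share,
      home_visits_per_patient =
        ifelse(.data$level == "home", .data$home_visits_total, 0)
    ) %>%
    select("condition", "status", "level", "inpatient_days_per_patient",
           "outpatient_visits_per_patient", "home_visits_per_patient") %>%
    arrange(.data$condition, .data$status,
            match(.data$level, pc_care_levels()))
}

# per-income-group condition weights over deaths (normalised at use);
# low-income mixes weight infectious, neonatal and nutritional causes more
# heavily, high-income mixes weight cancer, dementia and vascular disease
default_condition_weights <- function() {
  codes <- pc_conditions()$code
  w <- list(
    "low" = c(MAL = 10, HIV = 6, TB = 8, STROKE = 7, DEM = 2, CIHD = 7,
              NIHD = 5, LUNG = 4, LIVER = 4, RENAL = 3, CNSI = 3, CNSD = 2,
              INJ = 12, POIS = 2, MSK = 2, CONG = 5, PREM = 9, HEMF = 2,
              PEM = 5, ATH = 2),
    "lower-middle" = c(MAL = 14, HIV = 3, TB = 5, STROKE = 9, DEM = 3,
                       CIHD = 10, NIHD = 6, LUNG = 6, LIVER = 5, RENAL = 4,
                       CNSI = 2, CNSD = 2, INJ = 10, POIS = 2, MSK = 2,
                       CONG = 4, PREM = 6, HEMF = 1, PEM = 3, ATH = 3),
    "upper-middle" = c(MAL = 18, HIV = 2, TB = 3, STROKE = 10, DEM = 5,
                       CIHD = 12, NIHD = 7, LUNG = 7, LIVER = 5, RENAL = 4,
                       CNSI = 2, CNSD = 3, INJ = 8, POIS = 2, MSK = 2,
                       CONG = 3, PREM = 3, HEMF = 1, PEM = 1, ATH = 2),
    "high" = c(MAL = 24, HIV = 1, TB = 1, STROKE = 9, DEM = 9, CIHD = 13,
               NIHD = 8, LUNG = 8, LIVER = 4, RENAL = 4, CNSI = 1, CNSD = 4,
               INJ = 7, POIS = 1, MSK = 2, CONG = 2, PREM = 2, HEMF = 0.5,
               PEM = 0.5, ATH = 3)
  )
  lapply(w, function(v) {
    stopifnot(setequal(names(v), codes))
    v[codes] / sum(v)
  })
}

# prevalent non-fatal cases per death, by condition (planning defaults);
# chronic conditions carry many more prevalent cases than rapidly fatal ones
default_case_death_ratios <- function() {
  c(MAL = 2, HIV = 8, TB = 3, STROKE = 3, DEM = 6, CIHD = 4, NIHD = 3,
    LUNG = 5, LIVER = 3, RENAL = 4, CNSI = 2, CNSD = 5, INJ = 4, POIS = 1,
    MSK = 10, CONG = 6, PREM = 1, HEMF = 0.5, PEM = 4, ATH = 3)
}
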