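# Scenario builders for tests.

# a tiny fully hand-controlled scenario: one country, one condition, chosen
# coefficient rows — for worked single-number checks
hand_scenario <- function(deaths = 1000, cases = 0,
                          dec_frac = 0.8, nondec_frac = 0.3,
                          coef_rows = NULL) {
  conditions <- tibble::tibble(
    code = "MAL", name = "malignant neoplasms",
    decedent_need_fraction = dec_frac,
    nondecedent_need_fraction = nondec_frac)
  countries <- tibble::tibble(
    country = "A", income_group = "low", population = 1e6,
    data_available = TRUE)
  caseload <- tibble::tibble(
    country = "A", condition = "MAL",
    decedent_deaths = deaths, nondecedent_cases = cases)
  if (is.null(coef_rows)) {
    coef_rows <- tibble::tibble(
      condition = "MAL", symptom = c("pain", "dyspnea"),
      status = "decedent", prevalence = c(0.8, 0.5),
      duration_days = c(90, 60), source = "assumed")
  }
  new_scenario(
    reference_year = 2015,
    conditions = conditions, countries = countries, caseload = caseload,
    symptom_coefficients = coef_rows,
    opioid_supply = tibble::tibble(
      country = character(), opioid = character(),
      route_class = character(), quantity_mg = double()),
    equianalgesic = default_equianalgesic(),
    encounter_coefficients = build_encounter_coefficients(
      "MAL",
      dplyr::filter(default_level_allocation(),
                    income_group == "low")[, -1]),
    staffing_norms = default_staffing_norms(),
    level_allocation = default_level_allocation())
}

# a randomised small scenario (<= 5 countries, <= 6 conditions) with random
# coefficients in every table, for oracle-equivalence and property tests
tiny_scenario <- function(seed) {
  set.seed(seed)
  n_co <- sample(2:6, 1)
  n_cy <- sample(2:5, 1)
  conditions <- pc_conditions()[sample(20, n_co), ]
  countries <- tibble::tibble(
    country = sprintf("C%02d", seq_len(n_cy)),
    income_group = sample(pc_income_groups(), n_cy, replace = TRUE),
    population = round(runif(n_cy, 1e5, 2e7)),
    data_available = TRUE)
  caseload <- tidyr::crossing(country = countries$country,
                              condition = conditions$code)
  caseload$decedent_deaths <- round(runif(nrow(caseload), 0, 5e4))
  caseload$nondecedent_cases <- round(runif(nrow(caseload), 0, 2e5))

  symptoms <- unique(c("pain", "dyspnea",
                       sample(pc_symptoms()$symptom, sample(1:4, 1))))
  coefs <- tidyr::crossing(condition = conditions$code, symptom = symptoms,
                           status = c("decedent", "nondecedent"))
  coefs$prevalence <- runif(nrow(coefs))
  coefs$duration_days <- round(runif(nrow(coefs), 0, 120))
  coefs$source <- "assumed"

  eq <- default_equianalgesic()
  supply <- tidyr::crossing(country = countries$country,
                            eq[, c("opioid", "route_class")])
  supply$quantity_mg <- round(runif(nrow(supply), 0, 1e7))

  ecoefs <- tidyr::crossing(condition = conditions$code,
                            status = c("decedent", "nondecedent"),
                            level = pc_care_levels())
  ecoefs$inpatient_days_per_patient <-
    ifelse(ecoefs$level == "home", 0, runif(nrow(ecoefs), 0, 10))
  ecoefs$outpatient_visits_per_patient <-
    ifelse(ecoefs$level == "home", 0, runif(nrow(ecoefs), 0, 10))
  ecoefs$home_visits_per_patient <-
    ifelse(ecoefs$level == "home", runif(nrow(ecoefs), 0, 40), 0)

  norms <- default_staffing_norms(annual_fte_hours = round(runif(1, 1000, 2000)))
  scale_cols <- c("hours_per_inpatient_day", "hours_per_outpatient_visit",
                  "hours_per_home_visit")
  for (col in scale_cols) {
    norms[[col]] <- norms[[col]] * runif(nrow(norms), 0.5, 2)
  }

  new_scenario(
    reference_year = 2015,
    conditions = conditions, countries = countries, caseload = caseload,
    symptom_coefficients = coefs,
    opioid_supply = supply,
    equianalgesic = eq,
    encounter_coefficients = ecoefs,
    staffing_norms = norms,
    level_allocation = default_level_allocation())
}

# small end-to-end generator spec (cheap enough for property loops)
small_spec <- function(seed, ...) {
  generator_spec(
    seed = seed,
    n_countries = c("low" = 1, "lower-middle" = 1, "upper-middle" = 1,
                    "high" = 1),
    ...)
}

expect_rel_equal <- function(actual, expected, tol = 1e-9) {
  denom <- pmax(abs(expected), 1)
  expect_true(all(abs(actual - expected) / denom <= tol))
}
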