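# Seeded synthetic-scenario generator.
#
# Emulates the statistical structure the pipeline assumes without any
# external download: 21 countries across four income groups (3 low, 7
# lower-middle, 5 upper-middle, 6 high), cause-specific deaths roughly
# proportional to population with income-group condition mixes, prevalent
# non-decedent cases generated directly from per-condition case:death ratios,
# optionally one HIV-dominated low-income country, and opioid supplies
# planted as income-group-specific fractions of the modelled requirement
# (spanning well under 1% of need in low-income settings to over 100% in
# high-income ones). Output is fully determined by the seed.

#' Specification for the synthetic-scenario generator
#'
#' @param seed integer seed; fully determines the generated scenario.
#' @param n_countries named integer vector: countries per income group.
#' @param populations optional named numeric vector of populations (names are
#'   generated country names); drawn log-uniformly per income group when
#'   `NULL`.
#' @param mortality_rate named vector: serious-illness deaths per person-year
#'   by income group (the share of the population dying each year of the 20
#'   framework conditions).
#' @param condition_weights named list (one element per income group) of
#'   non-negative weights over the 20 condition codes; normalised at use.
#' @param case_death_ratios prevalent non-fatal cases per death, by condition.
#' @param hiv_dominated if `TRUE` (default) the first low-income country's
#'   mix is re-weighted so HIV/AIDS carries 80% of its deaths.
#' @param supply_fraction named vector: planted opioid supply as a fraction
#'   of the modelled requirement, by income group.
#' @param include_no_data_country if `TRUE`, append one country flagged
#'   `data_available = FALSE` carrying no counts (excluded from every
#'   aggregate).
#' @param reference_year calendar year the scenario describes.
#' @return object of class `pc_generator_spec`.
#' @export
generator_spec <- function(seed = 1L,
                           n_countries = c("low" = 3, "lower-middle" = 7,
                                           "upper-middle" = 5, "high" = 6),
                           populations = NULL,
                           mortality_rate = c("low" = 0.0045,
                                              "lower-middle" = 0.0035,
                                              "upper-middle" = 0.0030,
                                              "high" = 0.0020),
                           condition_weights = default_condition_weights(),
                           case_death_ratios = default_case_death_ratios(),
                           hiv_dominated = TRUE,
                           supply_fraction = c("low" = 0.005,
                                               "lower-middle" = 0.10,
                                               "upper-middle" = 0.50,
                                               "high" = 1.50),
                           include_no_data_country = FALSE,
                           reference_year = 2015L) {
  spec <- structure(
    list(seed = as.integer(seed), n_countries = n_countries,
         populations = populations, mortality_rate = mortality_rate,
         condition_weights = condition_weights,
         case_death_ratios = case_death_ratios,
         hiv_dominated = isTRUE(hiv_dominated),
         supply_fraction = supply_fraction,
         include_no_data_country = isTRUE(include_no_data_country),
         reference_year = as.integer(reference_year)),
    class = "pc_generator_spec"
  )
  validate_generator_spec(spec)
}

validate_generator_spec <- function(spec) {
  if (length(spec$seed) != 1 || is.na(spec$seed)) {
    pc_validation_error("generator spec: 'seed' must be a single integer")
  }
  groups <- pc_income_groups()
  for (f in c("n_countries", "mortality_rate", "supply_fraction")) {
    v <- spec[[f]]
    if (!all(groups %in% names(v))) {
      pc_validation_error(sprintf(
        "generator spec: '%s' must be named for all income groups", f))
    }
    if (any(v < 0)) {
      pc_validation_error(sprintf("generator spec: '%s' must be non-negative", f))
    }
  }
  codes <- pc_conditions()$code
  for (g in groups) {
    w <- spec$condition_weights[[g]]
    if (is.null(w) || !all(codes %in% names(w))) {
      pc_validation_error(sprintf(
        "generator spec: condition weights for group '%s' must cover all 20 conditions", g))
    }
    if (any(w < 0)) {
      pc_validation_error(sprintf(
        "generator spec: condition weights for group '%s' must be non-negative", g))
    }
    if (sum(w) <= 0) {
      pc_validation_error(sprintf(
        "generator spec: condition weights for group '%s' must not all be zero", g))
    }
  }
  spec
}

generated_country_names <- function(spec) {
  groups <- pc_income_groups()
  abbrev <- c("low" = "LIC", "lower-middle" = "LMC",
              "upper-middle" = "UMC", "high" = "HIC")
  unlist(lapply(groups, function(g) {
    n <- spec$n_countries[[g]]
    if (n == 0) return(character())
    sprintf("%s_%02d", abbrev[[g]], seq_len(n))
  }), use.names = FALSE)
}

population_ranges <- function() {
  list("low" = c(5e6, 4e7), "lower-middle" = c(2e6, 2e8),
       "upper-middle" = c(2e6, 9e7), "high" = c(1e6, 4e7))
}

#' Simulate cause-specific mortality and prevalence envelopes
#'
#' Deaths scale with population (expected deaths = population x income-group
#' mortality rate x normalised condition weight x lognormal noise); prevalent
#' non-decedent cases are generated directly as deaths x per-condition
#' case:death ratio x independent noise. All noise streams are drawn from
#' sub-seeds of `spec$seed` before populations are applied, so supplying
#' doubled populations doubles every expected count.
#'
#' @param spec a `pc_generator_spec`.
#' @return list with `countries` (tibble: `country`, `income_group`,
#'   `population`, `data_available`) and `caseload` (tibble: `country`,
#'   `condition`, `decedent_deaths`, `nondecedent_cases`).
#' @export
simulate_mortality <- function(spec) {
  validate_generator_spec(spec)
  groups <- pc_income_groups()
  codes <- pc_conditions()$code
  country <- generated_country_names(spec)
  income_group <- rep(groups, times = vapply(groups, function(g) {
    as.integer(spec$n_countries[[g]])
  }, integer(1)))

  # populations (sub-seed 0); independent of the count-noise stream
  set.seed(spec$seed)
  if (is.null(spec$populations)) {
    rng <- population_ranges()
    population <- vapply(seq_along(country), function(i) {
      r <- rng[[income_group[i]]]
      round(exp(runif(1, log(r[1]), log(r[2]))))
    }, double(1))
  } else {
    population <- unname(spec$populations[country])
    if (any(is.na(population))) {
      pc_validation_error(
        "generator spec: 'populations' must name every generated country")
    }
    runif(length(country))  # keep the stream position identical either way
  }

  # per-country condition weights; optionally one HIV-dominated low-income mix
  weights <- lapply(seq_along(country), function(i) {
    w <- spec$condition_weights[[income_group[i]]][codes]
    w / sum(w)
  })
  if (spec$hiv_dominated) {
    target <- which(income_group == "low")[1]
    if (is.na(target)) target <- 1L
    w <- weights[[target]]
    others <- w[codes != "HIV"]
    w[codes != "HIV"] <- 0.2 * others / sum(others)
    w["HIV"] <- 0.8
    weights[[target]] <- w
  }

  # multiplicative noise (sub-seeds 1 and 2), drawn per country x condition
  set.seed(spec$seed + 1L)
  death_noise <- matrix(exp(rnorm(length(country) * length(codes),
                                  sd = 0.15)),
                        nrow = length(country))
  set.seed(spec$seed + 2L)
  case_noise <- matrix(exp(rnorm(length(country) * length(codes),
                                 sd = 0.20)),
                       nrow = length(country))

  ratios <- spec$case_death_ratios[codes]
  caseload <- dplyr::bind_rows(lapply(seq_along(country), function(i) {
    mu <- population[i] * spec$mortality_rate[[income_group[i]]] *
      weights[[i]] * death_noise[i, ]
    tibble(
      country = country[i],
      condition = codes,
      decedent_deaths = unname(round(mu)),
      nondecedent_cases = unname(round(mu * ratios * case_noise[i, ]))
    )
  }))

  countries <- tibble(country = country, income_group = income_group,
                      population = population, data_available = TRUE)
  if (spec$include_no_data_country) {
    countries <- bind_rows(countries, tibble(
      country = "NDC_01", income_group = "low", population = NA_real_,
      data_available = FALSE))
  }
  list(countries = countries, caseload = caseload)
}

#' Simulate a country-level opioid supply table
#'
#' Plants, for each country, a total DOME equal to the income-group supply
#' fraction times the modelled requirement, decomposed across four
#' non-methadone products (oral morphine, oral oxycodone, parenteral
#' morphine, transdermal fentanyl) with random Dirichlet shares, plus a
#' methadone record that the DOME accounting must exclude.
#'
#' @param spec a `pc_generator_spec`.
#' @param requirement tibble with `country`, `required_mg` (from
#'   [required_ome()]).
#' @param countries tibble with `country`, `income_group`.
#' @return tibble with `country`, `opioid`, `route_class`, `quantity_mg`.
#' @export
simulate_opioid_supply <- function(spec, requirement, countries) {
  validate_generator_spec(spec)
  eq <- default_equianalgesic()
  products <- eq %>% filter(!.data$is_methadone)
  req <- requirement %>%
    inner_join(countries %>% select("country", "income_group"),
               by = "country")

  set.seed(spec$seed + 3L)
  bind_rows(lapply(seq_len(nrow(req)), function(i) {
    f <- spec$supply_fraction[[req$income_group[i]]]
    target <- f * req$required_mg[i]
    shares <- rgamma(nrow(products), shape = 1)
    shares <- shares / sum(shares)
    methadone_mg <- runif(1, 1e4, 1e6)
    tibble(
      country = req$country[i],
      opioid = c(products$opioid, "methadone"),
      route_class = c(products$route_class, "oral"),
      quantity_mg = c(target * shares / products$ome_multiplier, methadone_mg)
    )
  }))
}

#' Generate a complete synthetic scenario
#'
#' Assembles conditions, default symptom coefficients, simulated mortality
#' and prevalence, a planted opioid supply, encounter coefficients built from
#' the default level-allocation profile, and default staffing norms into a
#' fully validated scenario.
#'
#' @param spec a `pc_generator_spec`; defaults to `generator_spec()`.
#' @return a validated `pc_scenario`.
#' @export
make_scenario <- function(spec = generator_spec()) {
  validate_generator_spec(spec)
  conditions <- pc_conditions()
  coefs <- make_default_coefficients()
  mort <- simulate_mortality(spec)

  need <- mort$caseload %>%
    inner_join(conditions %>%
                 select("code", "decedent_need_fraction",
                        "nondecedent_need_fraction"),
               by = c("condition" = "code")) %>%
    mutate(
      decedents_in_need = .data$decedent_deaths * .data$decedent_need_fraction,
      nondecedents_in_need =
        .data$nondecedent_cases * .data$nondecedent_need_fraction
    ) %>%
    select("country", "condition", "decedents_in_need", "nondecedents_in_need")
  class(need) <- c("pc_need", class(need))

  params <- default_requirement_params()
  requirement <- required_ome(need, coefs, params)
  supply <- simulate_opioid_supply(spec, requirement, mort$countries)

  allocation <- default_level_allocation()
  encounter <- build_encounter_coefficients(
    conditions$code,
    allocation %>% filter(.data$income_group == "lower-middle") %>%
      select(-"income_group")
  )

  new_scenario(
    reference_year = spec$reference_year,
    conditions = conditions,
    countries = mort$countries,
    caseload = mort$caseload,
    symptom_coefficients = coefs,
    opioid_supply = supply,
    equianalgesic = default_equianalgesic(),
    encounter_coefficients = encounter,
    staffing_norms = default_staffing_norms(),
    level_allocation = allocation,
    config = c(list(at_least_weighting = "prevalence"), params)
  )
}
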