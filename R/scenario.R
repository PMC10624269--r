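# Scenario container and CSV/YAML persistence.
#
# A scenario is the complete input bundle one pipeline run consumes: the
# condition framework, per-country populations and cause-specific caseloads,
# symptom coefficients, opioid supply and equianalgesic factors, encounter
# coefficients, staffing norms, and configuration. On disk it is a directory
# of plain CSV tables plus a scenario.yaml config naming them — inspectable
# and diffable. All internal computation uses unrounded values; persistence
# keeps full double precision so write/read round-trips are exact.

scenario_tables <- function() {
  c("conditions", "countries", "symptom_coefficients", "opioid_supply",
    "equianalgesic", "encounter_coefficients", "staffing_norms",
    "level_allocation")
}

default_config <- function() {
  c(list(at_least_weighting = "prevalence"), default_requirement_params())
}

#' Construct and validate a scenario
#'
#' Assembles the input bundle for a pipeline run and checks every invariant
#' (bounds, closed enumerations, uniqueness, and cross-references). Most users
#' build scenarios with [make_scenario()] or read them with [load_scenario()];
#' `new_scenario()` is the low-level constructor.
#'
#' @param reference_year calendar year the mortality/prevalence envelope
#'   describes.
#' @param conditions condition framework, as in [pc_conditions()].
#' @param countries tibble with `country`, `income_group`, `population`,
#'   `data_available`.
#' @param caseload tibble with `country`, `condition`, `decedent_deaths`,
#'   `nondecedent_cases` (long form; only data-available countries appear).
#' @param symptom_coefficients as in [make_default_coefficients()].
#' @param opioid_supply tibble with `country`, `opioid`, `route_class`,
#'   `quantity_mg`.
#' @param equianalgesic as in [default_equianalgesic()].
#' @param encounter_coefficients as in [build_encounter_coefficients()].
#' @param staffing_norms as in [default_staffing_norms()].
#' @param level_allocation as in [default_level_allocation()].
#' @param config named list; `at_least_weighting` (`"prevalence"` or
#'   `"unit"`), plus the requirement parameters of
#'   [default_requirement_params()].
#' @return a validated object of class `pc_scenario`.
#' @export
new_scenario <- function(reference_year, conditions, countries, caseload,
                         symptom_coefficients, opioid_supply, equianalgesic,
                         encounter_coefficients, staffing_norms,
                         level_allocation, config = default_config()) {
  sc <- structure(
    list(
      reference_year = as.integer(reference_year),
      config = modifyList(default_config(), config),
      conditions = as_tibble(conditions),
      countries = as_tibble(countries),
      caseload = as_tibble(caseload),
      symptom_coefficients = as_tibble(symptom_coefficients),
      opioid_supply = as_tibble(opioid_supply),
      equianalgesic = as_tibble(equianalgesic),
      encounter_coefficients = as_tibble(encounter_coefficients),
      staffing_norms = as_tibble(staffing_norms),
      level_allocation = as_tibble(level_allocation)
    ),
    class = "pc_scenario"
  )
  validate_scenario(sc)
}

fail_rows <- function(table, df, bad, what) {
  if (any(bad, na.rm = TRUE)) {
    rows <- which(bad)
    pc_validation_error(sprintf(
      "table '%s': %s (row%s %s)",
      table, what, if (length(rows) > 1) "s" else "",
      paste(utils::head(rows, 5), collapse = ", ")
    ))
  }
}

#' Validate a scenario's invariants
#'
#' Checks all field bounds, closed enumerations, uniqueness constraints, and
#' cross-references between tables, raising a classed `pc_validation_error`
#' naming the offending table and rows on the first violation.
#'
#' @param sc a `pc_scenario`.
#' @return `sc`, invisibly usable in pipelines (returned visibly for
#'   constructor use).
#' @export
validate_scenario <- function(sc) {
  if (!inherits(sc, "pc_scenario")) {
    pc_validation_error("not a pc_scenario object")
  }

  co <- sc$conditions
  stopifnot_columns(co, c("code", "name", "decedent_need_fraction",
                          "nondecedent_need_fraction"), "conditions")
  fail_rows("conditions", co, duplicated(co$code), "duplicate condition code")
  fail_rows("conditions", co,
            co$decedent_need_fraction < 0 | co$decedent_need_fraction > 1,
            "field 'decedent_need_fraction' outside [0,1]")
  fail_rows("conditions", co,
            co$nondecedent_need_fraction < 0 | co$nondecedent_need_fraction > 1,
            "field 'nondecedent_need_fraction' outside [0,1]")

  cn <- sc$countries
  stopifnot_columns(cn, c("country", "income_group", "population",
                          "data_available"), "countries")
  fail_rows("countries", cn, duplicated(cn$country), "duplicate country")
  fail_rows("countries", cn, !cn$income_group %in% pc_income_groups(),
            "field 'income_group' not a recognised income group")
  fail_rows("countries", cn,
            cn$data_available & (is.na(cn$population) | cn$population <= 0),
            "field 'population' must be > 0 when data are available")

  cl <- sc$caseload
  stopifnot_columns(cl, c("country", "condition", "decedent_deaths",
                          "nondecedent_cases"), "caseload")
  fail_rows("caseload", cl, !cl$country %in% cn$country[cn$data_available],
            "country not declared as data-available")
  fail_rows("caseload", cl, !cl$condition %in% co$code,
            "condition code not declared")
  fail_rows("caseload", cl, cl$decedent_deaths < 0,
            "field 'decedent_deaths' negative")
  fail_rows("caseload", cl, cl$nondecedent_cases < 0,
            "field 'nondecedent_cases' negative")

  syc <- sc$symptom_coefficients
  stopifnot_columns(syc, c("condition", "symptom", "status", "prevalence",
                           "duration_days"), "symptom_coefficients")
  fail_rows("symptom_coefficients", syc, !syc$condition %in% co$code,
            "condition code not declared")
  fail_rows("symptom_coefficients", syc,
            !syc$symptom %in% pc_symptoms()$symptom,
            "field 'symptom' not a recognised symptom")
  fail_rows("symptom_coefficients", syc,
            !syc$status %in% c("decedent", "nondecedent"),
            "field 'status' must be decedent or nondecedent")
  fail_rows("symptom_coefficients", syc,
            syc$prevalence < 0 | syc$prevalence > 1,
            "field 'prevalence' outside [0,1]")
  fail_rows("symptom_coefficients", syc, syc$duration_days < 0,
            "field 'duration_days' negative")
  fail_rows("symptom_coefficients", syc,
            duplicated(syc[c("condition", "symptom", "status")]),
            "more than one row per (condition, symptom, status)")

  eq <- sc$equianalgesic
  stopifnot_columns(eq, c("opioid", "route_class", "ome_multiplier",
                          "is_methadone"), "equianalgesic")
  fail_rows("equianalgesic", eq, eq$ome_multiplier <= 0,
            "field 'ome_multiplier' must be > 0")

  os <- sc$opioid_supply
  stopifnot_columns(os, c("country", "opioid", "route_class", "quantity_mg"),
                    "opioid_supply")
  fail_rows("opioid_supply", os, os$quantity_mg < 0,
            "field 'quantity_mg' negative")
  fail_rows("opioid_supply", os, !os$country %in% cn$country,
            "country not declared")
  known <- paste(eq$opioid, eq$route_class)
  fail_rows("opioid_supply", os,
            !paste(os$opioid, os$route_class) %in% known,
            "opioid/route has no equianalgesic factor")

  ec <- sc$encounter_coefficients
  stopifnot_columns(ec, c("condition", "status", "level",
                          "inpatient_days_per_patient",
                          "outpatient_visits_per_patient",
                          "home_visits_per_patient"), "encounter_coefficients")
  fail_rows("encounter_coefficients", ec, !ec$condition %in% co$code,
            "condition code not declared")
  fail_rows("encounter_coefficients", ec, !ec$level %in% pc_care_levels(),
            "field 'level' not a recognised care level")
  for (f in c("inpatient_days_per_patient", "outpatient_visits_per_patient",
              "home_visits_per_patient")) {
    fail_rows("encounter_coefficients", ec, ec[[f]] < 0,
              sprintf("field '%s' negative", f))
  }
  fail_rows("encounter_coefficients", ec,
            ec$level == "home" & (ec$inpatient_days_per_patient > 0 |
                                    ec$outpatient_visits_per_patient > 0),
            "home level may carry only home visits")
  fail_rows("encounter_coefficients", ec,
            ec$level != "home" & ec$home_visits_per_patient > 0,
            "home visits allowed only at the home level")

  sn <- sc$staffing_norms
  stopifnot_columns(sn, c("staff_category", "level", "hours_per_inpatient_day",
                          "hours_per_outpatient_visit", "hours_per_home_visit",
                          "annual_fte_hours"), "staffing_norms")
  fail_rows("staffing_norms", sn,
            !sn$staff_category %in% pc_staff_categories(),
            "field 'staff_category' not a recognised category")
  fail_rows("staffing_norms", sn, !sn$level %in% pc_care_levels(),
            "field 'level' not a recognised care level")
  fail_rows("staffing_norms", sn, sn$annual_fte_hours <= 0,
            "field 'annual_fte_hours' must be > 0")

  la <- sc$level_allocation
  stopifnot_columns(la, c("income_group", "level", "inpatient_share",
                          "outpatient_share"), "level_allocation")
  fail_rows("level_allocation", la,
            la$inpatient_share < 0 | la$outpatient_share < 0,
            "allocation shares must be non-negative")

  cfg <- sc$config
  if (!cfg$at_least_weighting %in% c("prevalence", "unit")) {
    pc_validation_error(
      "config: 'at_least_weighting' must be 'prevalence' or 'unit'")
  }
  if (!cfg$requirement_population %in% c("all", "decedents")) {
    pc_validation_error(
      "config: 'requirement_population' must be 'all' or 'decedents'")
  }
  if (cfg$pain_daily_dose_mg <= 0 || cfg$dyspnea_daily_dose_mg <= 0) {
    pc_validation_error("config: daily doses must be > 0")
  }

  sc
}

#' @export
print.pc_scenario <- function(x, ...) {
  cat(sprintf(
    "<pc_scenario> reference year %d: %d countries (%d with data), %d conditions, %d symptom-coefficient rows\n",
    x$reference_year, nrow(x$countries), sum(x$countries$data_available),
    nrow(x$conditions), nrow(x$symptom_coefficients)
  ))
  invisible(x)
}

# full-precision CSV round-trip helpers ---------------------------------------

write_csv_exact <- function(df, path) {
  out <- df
  for (nm in names(out)) {
    if (is.double(out[[nm]])) {
      v <- sprintf("%.17g", out[[nm]])
      v[is.na(out[[nm]])] <- NA_character_
      out[[nm]] <- v
    }
  }
  readr::write_csv(out, path, na = "")
}

strip_readr_attrs <- function(df) {
  attr(df, "spec") <- NULL
  attr(df, "problems") <- NULL
  class(df) <- c("tbl_df", "tbl", "data.frame")
  df
}

read_scenario_csv <- function(path, double_cols, logical_cols = character()) {
  if (!file.exists(path)) {
    pc_io_error(sprintf("scenario table not found: %s", path))
  }
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                        na = "")
  df <- strip_readr_attrs(df)
  for (nm in intersect(double_cols, names(df))) df[[nm]] <- as.double(df[[nm]])
  for (nm in intersect(logical_cols, names(df))) {
    df[[nm]] <- as.logical(df[[nm]])
  }
  df
}

#' Write a scenario to a directory of CSV tables
#'
#' Persists the scenario as `scenario.yaml` plus one CSV per input table.
#' Country caseloads are stored as wide `deaths_<code>` / `cases_<code>`
#' columns of `countries.csv`. Doubles are written with 17 significant digits
#' so that [load_scenario()] reproduces the scenario exactly.
#'
#' @param sc a validated `pc_scenario`.
#' @param dir output directory (created if absent).
#' @return the directory path, invisibly.
#' @export
write_scenario <- function(sc, dir) {
  validate_scenario(sc)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  codes <- sc$conditions$code
  wide <- sc$countries
  if (nrow(sc$caseload) > 0) {
    deaths <- sc$caseload %>%
      select("country", "condition", "decedent_deaths") %>%
      pivot_wider(names_from = "condition", values_from = "decedent_deaths",
                  names_prefix = "deaths_")
    cases <- sc$caseload %>%
      select("country", "condition", "nondecedent_cases") %>%
      pivot_wider(names_from = "condition", values_from = "nondecedent_cases",
                  names_prefix = "cases_")
    wide <- wide %>% left_join(deaths, by = "country") %>%
      left_join(cases, by = "country")
  }

  files <- stats::setNames(paste0(scenario_tables(), ".csv"),
                           scenario_tables())
  write_csv_exact(wide, file.path(dir, files[["countries"]]))
  write_csv_exact(sc$conditions, file.path(dir, files[["conditions"]]))
  write_csv_exact(sc$symptom_coefficients,
                  file.path(dir, files[["symptom_coefficients"]]))
  write_csv_exact(sc$opioid_supply, file.path(dir, files[["opioid_supply"]]))
  write_csv_exact(sc$equianalgesic, file.path(dir, files[["equianalgesic"]]))
  write_csv_exact(sc$encounter_coefficients,
                  file.path(dir, files[["encounter_coefficients"]]))
  write_csv_exact(sc$staffing_norms,
                  file.path(dir, files[["staffing_norms"]]))
  write_csv_exact(sc$level_allocation,
                  file.path(dir, files[["level_allocation"]]))

  yaml::write_yaml(
    list(
      schema = "palneed-scenario/1",
      reference_year = sc$reference_year,
      tables = as.list(files),
      config = sc$config
    ),
    file.path(dir, "scenario.yaml")
  )
  invisible(dir)
}

#' Load and validate a scenario from disk
#'
#' Reads a scenario directory written by [write_scenario()] (or assembled by
#' hand in the same layout), resolves all cross-references, and validates
#' every invariant. Missing files raise a classed `pc_io_error`; invariant
#' violations raise a `pc_validation_error` naming the table and rows.
#'
#' @param path scenario directory, or the path of its `scenario.yaml`.
#' @return a validated `pc_scenario`.
#' @export
load_scenario <- function(path) {
  cfg_path <- if (dir.exists(path)) file.path(path, "scenario.yaml") else path
  if (!file.exists(cfg_path)) {
    pc_io_error(sprintf("scenario config not found: %s", cfg_path))
  }
  meta <- yaml::read_yaml(cfg_path)
  if (is.null(meta$schema) || !identical(meta$schema, "palneed-scenario/1")) {
    pc_validation_error(sprintf(
      "unsupported scenario schema: %s", meta$schema %||% "<missing>"))
  }
  dir <- dirname(cfg_path)
  tp <- function(key) file.path(dir, meta$tables[[key]])

  wide <- read_scenario_csv(
    tp("countries"),
    double_cols = setdiff(names(readr::read_csv(tp("countries"), n_max = 0,
                                                col_types = readr::cols())),
                          c("country", "income_group", "data_available")),
    logical_cols = "data_available"
  )
  count_cols <- grep("^(deaths|cases)_", names(wide), value = TRUE)
  countries <- wide %>%
    select("country", "income_group", "population", "data_available")

  caseload <- tibble(country = character(), condition = character(),
                     decedent_deaths = double(), nondecedent_cases = double())
  if (length(count_cols) > 0) {
    caseload <- wide %>%
      filter(.data$data_available) %>%
      select("country", all_of(count_cols)) %>%
      pivot_longer(-"country", names_to = c("kind", "condition"),
                   names_pattern = "^(deaths|cases)_(.+)$") %>%
      pivot_wider(names_from = "kind", values_from = "value") %>%
      rename(decedent_deaths = "deaths", nondecedent_cases = "cases")
  }

  conditions <- read_scenario_csv(
    tp("conditions"),
    double_cols = c("decedent_need_fraction", "nondecedent_need_fraction"))
  syc <- read_scenario_csv(
    tp("symptom_coefficients"),
    double_cols = c("prevalence", "duration_days"))
  opioid_supply <- read_scenario_csv(tp("opioid_supply"),
                                     double_cols = "quantity_mg")
  equianalgesic <- read_scenario_csv(tp("equianalgesic"),
                                     double_cols = "ome_multiplier",
                                     logical_cols = "is_methadone")
  encounter <- read_scenario_csv(
    tp("encounter_coefficients"),
    double_cols = c("inpatient_days_per_patient",
                    "outpatient_visits_per_patient",
                    "home_visits_per_patient"))
  norms <- read_scenario_csv(
    tp("staffing_norms"),
    double_cols = c("hours_per_inpatient_day", "hours_per_outpatient_visit",
                    "hours_per_home_visit", "annual_fte_hours"))
  allocation <- read_scenario_csv(
    tp("level_allocation"),
    double_cols = c("inpatient_share", "outpatient_share"))

  # canonical row order so round-trips are reproducible field-by-field
  caseload <- caseload %>%
    arrange(match(.data$country, countries$country),
            match(.data$condition, conditions$code))

  new_scenario(
    reference_year = meta$reference_year,
    conditions = conditions,
    countries = countries,
    caseload = caseload,
    symptom_coefficients = syc,
    opioid_supply = opioid_supply,
    equianalgesic = equianalgesic,
    encounter_coefficients = encounter,
    staffing_norms = norms,
    level_allocation = allocation,
    config = meta$config
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bundled example scenario
#'
#' Loads the synthetic demonstration scenario shipped with the package
#' (21 countries in four income groups plus one no-data country, 20
#' conditions, 15 symptoms), generated by [make_scenario()] with a fixed
#' seed and stored as plain CSV.
#'
#' @return a validated `pc_scenario`.
#' @export
pc_demo_scenario <- function() {
  load_scenario(system.file("extdata", "demo_scenario",
                            package = "palneed", mustWork = TRUE))
}

#' Reported regional reference tables
#'
#' Transcribed 2015 estimates for the WHO Eastern Mediterranean Region used
#' for arithmetic cross-checks: the per-country need/symptom-day table
#' (values as printed: symptom-days in millions, counts in thousands,
#' `"No data"` for Palestine) and the three-country workforce table
#' (population, patients, encounter days, FTEs, FTEs per 100,000). These are
#' reference inputs, not outputs of the pipeline.
#'
#' @return list with tibbles `need` and `workforce`.
#' @export
pc_reported_tables <- function() {
  dir <- system.file("extdata", "reported", package = "palneed",
                     mustWork = TRUE)
  need <- strip_readr_attrs(readr::read_csv(
    file.path(dir, "eamreg_2015_need_table.csv"),
    col_types = readr::cols(.default = "c")))
  workforce <- strip_readr_attrs(readr::read_csv(
    file.path(dir, "eamreg_2015_workforce_table.csv"),
    col_types = readr::cols(quantity = "c", .default = "d")))
  list(need = need, workforce = workforce)
}
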