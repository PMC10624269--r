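# Report tables, figure-data exports, and the end-to-end pipeline.
#
# Rounding happens only here, at the reporting boundary: counts in thousands
# (0 decimals), symptom-days in millions (0 decimals), FTE counts as
# integers, per-100k staffing densities to 2 decimals — all half-up. Totals
# are computed from unrounded values and rounded last. Countries flagged as
# having no data appear as "No data" and contribute nothing to totals.

fmt_count <- function(x, digits = 0) {
  v <- round_half_up(x, digits)
  if (digits == 0) {
    format(v, scientific = FALSE, trim = TRUE, big.mark = "")
  } else {
    sprintf(paste0("%.", digits, "f"), v)
  }
}

#' Write the per-country need and symptom-day table
#'
#' One row per country (grouped by income group) plus a Total row: at-most
#' and at-least symptom days in millions, decedents, non-decedents, and total
#' people in need in thousands. The Total row is computed from unrounded
#' country values and rounded last; countries without data appear as
#' `"No data"` and contribute nothing.
#'
#' @param need a `pc_need` tibble.
#' @param burden a `pc_burden` from [symptom_burden()] covering the same
#'   countries (otherwise a `pc_validation_error` is raised).
#' @param countries scenario country table (for income groups and no-data
#'   flags).
#' @param path output CSV path.
#' @return the written table, invisibly.
#' @export
write_country_table <- function(need, burden, countries, path) {
  if (nrow(need) == 0) {
    empty <- tibble(country = character(), income_group = character(),
                    at_most_symptom_days_millions = character(),
                    at_least_symptom_days_millions = character(),
                    decedents_thousands = character(),
                    nondecedents_thousands = character(),
                    total_thousands = character())
    readr::write_csv(empty, path)
    return(invisible(empty))
  }
  totals <- need_totals(need)
  if (!setequal(totals$country, burden$totals$country)) {
    pc_validation_error(
      "need and burden estimates cover different country sets")
  }
  values <- totals %>%
    inner_join(burden$totals, by = "country") %>%
    inner_join(countries %>% select("country", "income_group"),
               by = "country")

  rows <- values %>%
    arrange(match(.data$income_group, pc_income_groups()), .data$country) %>%
    mutate(
      at_most_symptom_days_millions = fmt_count(.data$at_most_days / 1e6),
      at_least_symptom_days_millions = fmt_count(.data$at_least_days / 1e6),
      decedents_thousands = fmt_count(.data$decedent_total / 1e3),
      nondecedents_thousands = fmt_count(.data$nondecedent_total / 1e3),
      total_thousands = fmt_count(.data$grand_total / 1e3)
    ) %>%
    select("country", "income_group", "at_most_symptom_days_millions",
           "at_least_symptom_days_millions", "decedents_thousands",
           "nondecedents_thousands", "total_thousands")

  nodata <- countries %>%
    filter(!.data$data_available) %>%
    mutate(
      at_most_symptom_days_millions = "No data",
      at_least_symptom_days_millions = "No data",
      decedents_thousands = "No data",
      nondecedents_thousands = "No data",
      total_thousands = "No data"
    ) %>%
    select(all_of(names(rows)))
  if (nrow(nodata) > 0) {
    rows <- bind_rows(rows, nodata) %>%
      arrange(match(.data$income_group, pc_income_groups()), .data$country)
  }

  total_row <- tibble(
    country = "Total", income_group = "",
    at_most_symptom_days_millions = fmt_count(sum(values$at_most_days) / 1e6),
    at_least_symptom_days_millions =
      fmt_count(sum(values$at_least_days) / 1e6),
    decedents_thousands = fmt_count(sum(values$decedent_total) / 1e3),
    nondecedents_thousands = fmt_count(sum(values$nondecedent_total) / 1e3),
    total_thousands = fmt_count(sum(values$grand_total) / 1e3)
  )
  out <- bind_rows(rows, total_row)
  readr::write_csv(out, path)
  invisible(out)
}

#' Write the encounter and workforce table
#'
#' Per country: population, decedents, non-decedents and total patients in
#' need; inpatient days and outpatient visits at the four facility levels;
#' total home visits; FTE per staff category (integers); and FTE per 100,000
#' population per category (2 decimals, printed as e.g. `"0.00"`).
#'
#' @param workforce a `pc_workforce` from [workforce_estimate()].
#' @param path output CSV path.
#' @return the written table, invisibly.
#' @export
write_workforce_table <- function(workforce, path) {
  if (nrow(workforce$patients) == 0) {
    pc_validation_error("workforce estimate covers no countries")
  }
  facility <- setdiff(pc_care_levels(), "home")

  enc_wide <- workforce$encounters %>%
    filter(.data$level != "home") %>%
    select("country", "level", "inpatient_days", "outpatient_visits") %>%
    pivot_wider(names_from = "level",
                values_from = c("inpatient_days", "outpatient_visits"))
  home <- workforce$encounters %>%
    filter(.data$level == "home") %>%
    select("country", total_home_visits = "home_visits")

  fte_wide <- workforce$fte %>%
    mutate(total_fte = round_half_up(.data$total_fte),
           fte_per_100k = sprintf("%.2f",
                                  round_half_up(.data$fte_per_100k, 2))) %>%
    pivot_wider(names_from = "staff_category",
                values_from = c("total_fte", "fte_per_100k"))

  out <- workforce$patients %>%
    inner_join(workforce$population, by = "country") %>%
    mutate(
      decedents = round_half_up(.data$decedent_total),
      nondecedents = round_half_up(.data$nondecedent_total),
      total_patients = round_half_up(.data$grand_total)
    ) %>%
    select("country", "population", "decedents", "nondecedents",
           "total_patients") %>%
    inner_join(enc_wide, by = "country") %>%
    inner_join(home, by = "country") %>%
    mutate(across(c(dplyr::starts_with("inpatient_days_"),
                    dplyr::starts_with("outpatient_visits_"),
                    "total_home_visits"), round_half_up)) %>%
    inner_join(fte_wide, by = "country")
  readr::write_csv(out, path)
  invisible(out)
}

#' Export long-format figure data
#'
#' Writes `fig1_condition_shares.csv` (percentage of need by condition),
#' `fig2_symptom_shares.csv` (percentage of symptom-days by symptom), and
#' `fig3_opioid_access.csv` (DOME per patient in need and percent of need
#' met), each as `country, key, value` rows at full precision.
#'
#' @param results named list with any of `condition_shares`,
#'   `symptom_shares`, `opioid_access` (outputs of the corresponding stage).
#' @param dir output directory.
#' @param figures which figure files to write. Requesting a figure whose
#'   stage result is absent raises a classed `pc_missing_stage_error`.
#' @return character vector of the files written, invisibly.
#' @export
export_figure_data <- function(results, dir,
                               figures = c("fig1", "fig2", "fig3")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  require_stage <- function(name, fig) {
    if (is.null(results[[name]])) {
      pc_abort(sprintf("stage result '%s' is missing; cannot export %s",
                       name, fig), class = "pc_missing_stage_error")
    }
    results[[name]]
  }
  if ("fig1" %in% figures) {
    shares <- require_stage("condition_shares", "fig1")
    f <- file.path(dir, "fig1_condition_shares.csv")
    write_csv_exact(shares %>%
                      select("country", key = "condition", value = "share"), f)
    written <- c(written, f)
  }
  if ("fig2" %in% figures) {
    shares <- require_stage("symptom_shares", "fig2")
    f <- file.path(dir, "fig2_symptom_shares.csv")
    write_csv_exact(shares %>%
                      select("country", key = "symptom", value = "share"), f)
    written <- c(written, f)
  }
  if ("fig3" %in% figures) {
    access <- require_stage("opioid_access", "fig3")
    f <- file.path(dir, "fig3_opioid_access.csv")
    write_csv_exact(
      access %>%
        select("country", "dome_per_patient_mg", "percent_met") %>%
        pivot_longer(-"country", names_to = "key", values_to = "value"),
      f)
    written <- c(written, f)
  }
  invisible(written)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, pc_error = function(e) {
    pc_abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
             class = class(e)[1])
  })
}

#' Run the full estimation pipeline
#'
#' Executes need estimation, symptom-day bounds, opioid access, and the
#' workforce model in order, writing every report table, the three
#' figure-data files, and a run manifest. All stage outputs are pure
#' functions of the scenario, so reruns are byte-identical.
#'
#' @param scenario a `pc_scenario`.
#' @param out_dir output directory (created if absent).
#' @param skip character vector of stages to skip, among `"symptoms"`,
#'   `"opioids"`, `"workforce"` (need estimation underlies everything and
#'   always runs). Tables depending on a skipped stage are not written.
#' @param workforce_countries countries for the workforce table; defaults to
#'   all data-available countries.
#' @return named list of stage results (invisibly): `need`, `burden`,
#'   `opioid_access`, `workforce`, `manifest`.
#' @export
run_pipeline <- function(scenario, out_dir, skip = character(),
                         workforce_countries = NULL) {
  validate_scenario(scenario)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- c("need", setdiff(c("symptoms", "opioids", "workforce"), skip))
  outputs <- character()
  results <- list()

  results$need <- run_stage("need", estimate_need(scenario))
  shares1 <- run_stage("need", condition_shares(results$need))
  f <- file.path(out_dir, "need_by_condition.csv")
  write_csv_exact(results$need, f)
  outputs <- c(outputs, f)
  f <- file.path(out_dir, "need_totals.csv")
  write_csv_exact(need_totals(results$need), f)
  outputs <- c(outputs, f)
  outputs <- c(outputs,
               export_figure_data(list(condition_shares = shares1), out_dir,
                                  figures = "fig1"))

  if ("symptoms" %in% stages) {
    results$burden <- run_stage("symptoms", symptom_burden(
      results$need, scenario$symptom_coefficients,
      weighting = scenario$config$at_least_weighting))
    shares2 <- run_stage("symptoms", symptom_shares(results$burden))
    f <- file.path(out_dir, "symptom_burden.csv")
    write_csv_exact(results$burden$totals, f)
    outputs <- c(outputs, f)
    outputs <- c(outputs,
                 export_figure_data(list(symptom_shares = shares2), out_dir,
                                    figures = "fig2"))
    f <- file.path(out_dir, "table1.csv")
    run_stage("tables", write_country_table(results$need, results$burden,
                                            scenario$countries, f))
    outputs <- c(outputs, f)
  }

  if ("opioids" %in% stages) {
    results$opioid_access <- run_stage("opioids",
                                       opioid_access(scenario, results$need))
    f <- file.path(out_dir, "opioid_access.csv")
    write_csv_exact(results$opioid_access, f)
    outputs <- c(outputs, f)
    outputs <- c(outputs,
                 export_figure_data(list(opioid_access = results$opioid_access),
                                    out_dir, figures = "fig3"))
  }

  if ("workforce" %in% stages) {
    results$workforce <- run_stage("workforce", workforce_estimate(
      scenario, countries = workforce_countries))
    f <- file.path(out_dir, "table2.csv")
    run_stage("workforce", write_workforce_table(results$workforce, f))
    outputs <- c(outputs, f)
    f <- file.path(out_dir, "workforce_ranges.csv")
    ranges <- bind_rows(lapply(pc_staff_categories(), function(cat) {
      r <- workforce_summary_range(results$workforce, cat)
      tibble(staff_category = cat, min_fte_per_100k = r[["min"]],
             max_fte_per_100k = r[["max"]])
    }))
    readr::write_csv(ranges, f)
    outputs <- c(outputs, f)
  }

  manifest <- list(
    schema = "palneed-run/1",
    reference_year = scenario$reference_year,
    config = scenario$config,
    scenario_hash = rlang::hash(unclass(scenario)),
    stages = stages,
    outputs = basename(outputs)
  )
  manifest$manifest_hash <- rlang::hash(manifest)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  results$manifest <- manifest
  invisible(results)
}
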