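test_that("encounter totals are patients times per-patient coefficients", {
  need <- tibble::tibble(country = "A", condition = "MAL",
                         decedents_in_need = 100, nondecedents_in_need = 0)
  class(need) <- c("pc_need", class(need))
  coefs <- tibble::tibble(
    condition = "MAL", status = "decedent", level = "district_hospital",
    inpatient_days_per_patient = 2, outpatient_visits_per_patient = 0,
    home_visits_per_patient = 0)
  enc <- encounter_totals(need, coefs)
  expect_equal(enc$inpatient_days[enc$level == "district_hospital"], 200)
  expect_true(all(enc$inpatient_days[enc$level != "district_hospital"] == 0))

  zero <- need
  zero$decedents_in_need <- 0
  encz <- encounter_totals(zero, coefs)
  expect_true(all(encz$inpatient_days == 0 & encz$outpatient_visits == 0 &
                    encz$home_visits == 0))

  uncovered <- need
  uncovered$condition <- "HIV"
  expect_error(encounter_totals(uncovered, coefs),
               class = "pc_validation_error")
})

test_that("staff FTEs divide staffing hours by annual FTE hours", {
  # 1,650 nurse-hours against a 1,650-hour year is exactly one FTE
  enc <- tibble::tibble(
    country = "A", level = pc_care_levels(),
    inpatient_days = c(1375, 0, 0, 0, 0),
    outpatient_visits = 0, home_visits = 0)
  norms <- default_staffing_norms() # nurse: 1.2 h per inpatient day
  fte <- staff_fte(enc, norms)
  nurse <- fte$fte[fte$staff_category == "nurse" &
                     fte$level == "referral_hospital"]
  expect_equal(nurse, 1375 * 1.2 / 1650)
  expect_true(all(fte$fte[fte$level != "referral_hospital"] == 0))

  bad <- norms
  bad$annual_fte_hours[1] <- 0
  expect_error(staff_fte(enc, bad), class = "pc_validation_error")
  expect_error(staff_fte(enc, norms[norms$level != "home", ]),
               class = "pc_validation_error")
})

test_that("FTE arithmetic matches the brute-force oracle and scales as hours do", {
  for (seed in c(81, 82)) {
    sc <- tiny_scenario(seed)
    need <- estimate_need(sc)
    enc <- encounter_totals(need, sc$encounter_coefficients)
    oenc <- oracle_encounters(as.data.frame(need),
                              as.data.frame(sc$encounter_coefficients))
    keys <- paste(enc$country, enc$level, sep = "\r")
    got <- cbind(enc$inpatient_days, enc$outpatient_visits, enc$home_visits)
    exp_ <- t(vapply(keys, function(k) {
      oenc[[k]] %||% c(ip = 0, op = 0, hv = 0)
    }, numeric(3)))
    expect_rel_equal(as.vector(got), as.vector(exp_))

    fte <- staff_fte(enc, sc$staffing_norms)
    ofte <- oracle_fte(oenc, as.data.frame(sc$staffing_norms))
    totals <- stats::aggregate(fte ~ country + staff_category, fte, sum)
    okeys <- paste(totals$country, totals$staff_category, sep = "\r")
    expect_rel_equal(totals$fte, unlist(ofte[okeys]))

    # doubling the norm hours doubles FTEs; doubling the year halves them
    sc2 <- sc
    for (col in c("hours_per_inpatient_day", "hours_per_outpatient_visit",
                  "hours_per_home_visit")) {
      sc2$staffing_norms[[col]] <- sc2$staffing_norms[[col]] * 2
    }
    expect_rel_equal(staff_fte(enc, sc2$staffing_norms)$fte, 2 * fte$fte)
    sc3 <- sc
    sc3$staffing_norms$annual_fte_hours <- sc3$staffing_norms$annual_fte_hours * 2
    expect_rel_equal(staff_fte(enc, sc3$staffing_norms)$fte, fte$fte / 2)
  }
})

test_that("per-100k normalisation reproduces reported staffing densities", {
  expect_equal(round_half_up(fte_per_100k(722, 38928340), 2), 1.85)
  expect_equal(round_half_up(fte_per_100k(554, 10203140), 2), 5.43)
  expect_equal(fte_per_100k(0, 5e6), 0)
  expect_error(fte_per_100k(10, 0), class = "pc_validation_error")
})

test_that("summary ranges take the min and max density across countries", {
  fte <- tibble::tibble(
    staff_category = rep(c("community_health_worker", "nurse"), each = 3),
    fte_per_100k = c(7.75, 11.10, 5.43, 3.71, 4.30, 2.18))
  expect_equal(workforce_summary_range(fte, "community_health_worker"),
               c(min = 5.4, max = 11.1))
  expect_equal(workforce_summary_range(fte, "nurse"), c(min = 2.2, max = 4.3))
  one <- fte[1, ]
  expect_equal(workforce_summary_range(one, "community_health_worker"),
               c(min = 7.8, max = 7.8))
  expect_error(workforce_summary_range(fte, "doctor"),
               class = "pc_validation_error")
})

test_that("workforce estimates are linear in patient counts and sum over levels", {
  sc <- tiny_scenario(91)
  wf <- workforce_estimate(sc)
  by_level <- stats::aggregate(fte ~ country + staff_category,
                               wf$fte_by_level, sum)
  merged <- merge(by_level, wf$fte, by = c("country", "staff_category"))
  expect_rel_equal(merged$fte, merged$total_fte)

  sck <- sc
  sck$caseload$decedent_deaths <- sck$caseload$decedent_deaths * 4
  sck$caseload$nondecedent_cases <- sck$caseload$nondecedent_cases * 4
  wfk <- workforce_estimate(sck)
  expect_rel_equal(wfk$fte$total_fte, 4 * wf$fte$total_fte)
  expect_rel_equal(wfk$fte$fte_per_100k, 4 * wf$fte$fte_per_100k)
})
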