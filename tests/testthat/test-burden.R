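# Worked single-number checks use the framework's stated cancer-pain cell:
# 100 decedents x prevalence 0.80 x 90 days = 7,200 symptom-days.

coef1 <- tibble::tibble(condition = "MAL", symptom = "pain",
                        status = "decedent", prevalence = 0.8,
                        duration_days = 90, source = "assumed")
coef2 <- rbind(coef1, tibble::tibble(
  condition = "MAL", symptom = "dyspnea", status = "decedent",
  prevalence = 0.5, duration_days = 60, source = "assumed"))

need100 <- function() {
  sc <- hand_scenario(deaths = 125, cases = 0, dec_frac = 0.8,
                      nondec_frac = 0, coef_rows = coef2)
  estimate_need(sc) # 125 x 0.8 = 100 decedents in need
}

test_that("the at-most bound adds every symptom's prevalence-weighted days", {
  need <- need100()
  upper <- at_most_days(need, coef1)
  expect_equal(upper$totals$at_most_days, 7200)

  upper2 <- at_most_days(need, coef2)
  expect_equal(upper2$totals$at_most_days, 7200 + 100 * 0.5 * 60) # 10,200
  expect_equal(sum(upper2$per_symptom$days), upper2$totals$at_most_days)

  zero <- need
  zero$decedents_in_need <- 0
  expect_equal(at_most_days(zero, coef2,
                            require_coverage = FALSE)$totals$at_most_days, 0)
})

test_that("the at-least bound keeps only the longest-duration symptom", {
  need <- need100()
  # the 90-day symptom wins over a 60-day symptom of higher prevalence
  coefs <- rbind(coef1, tibble::tibble(
    condition = "MAL", symptom = "dyspnea", status = "decedent",
    prevalence = 1.0, duration_days = 60, source = "assumed"))
  expect_equal(at_least_days(need, coefs)$at_least_days, 7200)

  # a single-symptom condition makes the bounds coincide
  b <- symptom_burden(need, coef1)
  expect_equal(b$totals$at_least_days, b$totals$at_most_days)

  # unit weighting drops the prevalence factor
  expect_equal(at_least_days(need, coef1, weighting = "unit")$at_least_days,
               100 * 90)

  # a condition with no symptom rows contributes nothing when coverage is
  # not enforced, and errors when it is
  none <- coef1[0, ]
  expect_equal(at_least_days(need, none,
                             require_coverage = FALSE)$at_least_days, 0)
  err <- expect_error(at_least_days(need, none),
                      class = "pc_validation_error")
  expect_match(conditionMessage(err), "MAL")

  # duration ties break toward higher prevalence, then symptom label
  tie <- rbind(coef1, tibble::tibble(
    condition = "MAL", symptom = "fatigue", status = "decedent",
    prevalence = 0.9, duration_days = 90, source = "assumed"))
  expect_equal(at_least_days(need100(), tie)$at_least_days, 100 * 0.9 * 90)
})

test_that("bounds and per-symptom days match the brute-force oracle", {
  for (seed in c(41, 42, 43)) {
    sc <- tiny_scenario(seed)
    need <- estimate_need(sc)
    b <- symptom_burden(need, sc$symptom_coefficients)
    o <- oracle_burden(as.data.frame(need),
                       as.data.frame(sc$symptom_coefficients))
    expect_rel_equal(b$totals$at_most_days, o$at_most[b$totals$country])
    expect_rel_equal(b$totals$at_least_days, o$at_least[b$totals$country])
    expect_true(all(b$totals$at_least_days <= b$totals$at_most_days + 1e-9))
    keys <- paste(b$per_symptom$country, b$per_symptom$symptom, sep = "\r")
    expect_rel_equal(b$per_symptom$days, unlist(o$per_symptom[keys]))

    bu <- symptom_burden(need, sc$symptom_coefficients, weighting = "unit")
    ou <- oracle_burden(as.data.frame(need),
                        as.data.frame(sc$symptom_coefficients),
                        weighting = "unit")
    expect_rel_equal(bu$totals$at_least_days, ou$at_least[bu$totals$country])
  }
})

test_that("symptom shares sum to 100 and dominant symptoms dominate", {
  sc <- make_scenario(generator_spec(17))
  burden <- symptom_burden(estimate_need(sc), sc$symptom_coefficients)
  shares <- symptom_shares(burden)
  sums <- tapply(shares$share, shares$country, sum)
  expect_true(all(abs(sums - 100) <= 1e-9))

  # under the default coefficients, pain + fatigue + weakness carry more
  # than half of all symptom-days in every country
  big3 <- shares[shares$symptom %in% c("pain", "fatigue", "weakness"), ]
  combined <- tapply(big3$share, big3$country, sum)
  expect_true(all(combined > 50))

  # one symptom only -> 100%
  one <- symptom_shares(symptom_burden(need100(), coef1))
  expect_equal(one$share, 100)

  zero <- need100()
  zero$decedents_in_need <- 0
  expect_error(
    symptom_shares(symptom_burden(zero, coef1, require_coverage = FALSE)),
    class = "pc_zero_burden_error")
})

test_that("burden is linear in the number of people in need", {
  sc <- tiny_scenario(55)
  need <- estimate_need(sc)
  b <- symptom_burden(need, sc$symptom_coefficients)
  needk <- need
  needk$decedents_in_need <- needk$decedents_in_need * 2.5
  needk$nondecedents_in_need <- needk$nondecedents_in_need * 2.5
  bk <- symptom_burden(needk, sc$symptom_coefficients)
  expect_rel_equal(bk$totals$at_most_days, 2.5 * b$totals$at_most_days)
  expect_rel_equal(bk$totals$at_least_days, 2.5 * b$totals$at_least_days)
})
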