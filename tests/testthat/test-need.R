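test_that("need is the product of counts and need fractions", {
  sc <- hand_scenario(deaths = 1000, cases = 500,
                      dec_frac = 0.8, nondec_frac = 0.3,
                      coef_rows = make_default_coefficients()[
                        make_default_coefficients()$condition == "MAL", ])
  need <- estimate_need(sc)
  expect_equal(need$decedents_in_need, 800)
  expect_equal(need$nondecedents_in_need, 150)

  zero <- hand_scenario(deaths = 1000, cases = 500,
                        dec_frac = 0, nondec_frac = 0)
  expect_true(all(estimate_need(zero)$decedents_in_need == 0))
  expect_true(all(estimate_need(zero)$nondecedents_in_need == 0))
})

test_that("need matches the brute-force oracle on random scenarios", {
  for (seed in c(11, 12, 13)) {
    sc <- tiny_scenario(seed)
    need <- estimate_need(sc)
    oracle <- oracle_need(sc$caseload, sc$conditions)
    merged <- merge(as.data.frame(need), oracle,
                    by = c("country", "condition"))
    expect_rel_equal(merged$decedents_in_need.x, merged$decedents_in_need.y)
    expect_rel_equal(merged$nondecedents_in_need.x,
                     merged$nondecedents_in_need.y)
    tot <- need_totals(need)
    expect_rel_equal(tot$grand_total,
                     tot$decedent_total + tot$nondecedent_total)
  }
})

test_that("condition shares normalise to 100 and fail on zero need", {
  sc <- tiny_scenario(21)
  shares <- condition_shares(estimate_need(sc))
  sums <- tapply(shares$share, shares$country, sum)
  expect_true(all(abs(sums - 100) <= 1e-9))

  one <- hand_scenario(deaths = 10, cases = 0, dec_frac = 1, nondec_frac = 0)
  s <- condition_shares(estimate_need(one))
  expect_equal(s$share, 100)

  zero <- hand_scenario(deaths = 0, cases = 0)
  expect_error(condition_shares(estimate_need(zero)),
               class = "pc_zero_need_error")
})

test_that("regional totals aggregate associatively and commute", {
  sc <- make_scenario(generator_spec(9))
  need <- estimate_need(sc)
  total <- regional_totals(need)

  # one country is the identity
  one <- need[need$country == need$country[1], ]
  r1 <- regional_totals(one)
  expect_equal(r1$totals$grand_total, sum(one$decedents_in_need) +
                 sum(one$nondecedents_in_need))

  # permuting countries changes nothing
  perm <- need[sample(nrow(need)), ]
  class(perm) <- class(need)
  r2 <- regional_totals(perm)
  expect_equal(dplyr::arrange(r2$per_condition, condition),
               dplyr::arrange(total$per_condition, condition))

  # region equals the total of income-group subtotals
  groups <- split(sc$countries$country[sc$countries$data_available],
                  sc$countries$income_group[sc$countries$data_available])
  sub <- lapply(groups, function(cs) {
    regional_totals(need[need$country %in% cs, ])$totals
  })
  expect_rel_equal(Reduce(`+`, lapply(sub, function(t) t$grand_total)),
                   total$totals$grand_total)

  expect_error(regional_totals(need[0, ]), class = "pc_validation_error")
})

test_that("need is linear and monotone in the caseload", {
  sc <- tiny_scenario(31)
  need <- estimate_need(sc)
  sck <- sc
  sck$caseload$decedent_deaths <- sck$caseload$decedent_deaths * 3
  sck$caseload$nondecedent_cases <- sck$caseload$nondecedent_cases * 3
  needk <- estimate_need(sck)
  expect_rel_equal(needk$decedents_in_need, 3 * need$decedents_in_need)
  expect_rel_equal(needk$nondecedents_in_need, 3 * need$nondecedents_in_need)

  bump <- sc
  bump$caseload$decedent_deaths[1] <- bump$caseload$decedent_deaths[1] + 100
  expect_true(all(estimate_need(bump)$decedents_in_need >=
                    need$decedents_in_need))
})

test_that("countries without data are excluded, never imputed", {
  sc <- make_scenario(small_spec(6, include_no_data_country = TRUE))
  nodata <- sc$countries$country[!sc$countries$data_available]
  expect_error(estimate_need(sc, countries = nodata),
               class = "pc_no_data_error")
  expect_false(nodata %in% estimate_need(sc)$country)
  expect_error(estimate_need(sc, countries = "Narnia"),
               class = "pc_validation_error")
})
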