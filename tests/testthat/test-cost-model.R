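test_that("years of life lost is the exact decimal difference", {
  expect_identical(years_of_life_lost(61.2, 6), 55.2)
  expect_identical(years_of_life_lost(62.0, 6), 56)
  expect_identical(years_of_life_lost(70, 70), 0)
  expect_error(years_of_life_lost(60, 61), class = "nomacost_validation_error")
})

test_that("cost lines are exact count-times-unit products", {
  expect_equal(cost_line("treatment", 9561, 345)$total_usd, 3298545)
  expect_equal(cost_line("accommodation", 5737, 765)$total_usd, 4388805)
  expect_equal(cost_line("care_abroad", 0, 85000)$total_usd, 0)
  expect_equal(cost_line("x", 9561, 345)$value_source, "computed")
})

test_that("the direct ledger honours overrides and sums exactly", {
  bf <- noma_example_config("burkina_faso_2018")
  cascade <- run_cascade(as_country_profile(bf), as_epi_params(bf), bf$cost_schedule)

  with_override <- direct_ledger(cascade, bf$cost_schedule, bf$overrides)
  expect_equal(direct_total(with_override), 28179901)
  ia <- with_override[with_override$component_id == "income_assistance", ]
  expect_equal(ia$total_usd, 1406398)
  expect_equal(ia$computed_total_usd, 1405565)
  expect_equal(ia$value_source, "printed_override")

  no_override <- direct_ledger(cascade, bf$cost_schedule)
  expect_equal(no_override$total_usd[no_override$component_id == "income_assistance"], 1405565)
  expect_equal(direct_total(no_override), 28179068)
  expect_true(all(no_override$value_source == "computed"))

  expect_error(direct_ledger(cascade, bf$cost_schedule, c(bogus = 1)),
               class = "nomacost_config_error")

  empty <- cost_schedule(tibble::tibble(
    id = character(), label = character(), category = character(),
    count_base = character(), eligibility = character()
  ))
  expect_equal(direct_total(direct_ledger(cascade, empty)), 0)
})

test_that("indirect cost formulas reproduce the published totals", {
  expect_equal(lost_production_cost(25870, 750), 19402500)
  expect_equal(lost_production_cost(28581, 570), 16291170)
  expect_equal(lost_production_cost(1000, 0), 0)
  expect_equal(premature_death_cost(86049, 750, 55.2), 3562428600)
  expect_equal(premature_death_cost(95272, 570, 56), 3041082240)
  expect_equal(premature_death_cost(0, 750, 55.2), 0)
  expect_equal(marriage_cost(14820, 1000), 14820000)
  expect_equal(marriage_cost(13356, 1000), 13356000)
  expect_equal(marriage_cost(0, 1000), 0)
})

test_that("the discounted human-capital extension collapses to the undiscounted cost", {
  expect_identical(discounted_human_capital(86049, 750, 55.2, 0, 1),
                   premature_death_cost(86049, 750, 55.2))
  expect_equal(round(discounted_human_capital(1, 100, 2, 0.5, 1), 2), 111.11)
  expect_equal(discounted_human_capital(0, 100, 10, 0.03, 1), 0)
  withr::with_seed(31, {
    for (i in 1:100) {
      deaths <- sample(0:1e5, 1)
      income <- sample(0:2000, 1)
      yll <- round(runif(1, 0, 60), 1)
      expect_identical(discounted_human_capital(deaths, income, yll, 0, 1),
                       premature_death_cost(deaths, income, yll))
    }
  })
})

test_that("premature-death cost matches per-person per-year brute force on small instances", {
  withr::with_seed(41, {
    for (i in 1:25) {
      deaths <- sample(0:20, 1)
      income <- sample(1:500, 1)
      yll <- round(runif(1, 0, 10.5), 1)
      expect_equal(premature_death_cost(deaths, income, yll),
                   oracle_human_capital(deaths, income, yll))
    }
  })
})

test_that("every cost operation is homogeneous of degree one in its count", {
  withr::with_seed(51, {
    for (i in 1:50) {
      n <- sample(0:1e5, 1)
      income <- sample(0:2000, 1)
      unit <- sample(0:90000, 1)
      yll <- round(runif(1, 0, 60), 1)
      expect_identical(cost_line("x", 2 * n, unit)$total_usd,
                       2 * cost_line("x", n, unit)$total_usd)
      expect_identical(lost_production_cost(2 * n, income), 2 * lost_production_cost(n, income))
      expect_identical(premature_death_cost(2 * n, income, yll),
                       2 * premature_death_cost(n, income, yll))
      expect_identical(marriage_cost(2 * n, unit), 2 * marriage_cost(n, unit))
    }
  })
})

test_that("ledger totals are invariant under permutation of lines", {
  bf <- noma_example_config("burkina_faso_2018")
  cascade <- run_cascade(as_country_profile(bf), as_epi_params(bf), bf$cost_schedule)
  lines <- direct_ledger(cascade, bf$cost_schedule, bf$overrides)
  withr::with_seed(61, {
    for (i in 1:20) {
      expect_identical(direct_total(lines[sample(nrow(lines)), ]), 28179901)
    }
  })
})

test_that("reports carry the published headline values and the intangible marker", {
  bf <- build_report(noma_example_config("burkina_faso_2018"))
  expect_equal(report_target(bf, "premature_death"), 3562428600)
  expect_equal(report_target(bf, "lost_production"), 19402500)
  expect_equal(bf$yll, 55.2)
  expect_identical(bf$intangible, "not computed")
  row <- tidy(bf)
  expect_true(is.na(row$total_usd[row$category == "intangible"]))
  expect_equal(row$value_source[row$category == "intangible"], "not_computed")

  ne <- build_report(noma_example_config("niger_2018"))
  printed <- c(treatment = 3651825, surgery = 2548800, accommodation = 4874580,
               psychological = 414180, physiotherapy = 1618488,
               income_assistance = 1561140, schooling = 379050, care_abroad = 15725000)
  for (id in names(printed)) {
    expect_equal(report_target(ne, paste0("line:", id)), unname(printed[[id]]))
  }

  zero_profile <- country_profile("Nowhere", 2018, 0, population_at_risk = 0,
                                  population_working_age = 0,
                                  female_population_marriageable = 0,
                                  life_expectancy_at_birth = 60, mean_annual_income = 0)
  zero_cascade <- run_cascade(zero_profile, epi_params(0.0064, 0.1, 0.9, 6),
                              fractional_schedule())
  expect_true(all(zero_cascade$count == 0))
})
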