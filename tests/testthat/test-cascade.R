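test_that("cascade stages reproduce the published counts with the floor rule", {
  expect_identical(potential_cases(14939063, 0.0064), 95610)
  expect_identical(potential_cases(16540452, 0.0064), 105858) # 105,858.89 floors
  expect_identical(potential_cases(0, 0.0064), 0)
  expect_identical(treated_cases(95610, 0.10), 9561)
  expect_identical(treated_cases(105858, 0.10), 10585) # 10,585.8 floors
  expect_identical(treated_cases(12345, 0), 0)
  expect_identical(untreated_deaths(95610, 0.90), 86049)
  expect_identical(untreated_deaths(105858, 0.90), 95272)
  expect_identical(untreated_deaths(10, 0.90), 9)
  expect_identical(cohort_cases(2086964, 0.0064), 13356)
  expect_identical(cohort_cases(4042188, 0.0064), 25870) # exact 25,870.0032
  expect_identical(cohort_cases(0, 0.5), 0)
})

test_that("sub-cohort eligibility rules resolve counts and bound absolutes", {
  expect_identical(sub_cohort(9561, "absolute", 5737), 5737)
  expect_identical(sub_cohort(9561, "fraction", 1), 9561)
  expect_identical(sub_cohort(10585, "fraction", 0.60), 6351)
  expect_identical(sub_cohort(9561, "all"), 9561)
  expect_error(sub_cohort(100, "absolute", 101), class = "nomacost_validation_error")
})

test_that("the full cascade reproduces both country tables", {
  bf <- noma_example_config("burkina_faso_2018")
  cascade <- run_cascade(as_country_profile(bf), as_epi_params(bf), bf$cost_schedule)
  counts <- setNames(cascade$count, cascade$cohort)
  expect_identical(counts[["potential_cases"]], 95610)
  expect_identical(counts[["treated_cases"]], 9561)
  expect_identical(counts[["untreated_deaths"]], 86049)
  expect_identical(counts[["working_age_cases"]], 25870)
  expect_identical(counts[["female_marriageable_cases"]], 13356)
  expect_identical(counts[["surgery"]], 5737)
  expect_identical(counts[["schooling"]], 1950)
  expect_identical(counts[["care_abroad"]], 172)

  ne <- noma_example_config("niger_2018")
  cascade <- run_cascade(as_country_profile(ne), as_epi_params(ne), ne$cost_schedule)
  counts <- setNames(cascade$count, cascade$cohort)
  expect_identical(counts[["potential_cases"]], 105858)
  expect_identical(counts[["treated_cases"]], 10585)
  expect_identical(counts[["untreated_deaths"]], 95272)
  expect_identical(counts[["working_age_cases"]], 28581)
  expect_identical(counts[["female_marriageable_cases"]], 14820)
})

test_that("a zero-population profile yields an all-zero cascade", {
  profile <- country_profile("Nowhere", 2018, 0, population_at_risk = 0,
                             population_working_age = 0,
                             female_population_marriageable = 0,
                             life_expectancy_at_birth = 60, mean_annual_income = 100)
  params <- epi_params(0.0064, 0.10, 0.90, 6)
  cascade <- run_cascade(profile, params, fractional_schedule())
  expect_true(all(cascade$count == 0))
})

test_that("cascade counts are monotone in population and incidence", {
  withr::with_seed(21, {
    for (i in 1:50) {
      pop <- sample(0:5e6, 2)
      rate <- sort(round(runif(2, 0, 0.05), 5))
      lo_pop <- min(pop); hi_pop <- max(pop)
      expect_lte(potential_cases(lo_pop, rate[1]), potential_cases(hi_pop, rate[1]))
      expect_lte(potential_cases(hi_pop, rate[1]), potential_cases(hi_pop, rate[2]))
      # composition: treated cases never exceed potential cases
      pot <- potential_cases(hi_pop, rate[2])
      expect_lte(treated_cases(pot, round(runif(1), 3)), pot)
    }
  })
})
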