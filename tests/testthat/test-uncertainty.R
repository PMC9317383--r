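bf_config <- noma_example_config("burkina_faso_2018")

test_that("one-way analysis recomputes the target at each parameter bound", {
  sens <- one_way(
    bf_config,
    distributions = param_dist("epidemiology.care_fraction", "uniform", 0.10, 0.15),
    target = "line:treatment"
  )
  expect_equal(sens$baseline, 3298545) # 9561 * 345
  expect_equal(sens$tornado$output_lo, 3298545)
  expect_equal(sens$tornado$output_hi, 4947645) # floor(95,610 * 0.15) = 14,341 cases
  expect_equal(sens$tornado$swing, 1649100)
})

test_that("a degenerate interval produces zero swing and ranking is by width", {
  sens <- one_way(
    bf_config,
    distributions = dplyr::bind_rows(
      param_dist("epidemiology.incidence_rate", "uniform", 0.0064, 0.0064),
      param_dist("epidemiology.care_fraction", "uniform", 0.10, 0.15)
    ),
    target = "direct_total"
  )
  inc <- sens$tornado[sens$tornado$parameter_path == "epidemiology.incidence_rate", ]
  expect_equal(inc$swing, 0)
  expect_equal(sens$tornado$parameter_path[1], "epidemiology.care_fraction")
  expect_true(all(diff(sens$tornado$swing) <= 0))
})

test_that("an empty distribution list yields only the baseline", {
  empty <- param_dist("epidemiology.care_fraction", "uniform", 0.1, 0.15)[0, ]
  sens <- one_way(bf_config, distributions = empty, target = "grand_total")
  expect_equal(nrow(sens$tornado), 0)
  expect_equal(sens$baseline, report_target(build_report(bf_config), "grand_total"))
})

test_that("point-mass distributions make every replicate equal the baseline", {
  dists <- dplyr::bind_rows(
    param_dist("epidemiology.incidence_rate", "point", mode = 0.0064),
    param_dist("epidemiology.care_fraction", "point", mode = 0.10)
  )
  mc <- monte_carlo(bf_config, dists, target = "grand_total",
                    replicates = 20, seed = 99)
  expect_true(all(mc$samples$value == mc$baseline))
})

test_that("Monte-Carlo runs are bit-identical under a fixed seed", {
  a <- monte_carlo(bf_config, replicates = 30, seed = 123, target = "grand_total")
  b <- monte_carlo(bf_config, replicates = 30, seed = 123, target = "grand_total")
  expect_identical(a$samples, b$samples)
  expect_identical(a$percentiles, b$percentiles)
  c <- monte_carlo(bf_config, replicates = 30, seed = 124, target = "grand_total")
  expect_false(identical(a$samples$value, c$samples$value))
})

test_that("the baseline lies inside the sampled envelope and medians are coherent", {
  dists <- param_dist("epidemiology.incidence_rate", "uniform", 0.005, 0.008)
  mc <- monte_carlo(bf_config, dists, target = "potential_cases",
                    replicates = 60, seed = 5)
  expect_gte(mc$baseline, min(mc$samples$value))
  expect_lte(mc$baseline, max(mc$samples$value))
  expect_gte(mc$percentiles[["50%"]], min(mc$samples$value))
  expect_lte(mc$percentiles[["50%"]], max(mc$samples$value))
})

test_that("sampled potential cases match the closed-form uniform mean", {
  lo <- 0.005; hi <- 0.008
  at_risk <- bf_config$demography$population_at_risk
  mc <- monte_carlo(bf_config,
                    param_dist("epidemiology.incidence_rate", "uniform", lo, hi),
                    target = "potential_cases", replicates = 200, seed = 17)
  expected <- at_risk * (lo + hi) / 2
  se <- at_risk * (hi - lo) / sqrt(12) / sqrt(200)
  expect_lt(abs(mean(mc$samples$value) - expected), 3 * se + 1) # +1 floor bias
})

test_that("parameter paths that do not resolve raise configuration errors", {
  expect_error(
    one_way(bf_config, param_dist("epidemiology.bogus", "uniform", 0, 1)),
    class = "nomacost_config_error"
  )
  expect_error(get_config_value(bf_config, "cost_schedule.nope.unit_cost_usd"),
               class = "nomacost_config_error")
  expect_equal(get_config_value(bf_config, "cost_schedule.treatment.unit_cost_usd"), 345)
})
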