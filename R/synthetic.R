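# Synthetic country profiles with known ground truth.
#
# The generator emulates the statistical shape of the real inputs — an age
# structure expressed as shares of the total (which is all the model
# consumes), a mean income, a life expectancy, a short unit-cost schedule —
# so every pipeline stage can be exercised, and verified against closed-form
# expectations, without any real-world data.

#' Specification for a synthetic country profile
#'
#' @param seed Integer seed; the generated profile is deterministic given
#'   the seed.
#' @param total_population Total population (persons).
#' @param at_risk_share Share of the total population in the at-risk age
#'   range (0-29).
#' @param working_age_share_of_risk Share of the at-risk population of
#'   working age (15-29).
#' @param female_share_of_working_age Female share of the working-age
#'   population.
#' @param income_range Mean annual income interval, USD (integer draws).
#' @param life_expectancy_range Life expectancy interval, years (one
#'   decimal).
#' @param incidence_range Annual incidence interval, per person-year.
#' @param care_fraction_range Care-seeking fraction interval.
#' @param mortality_range Untreated-mortality interval.
#' @param n_direct_components Direct cost components to generate (>= 1; the
#'   first covers all treated cases, the rest fractional sub-cohorts).
#' @param unit_cost_range Unit-cost interval, USD (integer draws).
#' @param dowry_range Dowry cost interval, USD (integer draws).
#' @return A `noma_synth_spec` object. Shares are carried at 8 decimal
#'   digits so derived populations are exact floors of share products.
#' @export
synthetic_spec <- function(seed,
                           total_population = 2e7,
                           at_risk_share = 0.72,
                           working_age_share_of_risk = 0.27,
                           female_share_of_working_age = 0.5,
                           income_range = c(300, 1500),
                           life_expectancy_range = c(50, 70),
                           incidence_range = c(0.001, 0.01),
                           care_fraction_range = c(0.05, 0.20),
                           mortality_range = c(0.70, 0.95),
                           n_direct_components = 5,
                           unit_cost_range = c(25, 1000),
                           dowry_range = c(500, 2000)) {
  check_count(seed, "seed")
  check_count(total_population, "total_population")
  for (nm in c("at_risk_share", "working_age_share_of_risk", "female_share_of_working_age")) {
    check_proportion(get(nm), nm)
  }
  check_count(n_direct_components, "n_direct_components")
  if (n_direct_components < 1) abort_validation("`n_direct_components` must be at least 1.")
  for (nm in c("income_range", "life_expectancy_range", "incidence_range",
               "care_fraction_range", "mortality_range", "unit_cost_range", "dowry_range")) {
    rg <- get(nm)
    if (length(rg) != 2L || rg[[1]] > rg[[2]] || any(rg < 0)) {
      abort_validation(sprintf("`%s` must be an ordered non-negative interval.", nm))
    }
  }
  structure(
    list(
      seed = seed, total_population = total_population,
      at_risk_share = round(at_risk_share, 8),
      working_age_share_of_risk = round(working_age_share_of_risk, 8),
      female_share_of_working_age = round(female_share_of_working_age, 8),
      income_range = income_range, life_expectancy_range = life_expectancy_range,
      incidence_range = incidence_range, care_fraction_range = care_fraction_range,
      mortality_range = mortality_range,
      n_direct_components = n_direct_components,
      unit_cost_range = unit_cost_range, dowry_range = dowry_range
    ),
    class = "noma_synth_spec"
  )
}

runif_decimal <- function(n, range, digits) round(runif(n, range[[1]], range[[2]]), digits)
runif_int <- function(n, range) floor(runif(n, range[[1]], range[[2]] + 1))

#' Generate a synthetic country configuration
#'
#' Deterministic given the spec's seed. The returned configuration passes
#' every profile invariant by construction (working-age population is a
#' floored share of the at-risk population, which is a floored share of the
#' total), and the drawn ground-truth parameters are attached as the
#' `"ground_truth"` attribute.
#'
#' @param spec A [synthetic_spec()].
#' @return A `noma_config`, with the generating spec and drawn parameters
#'   in `attr(, "ground_truth")`.
#' @examples
#' cfg <- generate_profile(synthetic_spec(seed = 42))
#' all(recovery_check(cfg)$pass)
#' @export
generate_profile <- function(spec) {
  stopifnot(inherits(spec, "noma_synth_spec"))
  withr::with_seed(spec$seed, {
    at_risk <- floor_count(spec$total_population, spec$at_risk_share)
    working <- floor_count(at_risk, spec$working_age_share_of_risk)
    female <- floor_count(working, spec$female_share_of_working_age)
    income <- runif_int(1, spec$income_range)
    life_exp <- runif_decimal(1, spec$life_expectancy_range, 1)
    incidence <- runif_decimal(1, spec$incidence_range, 6)
    care <- runif_decimal(1, spec$care_fraction_range, 4)
    mortality <- runif_decimal(1, spec$mortality_range, 4)
    mean_age_at_death <- runif_decimal(1, c(3, 10), 1)
    dowry <- runif_int(1, spec$dowry_range)

    n_extra <- spec$n_direct_components - 1L
    fractions <- runif_decimal(n_extra, c(0.05, 0.9), 4)
    unit_costs <- runif_int(spec$n_direct_components, spec$unit_cost_range)
    direct <- bind_rows(
      tibble(id = "treatment", label = "Costs of treatment", category = "direct",
             count_base = "treated", eligibility = "all",
             eligibility_value = NA_real_, unit_cost_usd = unit_costs[[1]]),
      if (n_extra > 0) {
        tibble(
          id = sprintf("component_%02d", seq_len(n_extra)),
          label = sprintf("Synthetic direct component %d", seq_len(n_extra)),
          category = "direct", count_base = "treated", eligibility = "fraction",
          eligibility_value = fractions, unit_cost_usd = unit_costs[-1]
        )
      }
    )
    indirect <- tibble(
      id = c("lost_production", "premature_death", "inability_to_marry"),
      label = c("Costs of loss of production", "Costs related to premature death",
                "Costs of inability to marry"),
      category = "indirect",
      count_base = c("working_age", "deaths", "female_marriageable"),
      eligibility = "all", eligibility_value = NA_real_,
      unit_source = c("mean_annual_income", "income_times_yll", "config"),
      unit_cost_usd = c(NA_real_, NA_real_, dowry)
    )

    raw <- list(
      schema_version = CONFIG_SCHEMA_VERSION,
      country = sprintf("Synthetica (seed %d)", spec$seed),
      year = 2018,
      demography = list(
        total_population = spec$total_population,
        population_at_risk = at_risk,
        population_working_age = working,
        female_population_marriageable = female,
        life_expectancy_at_birth = life_exp,
        note = "synthetic profile with known ground truth"
      ),
      economy = list(mean_annual_income = income, currency_label = "USD"),
      epidemiology = list(
        incidence_rate = incidence, care_fraction = care,
        untreated_mortality = mortality, mean_age_at_death = mean_age_at_death,
        at_risk_age_range = c(0, 29), working_age_range = c(15, 29),
        marriageable_age_range = c(15, 29)
      ),
      cost_schedule = purrr::transpose(as.list(bind_rows(direct, indirect)))
    )
    config <- as_noma_config(raw, source = sprintf("synthetic:seed=%d", spec$seed))
    attr(config, "ground_truth") <- list(
      spec = spec, population_at_risk = at_risk,
      population_working_age = working, female_population_marriageable = female,
      mean_annual_income = income, life_expectancy_at_birth = life_exp,
      incidence_rate = incidence, care_fraction = care,
      untreated_mortality = mortality, mean_age_at_death = mean_age_at_death,
      dowry_cost = dowry
    )
    config
  })
}

# independent floor oracle: modulus route rather than the division-repair
# route used by floor_count()
oracle_floor <- function(base, rate, digits = 8L) {
  num <- round(rate * 10^digits)
  den <- 10^digits
  stopifnot(num / den == rate, base * num <= MAX_EXACT)
  p <- base * num
  (p - p %% den) / den
}

#' Verify a generated instance against closed-form ground truth
#'
#' Runs the full model on a synthetic configuration and checks every
#' output — cascade counts, each cost line, the ledger total, the three
#' indirect costs — against an expectation computed independently from the
#' recorded ground truth (floored share chains and exact products via a
#' separate modular-arithmetic floor). Agreement is required to be exact;
#' no tolerance.
#'
#' @param config A configuration from [generate_profile()].
#' @return A tibble with columns `quantity`, `expected`, `actual`, `pass`.
#' @export
recovery_check <- function(config) {
  truth <- attr(config, "ground_truth")
  if (is.null(truth)) abort_config("`config` carries no ground truth; generate it with generate_profile().")
  report <- build_report(config)

  pot <- oracle_floor(truth$population_at_risk, truth$incidence_rate)
  treat <- oracle_floor(pot, truth$care_fraction)
  dead <- oracle_floor(pot, truth$untreated_mortality)
  work <- oracle_floor(truth$population_working_age, truth$incidence_rate)
  fem <- oracle_floor(truth$female_population_marriageable, truth$incidence_rate)
  yll10 <- round(truth$life_expectancy_at_birth * 10) - round(truth$mean_age_at_death * 10)

  sched <- config$cost_schedule
  direct <- sched[sched$category == "direct", ]
  counts <- map_dbl(seq_len(nrow(direct)), function(i) {
    if (direct$eligibility[[i]] == "all") treat else oracle_floor(treat, direct$eligibility_value[[i]])
  })
  line_totals <- counts * direct$unit_cost_usd

  checks <- tibble(
    quantity = c("potential_cases", "treated_cases", "untreated_deaths",
                 "working_age_cases", "female_marriageable_cases",
                 paste0("count:", direct$id), paste0("line:", direct$id),
                 "direct_total", "lost_production", "premature_death",
                 "inability_to_marry"),
    expected = c(pot, treat, dead, work, fem, counts, line_totals,
                 sum(line_totals),
                 work * truth$mean_annual_income,
                 dead * truth$mean_annual_income * yll10 / 10,
                 fem * truth$dowry_cost)
  )
  checks$actual <- map_dbl(checks$quantity, function(q) {
    if (startsWith(q, "count:")) {
      cascade_count(report$cascade, sub("^count:", "", q))
    } else {
      report_target(report, q)
    }
  })
  mutate(checks, pass = .data$expected == .data$actual)
}
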