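# The prevalence cascade: population at risk -> potential cases -> cases
# receiving care / untreated deaths, plus the cohorts the cost ledger needs.
#
# The rounding convention at every stage is FLOOR, applied through exact
# integer-ratio arithmetic (see arithmetic.R).  The convention is pinned by
# the published Niger counts: 16,540,452 * 0.0064 = 105,858.89 prints as
# 105,858 and 105,858 * 0.10 = 10,585.8 prints as 10,585; nearest rounding
# would give 105,859 and 10,586.

#' Potential annual cases from the population at risk
#'
#' @param population_at_risk Persons in the at-risk age range.
#' @param incidence_rate Annual incidence, cases per person per year.
#' @return `floor(population_at_risk * incidence_rate)`, exactly.
#' @examples
#' potential_cases(14939063, 0.0064) # 95,610
#' @export
potential_cases <- function(population_at_risk, incidence_rate) {
  check_proportion(incidence_rate, "incidence_rate")
  floor_count(population_at_risk, incidence_rate)
}

#' Cases receiving treatment
#'
#' @param potential Potential case count.
#' @param care_fraction Proportion of potential cases that receive care.
#' @return `floor(potential * care_fraction)`, exactly.
#' @examples
#' treated_cases(95610, 0.10) # 9561
#' @export
treated_cases <- function(potential, care_fraction) {
  check_proportion(care_fraction, "care_fraction")
  floor_count(potential, care_fraction)
}

#' Deaths among cases that go untreated
#'
#' @param potential Potential case count.
#' @param mortality Case-fatality proportion without treatment.
#' @return `floor(potential * mortality)`, exactly.
#' @examples
#' untreated_deaths(95610, 0.90) # 86,049
#' @export
untreated_deaths <- function(potential, mortality) {
  check_proportion(mortality, "mortality")
  floor_count(potential, mortality)
}

#' Potential cases within a demographic sub-population
#'
#' Applies the incidence rate to a profile sub-population (working-age
#' persons, marriageable-age women) to obtain the cohort a cost line is
#' based on.
#'
#' @param subpopulation Persons in the sub-population.
#' @param incidence_rate Annual incidence, cases per person per year.
#' @return `floor(subpopulation * incidence_rate)`, exactly.
#' @examples
#' cohort_cases(2086964, 0.0064) # 13,356 marriageable-age female cases
#' @export
cohort_cases <- function(subpopulation, incidence_rate) {
  check_proportion(incidence_rate, "incidence_rate")
  floor_count(subpopulation, incidence_rate)
}

#' Resolve a cost component's head count from its base cohort
#'
#' @param base Persons in the component's base cohort.
#' @param eligibility `"all"` (the whole base), `"fraction"` (a proportion of
#'   it, floored), or `"absolute"` (a fixed count, which must not exceed the
#'   base).
#' @param value The fraction or absolute count; ignored for `"all"`.
#' @return Persons the component applies to.
#' @examples
#' sub_cohort(9561, "absolute", 5737) # 5737
#' sub_cohort(10585, "fraction", 0.6) # 6351
#' @export
sub_cohort <- function(base, eligibility = c("all", "fraction", "absolute"),
                       value = NA_real_) {
  eligibility <- match.arg(eligibility)
  check_count(base, "base")
  switch(eligibility,
    all = base,
    fraction = {
      check_proportion(value, "value")
      floor_count(base, value)
    },
    absolute = {
      check_count(value, "value")
      if (value > base) {
        abort_validation(sprintf(
          "absolute sub-cohort count %s exceeds its base cohort of %s.",
          format(value, big.mark = ","), format(base, big.mark = ",")
        ))
      }
      value
    }
  )
}

#' Run the full prevalence cascade
#'
#' Composes the cascade stages and resolves the head count of every cost
#' component in the schedule against its declared base cohort.
#'
#' @param profile A [country_profile()].
#' @param params An [epi_params()].
#' @param schedule A [cost_schedule()] tibble (may be empty).
#' @return A tibble with columns `cohort`, `count` and `basis`: the core
#'   cascade rows (`total_population`, `population_at_risk`,
#'   `potential_cases`, `treated_cases`, `untreated_deaths`,
#'   `working_age_cases`, `female_marriageable_cases`) followed by one row
#'   per schedule component (named by its id).
#' @examples
#' cfg <- noma_example_config("burkina_faso_2018")
#' run_cascade(as_country_profile(cfg), as_epi_params(cfg), cfg$cost_schedule)
#' @export
run_cascade <- function(profile, params, schedule = cost_schedule(tibble(
                          id = character(), label = character(),
                          category = character(), count_base = character(),
                          eligibility = character()
                        ))) {
  stopifnot(inherits(profile, "noma_profile"), inherits(params, "noma_epi_params"))
  schedule <- cost_schedule(schedule)

  potential <- potential_cases(profile$population_at_risk, params$incidence_rate)
  treated <- treated_cases(potential, params$care_fraction)
  deaths <- untreated_deaths(potential, params$untreated_mortality)
  working <- cohort_cases(profile$population_working_age, params$incidence_rate)
  female <- cohort_cases(profile$female_population_marriageable, params$incidence_rate)

  core <- tibble(
    cohort = c("total_population", "population_at_risk", "potential_cases",
               "treated_cases", "untreated_deaths", "working_age_cases",
               "female_marriageable_cases"),
    count = c(profile$total_population, profile$population_at_risk, potential,
              treated, deaths, working, female),
    basis = c("profile", "profile", "population_at_risk", "potential_cases",
              "potential_cases", "population_working_age",
              "female_population_marriageable")
  )
  bases <- c(
    treated = treated, potential = potential, deaths = deaths,
    working_age = working, female_marriageable = female,
    at_risk = profile$population_at_risk
  )
  components <- schedule[schedule$category != "intangible", ]
  comp_rows <- pmap(
    components[c("id", "count_base", "eligibility", "eligibility_value")],
    function(id, count_base, eligibility, eligibility_value) {
      tibble(
        cohort = id,
        count = sub_cohort(bases[[count_base]], eligibility, eligibility_value),
        basis = count_base
      )
    }
  )
  bind_rows(core, comp_rows)
}

# count_base name -> cascade cohort row
BASE_COHORT_ROW <- c(
  treated = "treated_cases", potential = "potential_cases",
  deaths = "untreated_deaths", working_age = "working_age_cases",
  female_marriageable = "female_marriageable_cases",
  at_risk = "population_at_risk"
)

# lookup helper shared by the costing code
cascade_count <- function(cascade, cohort) {
  i <- match(cohort, cascade$cohort)
  if (is.na(i)) abort_validation(sprintf("no cascade cohort `%s`.", cohort))
  cascade$count[[i]]
}
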