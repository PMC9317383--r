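# Country profiles: the exogenous demographic and economic inputs.

#' Build a validated country profile
#'
#' A country profile carries every exogenous demographic and economic input
#' the cost model consumes for one country-year: total population, the
#' population at risk of noma (ages 0-29 by default), the working-age subset
#' (15-29), the female marriageable subset (women 15-29), life expectancy at
#' birth and mean annual income.
#'
#' @param name Country name.
#' @param year Calendar year of the snapshot.
#' @param total_population Total population (persons).
#' @param population_at_risk Persons in the at-risk age range. Supply either
#'   this directly or an `age_pyramid` to derive it from (a direct value
#'   takes precedence).
#' @param population_working_age Persons in the working-age range (a subset
#'   of the population at risk).
#' @param female_population_marriageable Women in the marriageable age range
#'   belonging to the population at risk.
#' @param life_expectancy_at_birth Years (decimal).
#' @param mean_annual_income Mean annual income, USD per person per year.
#' @param currency_label Currency of the monetary fields (default `"USD"`).
#' @param age_pyramid Optional [age_pyramid()] tibble; used to derive
#'   `population_at_risk` when that is not given directly.
#' @param at_risk_age_range Inclusive age range used with `age_pyramid`.
#' @return A `noma_profile` object (a named list).
#' @examples
#' country_profile("Burkina Faso", 2018,
#'   total_population = 20244080, population_at_risk = 14939063,
#'   population_working_age = 4042188,
#'   female_population_marriageable = 2086964,
#'   life_expectancy_at_birth = 61.2, mean_annual_income = 750
#' )
#' @export
country_profile <- function(name, year, total_population,
                            population_at_risk = NULL,
                            population_working_age,
                            female_population_marriageable,
                            life_expectancy_at_birth,
                            mean_annual_income,
                            currency_label = "USD",
                            age_pyramid = NULL,
                            at_risk_age_range = c(0, 29)) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    abort_validation("`name` must be a non-empty string.")
  }
  check_count(year, "year")
  check_count(total_population, "total_population")
  if (is.null(population_at_risk)) {
    if (is.null(age_pyramid)) {
      abort_config("supply `population_at_risk` directly or via `age_pyramid`.")
    }
    population_at_risk <- derive_population_at_risk(age_pyramid, at_risk_age_range)
  }
  check_count(population_at_risk, "population_at_risk")
  check_count(population_working_age, "population_working_age")
  check_count(female_population_marriageable, "female_population_marriageable")
  check_scalar_number(life_expectancy_at_birth, "life_expectancy_at_birth")
  if (life_expectancy_at_birth <= 0) {
    abort_validation("`life_expectancy_at_birth` must be positive.")
  }
  check_scalar_number(mean_annual_income, "mean_annual_income", min = 0)
  if (population_at_risk > total_population) {
    abort_validation(sprintf(
      "`population_at_risk` (%s) exceeds `total_population` (%s).",
      format(population_at_risk, big.mark = ","), format(total_population, big.mark = ",")
    ))
  }
  if (population_working_age > population_at_risk) {
    abort_validation("`population_working_age` exceeds `population_at_risk`.")
  }
  if (female_population_marriageable > population_working_age) {
    abort_validation("`female_population_marriageable` exceeds `population_working_age`.")
  }
  structure(
    list(
      name = name, year = year,
      total_population = total_population,
      population_at_risk = population_at_risk,
      population_working_age = population_working_age,
      female_population_marriageable = female_population_marriageable,
      life_expectancy_at_birth = life_expectancy_at_birth,
      mean_annual_income = mean_annual_income,
      currency_label = currency_label,
      age_pyramid = age_pyramid
    ),
    class = "noma_profile"
  )
}

#' @export
print.noma_profile <- function(x, ...) {
  cat(sprintf("<noma_profile> %s (%d)\n", x$name, x$year))
  cat(sprintf("  total population   %15s\n", format(x$total_population, big.mark = ",")))
  cat(sprintf("  population at risk %15s\n", format(x$population_at_risk, big.mark = ",")))
  cat(sprintf("  working age (15-29)%15s\n", format(x$population_working_age, big.mark = ",")))
  cat(sprintf("  women marriageable %15s\n", format(x$female_population_marriageable, big.mark = ",")))
  cat(sprintf("  life expectancy    %15s years\n", format(x$life_expectancy_at_birth)))
  cat(sprintf("  mean annual income %15s %s\n", format(x$mean_annual_income, big.mark = ","), x$currency_label))
  invisible(x)
}

#' Build an age-banded population pyramid
#'
#' @param start_age,end_age Inclusive band endpoints in years.
#' @param count Persons in each band (non-negative integers).
#' @return A tibble with columns `start_age`, `end_age`, `count`, validated:
#'   bands sorted, non-overlapping, counts non-negative integers.
#' @examples
#' age_pyramid(c(0, 15, 30), c(14, 29, 59), c(9e6, 5939063, 5e6))
#' @export
age_pyramid <- function(start_age, end_age, count) {
  bands <- tibble(start_age = start_age, end_age = end_age, count = count)
  if (nrow(bands) == 0L) abort_validation("an age pyramid needs at least one band.")
  if (any(bands$count < 0) || any(bands$count != floor(bands$count))) {
    abort_validation("band counts must be non-negative integers.")
  }
  if (any(bands$end_age < bands$start_age)) {
    abort_validation("each band must have `end_age >= start_age`.")
  }
  bands <- arrange(bands, .data$start_age)
  if (nrow(bands) > 1L && any(bands$start_age[-1] <= bands$end_age[-nrow(bands)])) {
    abort_validation("age bands must not overlap.")
  }
  bands
}

#' Sum pyramid counts over an inclusive age range
#'
#' Returns the persons in bands lying wholly inside `age_range`. The range
#' must align with band boundaries: a range that cuts through a band raises
#' an alignment error rather than interpolating within the band.
#'
#' @param pyramid An [age_pyramid()] tibble.
#' @param age_range Inclusive `c(low, high)` in years; `low > high` denotes
#'   an empty range and returns 0.
#' @return Persons in range.
#' @examples
#' p <- age_pyramid(c(0, 15, 30), c(14, 29, 59), c(9e6, 5939063, 5e6))
#' derive_population_at_risk(p, c(0, 29)) # 14,939,063
#' @export
derive_population_at_risk <- function(pyramid, age_range) {
  pyramid <- age_pyramid(pyramid$start_age, pyramid$end_age, pyramid$count)
  if (length(age_range) != 2L || any(!is.finite(age_range))) {
    abort_validation("`age_range` must be c(low, high).")
  }
  low <- age_range[[1]]; high <- age_range[[2]]
  if (low > high) return(0)
  inside <- pyramid$start_age >= low & pyramid$end_age <= high
  touching <- pyramid$start_age <= high & pyramid$end_age >= low
  if (any(touching & !inside)) {
    bad <- which(touching & !inside)[1]
    abort_alignment(sprintf(
      "age range [%s, %s] cuts through band [%s, %s]; no interpolation is attempted.",
      low, high, pyramid$start_age[bad], pyramid$end_age[bad]
    ))
  }
  sum(pyramid$count[inside])
}

#' Epidemiological parameters of the cascade
#'
#' @param incidence_rate Annual incidence, cases per person per year
#'   (e.g. `0.0064` for 6.4 per 1000).
#' @param care_fraction Proportion of potential cases receiving care.
#' @param untreated_mortality Proportion of potential cases dying without
#'   treatment.
#' @param mean_age_at_death Mean age at death from the disease, years.
#' @param at_risk_age_range,working_age_range,marriageable_age_range
#'   Inclusive age ranges in years.
#' @return A `noma_epi_params` object.
#' @examples
#' epi_params(0.0064, 0.10, 0.90, 6)
#' @export
epi_params <- function(incidence_rate, care_fraction, untreated_mortality,
                       mean_age_at_death,
                       at_risk_age_range = c(0, 29),
                       working_age_range = c(15, 29),
                       marriageable_age_range = c(15, 29)) {
  check_proportion(incidence_rate, "incidence_rate")
  check_proportion(care_fraction, "care_fraction")
  check_proportion(untreated_mortality, "untreated_mortality")
  check_scalar_number(mean_age_at_death, "mean_age_at_death", min = 0)
  for (nm in c("at_risk_age_range", "working_age_range", "marriageable_age_range")) {
    rg <- get(nm)
    if (length(rg) != 2L || rg[[1]] > rg[[2]] || any(rg < 0)) {
      abort_validation(sprintf("`%s` must be an ordered non-negative c(low, high).", nm))
    }
  }
  if (mean_age_at_death >= at_risk_age_range[[2]]) {
    abort_validation("`mean_age_at_death` must lie below the upper at-risk age bound.")
  }
  structure(
    list(
      incidence_rate = incidence_rate,
      care_fraction = care_fraction,
      untreated_mortality = untreated_mortality,
      mean_age_at_death = mean_age_at_death,
      at_risk_age_range = as.numeric(at_risk_age_range),
      working_age_range = as.numeric(working_age_range),
      marriageable_age_range = as.numeric(marriageable_age_range)
    ),
    class = "noma_epi_params"
  )
}

#' @export
print.noma_epi_params <- function(x, ...) {
  cat("<noma_epi_params>\n")
  cat(sprintf("  incidence            %s per person-year\n", format(x$incidence_rate)))
  cat(sprintf("  care fraction        %s\n", format(x$care_fraction)))
  cat(sprintf("  untreated mortality  %s\n", format(x$untreated_mortality)))
  cat(sprintf("  mean age at death    %s years\n", format(x$mean_age_at_death)))
  invisible(x)
}
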