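# The cost model: the direct-cost ledger and the three human-capital
# indirect cost lines (lost production, premature death, inability to marry).

#' Years of life lost to a premature death
#'
#' Life expectancy at birth minus the mean age at death, computed as an
#' exact decimal difference (61.2 - 6 gives exactly 55.2).
#'
#' @param life_expectancy Life expectancy at birth, years.
#' @param mean_age_at_death Mean age at death, years.
#' @return Years of life lost (decimal).
#' @examples
#' years_of_life_lost(61.2, 6) # 55.2
#' @export
years_of_life_lost <- function(life_expectancy, mean_age_at_death) {
  check_scalar_number(life_expectancy, "life_expectancy", min = 0)
  check_scalar_number(mean_age_at_death, "mean_age_at_death", min = 0)
  a <- decimal_to_ratio(life_expectancy, max_digits = 6L)
  b <- decimal_to_ratio(mean_age_at_death, max_digits = 6L)
  den <- max(a$den, b$den)
  num <- a$num * (den / a$den) - b$num * (den / b$den)
  if (num < 0) {
    abort_validation("mean age at death exceeds life expectancy; years of life lost would be negative.")
  }
  num / den
}

#' One computed cost line
#'
#' @param component_id Component identifier.
#' @param count Persons the line applies to.
#' @param unit_cost USD per person (whole dollars in the published schedule).
#' @return A one-row tibble with `total_usd = count * unit_cost` computed
#'   exactly and `value_source = "computed"`.
#' @examples
#' cost_line("treatment", 9561, 345)$total_usd # 3,298,545
#' @export
cost_line <- function(component_id, count, unit_cost) {
  check_count(count, "count")
  check_scalar_number(unit_cost, "unit_cost", min = 0)
  tibble(
    component_id = component_id,
    count = count,
    unit_cost_usd = unit_cost,
    total_usd = exact_product(count, unit_cost),
    computed_total_usd = exact_product(count, unit_cost),
    value_source = "computed"
  )
}

#' Assemble the direct-cost ledger
#'
#' One line per direct component in the schedule, with head counts taken
#' from the cascade. An entry in `overrides` replaces a line's computed
#' total with a published figure and marks the line
#' `value_source = "printed_override"`; the computed value is retained in
#' `computed_total_usd` so validation can report the difference rather than
#' silently choosing.
#'
#' @param cascade A [run_cascade()] tibble.
#' @param schedule A [cost_schedule()] tibble.
#' @param overrides Named numeric vector of published totals keyed by
#'   component id (optional).
#' @return A tibble of direct cost lines.
#' @export
direct_ledger <- function(cascade, schedule, overrides = NULL) {
  schedule <- cost_schedule(schedule)
  direct <- schedule[schedule$category == "direct", ]
  if (!is.null(overrides)) {
    unknown <- setdiff(names(overrides), schedule$id)
    if (length(unknown)) {
      abort_config(sprintf("override(s) for unknown component(s): %s.", paste(unknown, collapse = ", ")))
    }
  }
  lines <- bind_rows(pmap(direct[c("id", "label", "unit_cost_usd")], function(id, label, unit_cost_usd) {
    line <- cost_line(id, cascade_count(cascade, id), unit_cost_usd)
    line$label <- label
    line
  }))
  if (nrow(lines) == 0L) {
    return(tibble(component_id = character(), label = character(), count = numeric(),
                  unit_cost_usd = numeric(), total_usd = numeric(),
                  computed_total_usd = numeric(), value_source = character()))
  }
  for (id in intersect(names(overrides), lines$component_id)) {
    i <- match(id, lines$component_id)
    lines$total_usd[i] <- overrides[[id]]
    lines$value_source[i] <- "printed_override"
  }
  lines[c("component_id", "label", "count", "unit_cost_usd", "total_usd",
          "computed_total_usd", "value_source")]
}

#' Total of a ledger
#'
#' @param lines A ledger tibble from [direct_ledger()].
#' @return The exact sum of `total_usd`.
#' @export
direct_total <- function(lines) {
  sum(lines$total_usd)
}

#' Indirect cost of lost production
#'
#' One year of mean income per potential case of working age (morbidity
#' cost under the human capital approach).
#'
#' @param working_age_cases Potential cases of legal working age.
#' @param mean_annual_income USD per person per year.
#' @return USD, exact.
#' @examples
#' lost_production_cost(25870, 750) # 19,402,500
#' @export
lost_production_cost <- function(working_age_cases, mean_annual_income) {
  check_count(working_age_cases, "working_age_cases")
  check_scalar_number(mean_annual_income, "mean_annual_income", min = 0)
  exact_product(working_age_cases, mean_annual_income)
}

#' Indirect cost of premature deaths (human capital approach)
#'
#' Values each untreated death at the mean annual income over the years of
#' life lost, undiscounted: `deaths * income * yll`, carried out in exact
#' arithmetic (the decimal YLL is rewritten as an integer ratio) so that
#' published whole-dollar totals are matched exactly.
#'
#' @param deaths Untreated deaths.
#' @param mean_annual_income USD per person per year.
#' @param yll Years of life lost per death (decimal).
#' @return USD, exact.
#' @examples
#' premature_death_cost(86049, 750, 55.2) # 3,562,428,600
#' @export
premature_death_cost <- function(deaths, mean_annual_income, yll) {
  check_count(deaths, "deaths")
  check_scalar_number(mean_annual_income, "mean_annual_income", min = 0)
  check_scalar_number(yll, "yll", min = 0)
  scaled_product(deaths, mean_annual_income, yll)
}

#' Indirect cost of survivors' inability to marry
#'
#' The forgone dowry and related marriage expenses for marriageable-age
#' women among potential cases.
#'
#' @param female_marriageable_cases Potential cases among marriageable-age
#'   women.
#' @param dowry_cost USD per marriage.
#' @return USD, exact.
#' @examples
#' marriage_cost(14820, 1000) # 14,820,000
#' @export
marriage_cost <- function(female_marriageable_cases, dowry_cost) {
  check_count(female_marriageable_cases, "female_marriageable_cases")
  check_scalar_number(dowry_cost, "dowry_cost", min = 0)
  exact_product(female_marriageable_cases, dowry_cost)
}

#' Discounted human-capital cost of premature deaths
#'
#' Standard present-value extension of [premature_death_cost()]: each of the
#' `yll` lost years contributes one year of income discounted at
#' `discount_rate`, starting `start_offset` years from now, with the final
#' partial year weighted by the fractional remainder of `yll`. At a zero
#' discount rate this equals the undiscounted cost exactly.
#'
#' @inheritParams premature_death_cost
#' @param discount_rate Annual discount rate in `[0, 1)`. Default 0.
#' @param start_offset Years until the first lost income year (default 1).
#' @return USD.
#' @examples
#' discounted_human_capital(86049, 750, 55.2, 0) # 3,562,428,600
#' discounted_human_capital(1, 100, 2, 0.5)      # 111.11...
#' @export
discounted_human_capital <- function(deaths, mean_annual_income, yll,
                                     discount_rate = 0, start_offset = 1) {
  check_scalar_number(discount_rate, "discount_rate", min = 0)
  if (discount_rate >= 1) abort_validation("`discount_rate` must be below 1.")
  check_count(start_offset, "start_offset")
  if (discount_rate == 0) {
    return(premature_death_cost(deaths, mean_annual_income, yll))
  }
  check_count(deaths, "deaths")
  check_scalar_number(mean_annual_income, "mean_annual_income", min = 0)
  check_scalar_number(yll, "yll", min = 0)
  full <- floor(yll)
  frac <- yll - full
  t <- seq_len(full) + start_offset - 1
  w <- rep(1, full)
  if (frac > 0) {
    t <- c(t, start_offset + full)
    w <- c(w, frac)
  }
  deaths * mean_annual_income * sum(w * (1 + discount_rate)^(-t))
}
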