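# Assembling a full country cost report.

#' Build a country cost report
#'
#' Runs the prevalence cascade and the complete cost model for one country
#' configuration: the direct-cost ledger, the three indirect cost lines
#' (lost production, premature death, inability to marry) and the explicit
#' not-computed marker for intangible costs.
#'
#' @param config A `noma_config` from [read_country_config()] /
#'   [noma_example_config()].
#' @param discount_rate Annual discount rate applied to the premature-death
#'   human-capital cost; the default 0 reproduces the undiscounted model.
#' @param overrides Published line totals replacing computed ones; defaults
#'   to the configuration's own `overrides` section.
#' @return A `noma_report` object; see [tidy.noma_report()] /
#'   [glance.noma_report()] for tabular views.
#' @examples
#' report <- build_report(noma_example_config("burkina_faso_2018"))
#' glance(report)
#' @export
build_report <- function(config, discount_rate = 0, overrides = config$overrides) {
  stopifnot(inherits(config, "noma_config"))
  profile <- as_country_profile(config)
  params <- as_epi_params(config)
  schedule <- config$cost_schedule

  cascade <- run_cascade(profile, params, schedule)
  direct <- direct_ledger(cascade, schedule, overrides)
  yll <- years_of_life_lost(profile$life_expectancy_at_birth, params$mean_age_at_death)

  indirect_sched <- schedule[schedule$category == "indirect", ]
  indirect <- bind_rows(pmap(
    indirect_sched[c("id", "label", "unit_source", "unit_cost_usd")],
    function(id, label, unit_source, unit_cost_usd) {
      count <- cascade_count(cascade, id)
      if (unit_source == "mean_annual_income") {
        unit <- profile$mean_annual_income
        unit_label <- format(unit)
        total <- lost_production_cost(count, unit)
      } else if (unit_source == "income_times_yll") {
        unit <- profile$mean_annual_income * yll
        unit_label <- sprintf("%s x %s", format(profile$mean_annual_income), format(yll))
        total <- discounted_human_capital(count, profile$mean_annual_income, yll,
                                          discount_rate = discount_rate)
      } else {
        unit <- unit_cost_usd
        unit_label <- format(unit)
        total <- exact_product(count, unit)
      }
      tibble(component_id = id, label = label, count = count,
             unit_label = unit_label, unit_cost_usd = unit, total_usd = total)
    }
  ))
  if (nrow(indirect) == 0L) {
    indirect <- tibble(component_id = character(), label = character(),
                       count = numeric(), unit_label = character(),
                       unit_cost_usd = numeric(), total_usd = numeric())
  }

  structure(
    list(
      country = profile$name,
      year = profile$year,
      profile = profile,
      params = params,
      yll = yll,
      discount_rate = discount_rate,
      cascade = cascade,
      direct = direct,
      direct_total_usd = direct_total(direct),
      indirect = indirect,
      intangible = "not computed",
      overrides = overrides
    ),
    class = "noma_report"
  )
}

#' @export
print.noma_report <- function(x, ...) {
  fmt <- function(v) format(v, big.mark = ",", scientific = FALSE)
  cat(sprintf("<noma_report> %s (%d)\n", x$country, x$year))
  cat(sprintf("  potential cases        %14s\n", fmt(cascade_count(x$cascade, "potential_cases"))))
  cat(sprintf("  receiving treatment    %14s\n", fmt(cascade_count(x$cascade, "treated_cases"))))
  cat(sprintf("  untreated deaths       %14s\n", fmt(cascade_count(x$cascade, "untreated_deaths"))))
  cat(sprintf("  direct costs (USD)     %14s\n", fmt(x$direct_total_usd)))
  for (i in seq_len(nrow(x$indirect))) {
    cat(sprintf("  %-22s %14s\n", x$indirect$component_id[i], fmt(x$indirect$total_usd[i])))
  }
  cat("  intangible costs        ", x$intangible, "\n")
  invisible(x)
}

#' Tidy a country cost report into one row per cost line
#'
#' @param x A `noma_report`.
#' @param ... Unused.
#' @return A tibble with columns `country`, `year`, `category`,
#'   `component_id`, `label`, `count`, `unit_cost_usd`, `total_usd`,
#'   `value_source`. The intangible row carries `NA` costs and
#'   `value_source = "not_computed"` — never a number.
#' @export
tidy.noma_report <- function(x, ...) {
  direct <- mutate(x$direct, category = "direct")
  indirect <- mutate(
    x$indirect[c("component_id", "label", "count", "unit_cost_usd", "total_usd")],
    category = "indirect", value_source = "computed"
  )
  intangible <- tibble(
    component_id = "intangible", label = "Intangible costs (pain, stigma, discrimination)",
    count = NA_real_, unit_cost_usd = NA_real_, total_usd = NA_real_,
    category = "intangible", value_source = "not_computed"
  )
  out <- bind_rows(direct, indirect, intangible)
  mutate(out[c("category", "component_id", "label", "count", "unit_cost_usd",
               "total_usd", "value_source")],
         country = x$country, year = x$year, .before = 1)
}

#' One-row summary of a country cost report
#'
#' @param x A `noma_report`.
#' @param ... Unused.
#' @return A one-row tibble with the cascade head counts, the direct total,
#'   the three indirect totals and the intangible marker.
#' @export
glance.noma_report <- function(x, ...) {
  ind <- function(id) {
    i <- match(id, x$indirect$component_id)
    if (is.na(i)) NA_real_ else x$indirect$total_usd[[i]]
  }
  tibble(
    country = x$country, year = x$year,
    potential_cases = cascade_count(x$cascade, "potential_cases"),
    treated_cases = cascade_count(x$cascade, "treated_cases"),
    untreated_deaths = cascade_count(x$cascade, "untreated_deaths"),
    yll = x$yll,
    direct_total_usd = x$direct_total_usd,
    lost_production_usd = ind("lost_production"),
    premature_death_usd = ind("premature_death"),
    inability_to_marry_usd = ind("inability_to_marry"),
    intangible = x$intangible
  )
}

#' Extract a named output from a report
#'
#' Target selectors are used by the sensitivity analyses: cascade counts
#' (`"potential_cases"`, `"treated_cases"`, `"untreated_deaths"`), totals
#' (`"direct_total"`, `"indirect_total"`, `"grand_total"`), indirect lines
#' by id (`"lost_production"`, `"premature_death"`, `"inability_to_marry"`)
#' and direct lines as `"line:<component_id>"`.
#'
#' @param report A `noma_report`.
#' @param target Selector string.
#' @return The selected number.
#' @examples
#' report_target(build_report(noma_example_config("niger_2018")), "direct_total")
#' @export
report_target <- function(report, target) {
  stopifnot(inherits(report, "noma_report"), is.character(target), length(target) == 1L)
  if (startsWith(target, "line:")) {
    id <- sub("^line:", "", target)
    i <- match(id, report$direct$component_id)
    if (is.na(i)) abort_config(sprintf("no direct cost line `%s`.", id))
    return(report$direct$total_usd[[i]])
  }
  if (target %in% report$indirect$component_id) {
    return(report$indirect$total_usd[[match(target, report$indirect$component_id)]])
  }
  switch(target,
    direct_total = report$direct_total_usd,
    indirect_total = sum(report$indirect$total_usd),
    grand_total = report$direct_total_usd + sum(report$indirect$total_usd),
    potential_cases = ,
    treated_cases = ,
    untreated_deaths = ,
    working_age_cases = ,
    female_marriageable_cases = cascade_count(report$cascade, target),
    abort_config(sprintf("unknown report target `%s`.", target))
  )
}
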