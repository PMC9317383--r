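# Reading, validating and writing country configuration files.

CONFIG_SCHEMA_VERSION <- "1.0"
TOP_KEYS <- c("schema_version", "country", "year",
              "demography", "economy", "epidemiology", "cost_schedule",
              "overrides", "note")
DEMOGRAPHY_KEYS <- c("total_population", "population_at_risk",
                     "population_working_age", "female_population_marriageable",
                     "life_expectancy_at_birth", "age_pyramid", "note")
ECONOMY_KEYS <- c("mean_annual_income", "currency_label", "note")
EPI_KEYS <- c("incidence_rate", "care_fraction", "untreated_mortality",
              "mean_age_at_death", "at_risk_age_range", "working_age_range",
              "marriageable_age_range", "note")

check_known_keys <- function(x, known, where) {
  extra <- setdiff(names(x), known)
  if (length(extra)) {
    abort_config(sprintf("unknown key(s) in %s: %s.", where, paste(extra, collapse = ", ")))
  }
}

need_key <- function(x, key, where) {
  if (is.null(x[[key]])) {
    abort_config(sprintf("missing required field `%s` in %s.", key, where))
  }
  x[[key]]
}

#' Read and validate a country configuration file
#'
#' A configuration is a YAML (or JSON) file with top-level sections
#' `demography`, `economy`, `epidemiology` and `cost_schedule`, plus an
#' optional `overrides` map of published line totals that replace computed
#' ones. Unknown keys are rejected and every type invariant is checked at
#' load time.
#'
#' @param path Path to the configuration file.
#' @param schema_version Schema version the file must declare.
#' @return A validated `noma_config` object.
#' @seealso [noma_example_config()] for the bundled Burkina Faso and Niger
#'   configurations, [write_country_config()] for the inverse.
#' @export
read_country_config <- function(path, schema_version = CONFIG_SCHEMA_VERSION) {
  if (!file.exists(path)) abort_config(sprintf("config file not found: %s.", path))
  raw <- yaml::read_yaml(path)
  if (!identical(as.character(raw$schema_version), schema_version)) {
    abort_config(sprintf(
      "config declares schema_version `%s`; expected `%s`.",
      raw$schema_version %||% "<missing>", schema_version
    ))
  }
  as_noma_config(raw, source = path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_noma_config <- function(raw, source = NA_character_) {
  check_known_keys(raw, TOP_KEYS, "the configuration")
  country <- need_key(raw, "country", "the configuration")
  year <- need_key(raw, "year", "the configuration")
  demography <- need_key(raw, "demography", "the configuration")
  economy <- need_key(raw, "economy", "the configuration")
  epidemiology <- need_key(raw, "epidemiology", "the configuration")
  schedule_raw <- need_key(raw, "cost_schedule", "the configuration")
  check_known_keys(demography, DEMOGRAPHY_KEYS, "`demography`")
  check_known_keys(economy, ECONOMY_KEYS, "`economy`")
  check_known_keys(epidemiology, EPI_KEYS, "`epidemiology`")
  for (key in c("total_population", "population_working_age",
                "female_population_marriageable", "life_expectancy_at_birth")) {
    need_key(demography, key, "`demography`")
  }
  need_key(economy, "mean_annual_income", "`economy`")
  for (key in c("incidence_rate", "care_fraction", "untreated_mortality", "mean_age_at_death")) {
    need_key(epidemiology, key, "`epidemiology`")
  }

  schedule <- cost_schedule(bind_rows(map(schedule_raw, function(comp) {
    as_tibble(map(comp, function(v) if (is.null(v)) NA else v))
  })))

  overrides <- raw$overrides
  if (!is.null(overrides)) {
    overrides <- unlist(overrides)
    unknown <- setdiff(names(overrides), schedule$id)
    if (length(unknown)) {
      abort_config(sprintf("override(s) for unknown component(s): %s.", paste(unknown, collapse = ", ")))
    }
    if (any(!is.finite(overrides)) || any(overrides < 0)) {
      abort_validation("override totals must be non-negative numbers.")
    }
  }

  config <- structure(
    list(
      schema_version = as.character(raw$schema_version %||% CONFIG_SCHEMA_VERSION),
      country = country, year = year,
      demography = demography, economy = economy, epidemiology = epidemiology,
      cost_schedule = schedule, overrides = overrides,
      note = raw$note, source = source
    ),
    class = "noma_config"
  )
  # construct the typed objects once so every invariant is checked at load
  as_country_profile(config)
  as_epi_params(config)
  config
}

#' @export
print.noma_config <- function(x, ...) {
  cat(sprintf("<noma_config> %s (%s), schema %s\n", x$country, x$year, x$schema_version))
  cat(sprintf("  %d cost components (%d direct), %d override(s)\n",
              nrow(x$cost_schedule), sum(x$cost_schedule$category == "direct"),
              length(x$overrides)))
  invisible(x)
}

#' Extract the typed country profile from a configuration
#'
#' @param config A `noma_config`.
#' @return A [country_profile()] object.
#' @export
as_country_profile <- function(config) {
  d <- config$demography
  pyramid <- NULL
  if (!is.null(d$age_pyramid)) {
    pyramid <- age_pyramid(d$age_pyramid$start_age, d$age_pyramid$end_age, d$age_pyramid$count)
  }
  country_profile(
    name = config$country, year = config$year,
    total_population = d$total_population,
    population_at_risk = d$population_at_risk,
    population_working_age = d$population_working_age,
    female_population_marriageable = d$female_population_marriageable,
    life_expectancy_at_birth = d$life_expectancy_at_birth,
    mean_annual_income = config$economy$mean_annual_income,
    currency_label = config$economy$currency_label %||% "USD",
    age_pyramid = pyramid,
    at_risk_age_range = config$epidemiology$at_risk_age_range %||% c(0, 29)
  )
}

#' Extract the typed epidemiological parameters from a configuration
#'
#' @param config A `noma_config`.
#' @return An [epi_params()] object.
#' @export
as_epi_params <- function(config) {
  e <- config$epidemiology
  epi_params(
    incidence_rate = e$incidence_rate,
    care_fraction = e$care_fraction,
    untreated_mortality = e$untreated_mortality,
    mean_age_at_death = e$mean_age_at_death,
    at_risk_age_range = unlist(e$at_risk_age_range %||% c(0, 29)),
    working_age_range = unlist(e$working_age_range %||% c(15, 29)),
    marriageable_age_range = unlist(e$marriageable_age_range %||% c(15, 29))
  )
}

#' Serialize a configuration back to YAML
#'
#' The written file reads back to an identical configuration (key order may
#' differ from the original file).
#'
#' @param config A `noma_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_country_config <- function(config, path) {
  sched <- purrr::transpose(as.list(config$cost_schedule))
  sched <- map(sched, function(row) keep(row, ~ !is.null(.x) && !all(is.na(.x))))
  out <- list(
    schema_version = config$schema_version,
    country = config$country,
    year = config$year,
    demography = config$demography,
    economy = config$economy,
    epidemiology = config$epidemiology,
    cost_schedule = sched
  )
  if (!is.null(config$overrides)) out$overrides <- as.list(config$overrides)
  if (!is.null(config$note)) out$note <- config$note
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Bundled country configurations
#'
#' Returns one of the configurations shipped with the package:
#' `"burkina_faso_2018"` or `"niger_2018"`, encoding the published
#' demographic, economic, epidemiological and unit-cost inputs for the two
#' countries (populations not printed in the source tables, such as the
#' working-age population, are back-computed from the printed cohort counts
#' and marked as such in their provenance notes).
#'
#' @param country `"burkina_faso_2018"` or `"niger_2018"`.
#' @return A `noma_config`.
#' @examples
#' cfg <- noma_example_config("burkina_faso_2018")
#' cfg$economy$mean_annual_income # 750
#' @export
noma_example_config <- function(country = c("burkina_faso_2018", "niger_2018")) {
  country <- match.arg(country)
  path <- system.file("extdata", paste0(country, ".yaml"), package = "nomacost")
  read_country_config(path)
}

# dotted-path accessors used by the sensitivity machinery ---------------------

resolve_path <- function(path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (length(parts) < 2L) abort_config(sprintf("cannot resolve parameter path `%s`.", path))
  parts
}

#' Read a configuration value by dotted path
#'
#' Paths address scalar fields (`"epidemiology.incidence_rate"`,
#' `"economy.mean_annual_income"`), schedule cells
#' (`"cost_schedule.<id>.<column>"`) and overrides (`"overrides.<id>"`).
#'
#' @param config A `noma_config`.
#' @param path Dotted path string.
#' @return The value at `path`.
#' @export
get_config_value <- function(config, path) {
  parts <- resolve_path(path)
  if (parts[[1]] == "cost_schedule") {
    if (length(parts) != 3L) abort_config(sprintf("schedule paths have the form cost_schedule.<id>.<column>; got `%s`.", path))
    i <- match(parts[[2]], config$cost_schedule$id)
    if (is.na(i)) abort_config(sprintf("no cost component `%s`.", parts[[2]]))
    if (!parts[[3]] %in% names(config$cost_schedule)) {
      abort_config(sprintf("no schedule column `%s`.", parts[[3]]))
    }
    return(config$cost_schedule[[parts[[3]]]][[i]])
  }
  node <- config
  for (p in parts) {
    if (!is.list(node) || is.null(node[[p]])) {
      abort_config(sprintf("cannot resolve parameter path `%s` (at `%s`).", path, p))
    }
    node <- node[[p]]
  }
  node
}

#' Set a configuration value by dotted path
#'
#' @inheritParams get_config_value
#' @param value Replacement value; the modified configuration is re-validated
#'   in full.
#' @return The modified `noma_config`.
#' @export
set_config_value <- function(config, path, value) {
  parts <- resolve_path(path)
  if (parts[[1]] == "cost_schedule") {
    get_config_value(config, path) # existence check
    i <- match(parts[[2]], config$cost_schedule$id)
    config$cost_schedule[[parts[[3]]]][i] <- value
  } else if (parts[[1]] == "overrides") {
    config$overrides[[parts[[2]]]] <- value
  } else {
    get_config_value(config, path)
    config[[parts[[1]]]][[parts[[2]]]] <- value
  }
  # re-validate the whole configuration with the new value in place
  as_noma_config(unclass_config(config), source = config$source)
}

unclass_config <- function(config) {
  raw <- list(
    schema_version = config$schema_version,
    country = config$country, year = config$year,
    demography = config$demography, economy = config$economy,
    epidemiology = config$epidemiology,
    cost_schedule = purrr::transpose(as.list(config$cost_schedule)),
    note = config$note
  )
  if (!is.null(config$overrides)) raw$overrides <- as.list(config$overrides)
  raw
}
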