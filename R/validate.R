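# Cell-by-cell validation against the published tables, and report output.

#' Published table values bundled with the package
#'
#' Every number of the published country tables (prevalence, cost and
#' summary tables) with its table and row key, so any drift between
#' computed and published values — including the publication's own internal
#' inconsistencies — is detectable cell by cell.
#'
#' @param country Optional country name to filter on.
#' @return A tibble with columns `country`, `table`, `row`, `key`,
#'   `printed`.
#' @export
printed_values <- function(country = NULL) {
  path <- system.file("extdata", "printed_values.csv", package = "nomacost")
  vals <- readr::read_csv(path, col_types = readr::cols(
    country = readr::col_character(), table = readr::col_character(),
    row = readr::col_character(), key = readr::col_character(),
    printed = readr::col_double()
  ))
  if (!is.null(country)) vals <- vals[vals$country == country, ]
  vals
}

computed_for_key <- function(report, key) {
  kind <- sub(":.*$", "", key)
  id <- sub("^[^:]*:", "", key)
  switch(kind,
    cascade = cascade_count(report$cascade, id),
    yll = report$yll,
    direct_total = report$direct_total_usd,
    direct_count = report$direct$count[[match(id, report$direct$component_id)]],
    direct_line = report$direct$computed_total_usd[[match(id, report$direct$component_id)]],
    indirect_count = report$indirect$count[[match(id, report$indirect$component_id)]],
    indirect_line = report$indirect$total_usd[[match(id, report$indirect$component_id)]],
    abort_config(sprintf("unknown printed-value key `%s`.", key))
  )
}

#' Validate a report against the published table values
#'
#' Compares each published cell with the model's computed value. For cost
#' lines the comparison uses the purely computed `count * unit cost` total,
#' so a line whose configuration ships a published override is reported as
#' `printed_override_used` with its exact delta rather than silently
#' matching; any other non-zero delta is classified `discrepancy`.
#'
#' @param report A `noma_report`.
#' @param printed Published values to compare against; defaults to the
#'   bundled table for the report's country.
#' @return A tibble with columns `table`, `row`, `key`, `printed`,
#'   `computed`, `delta` (`printed - computed`) and `classification`
#'   (`match` iff `delta == 0`).
#' @examples
#' deltas <- validate_report(build_report(noma_example_config("niger_2018")))
#' subset(deltas, classification != "match")
#' @export
validate_report <- function(report, printed = printed_values(report$country)) {
  stopifnot(inherits(report, "noma_report"))
  if (nrow(printed) == 0L) {
    abort_config(sprintf("no published values available for `%s`.", report$country))
  }
  computed <- map_dbl(printed$key, function(key) computed_for_key(report, key))
  delta <- printed$printed - computed
  overridden <- names(report$overrides) %||% character()
  key_id <- sub("^direct_line:", "", printed$key)
  override_val <- map_dbl(seq_along(printed$key), function(i) {
    if (startsWith(printed$key[[i]], "direct_line:") && key_id[[i]] %in% overridden) {
      report$overrides[[key_id[[i]]]]
    } else {
      NA_real_
    }
  })
  classification <- dplyr::case_when(
    delta == 0 ~ "match",
    !is.na(override_val) & printed$printed == override_val ~ "printed_override_used",
    .default = "discrepancy"
  )
  tibble(
    table = printed$table, row = printed$row, key = printed$key,
    printed = printed$printed, computed = computed,
    delta = delta, classification = classification
  )
}

#' Side-by-side summary of country cost reports
#'
#' Lays one or more reports out in the summary-table shape: one row per
#' cost category and line, a head-count and a cost column per country.
#' Intangible costs are rendered as the non-numeric marker `"NN"`, never a
#' number. Duplicate country names are suffixed deterministically.
#'
#' @param reports A `noma_report` or list of them.
#' @param grouped Use thousands separators (human-readable output). Machine
#'   output (`FALSE`, default) renders bare digits.
#' @return A tibble with a `cost_category` column and, per report, a
#'   population and a cost column (character, since the intangible row is a
#'   marker).
#' @export
render_summary <- function(reports, grouped = FALSE) {
  if (inherits(reports, "noma_report")) reports <- list(reports)
  stopifnot(length(reports) >= 1L, all(map_chr(reports, ~ class(.x)[1]) == "noma_report"))
  countries <- make.unique(map_chr(reports, "country"), sep = " ")
  fmt <- function(v) {
    ifelse(is.na(v), "NN",
           format(v, big.mark = if (grouped) "," else "", scientific = FALSE, trim = TRUE))
  }
  cols <- map(reports, function(r) {
    lines <- tidy(r)
    header <- tibble(
      cost_category = "1. Direct costs",
      population = fmt(cascade_count(r$cascade, "treated_cases")),
      total = fmt(r$direct_total_usd)
    )
    direct <- tibble(
      cost_category = lines$label[lines$category == "direct"],
      population = fmt(lines$count[lines$category == "direct"]),
      total = fmt(lines$total_usd[lines$category == "direct"])
    )
    indirect <- tibble(
      cost_category = c("2. Indirect costs", lines$label[lines$category == "indirect"]),
      population = c("", fmt(lines$count[lines$category == "indirect"])),
      total = c("", fmt(lines$total_usd[lines$category == "indirect"]))
    )
    intangible <- tibble(cost_category = "3. Intangible costs",
                         population = "NN", total = "NN")
    bind_rows(header, direct, indirect, intangible)
  })
  out <- cols[[1]]["cost_category"]
  for (i in seq_along(cols)) {
    out[[paste0("population_", countries[[i]])]] <- cols[[i]]$population
    out[[paste0("cost_usd_", countries[[i]])]] <- cols[[i]]$total
  }
  out
}

#' Write a report's artifacts to a directory
#'
#' Writes the cascade, the cost lines and the summary as CSV, the full
#' report as JSON, and (optionally) the validation deltas. Rendering is
#' pure: writing the same report twice yields byte-identical files.
#'
#' @param report A `noma_report`.
#' @param dir Output directory (created if needed).
#' @param validate Also write `validation.csv` with
#'   [validate_report()] output.
#' @return The paths written, invisibly.
#' @export
write_report <- function(report, dir, validate = FALSE) {
  stopifnot(inherits(report, "noma_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    cascade = file.path(dir, "table2_cascade.csv"),
    costs = file.path(dir, "table4_5_costs.csv"),
    summary = file.path(dir, "table6_summary.csv"),
    json = file.path(dir, "report.json")
  )
  readr::write_csv(report$cascade, paths[["cascade"]])
  costs <- tidy(report)
  names(costs)[names(costs) == "count"] <- "Population"
  names(costs)[names(costs) == "unit_cost_usd"] <- "Mean Cost per Person in USD"
  names(costs)[names(costs) == "total_usd"] <- "Total Costs in USD"
  readr::write_csv(costs, paths[["costs"]])
  readr::write_csv(render_summary(report), paths[["summary"]])
  json <- list(
    country = report$country, year = report$year,
    yll = report$yll, discount_rate = report$discount_rate,
    cascade = report$cascade, direct = report$direct,
    direct_total_usd = report$direct_total_usd,
    indirect = report$indirect, intangible = report$intangible
  )
  jsonlite::write_json(json, paths[["json"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (validate) {
    paths <- c(paths, validation = file.path(dir, "validation.csv"))
    readr::write_csv(validate_report(report), paths[["validation"]])
  }
  invisible(paths)
}
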