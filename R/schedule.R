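# The unit-cost schedule: one row per cost component.

COST_CATEGORIES <- c("direct", "indirect", "intangible")
COUNT_BASES <- c("treated", "potential", "deaths", "working_age",
                 "female_marriageable", "at_risk")
ELIGIBILITIES <- c("all", "fraction", "absolute")
UNIT_SOURCES <- c("config", "mean_annual_income", "income_times_yll")

#' Validate a unit-cost schedule
#'
#' A schedule is a tibble with one row per cost component. Each component
#' declares the cohort it applies to (`count_base`), how its head count is
#' derived from that base (`eligibility`: the whole base, a fraction of it,
#' or an absolute count), and its unit cost. Indirect components may derive
#' their unit value from the profile instead of a fixed dollar amount
#' (`unit_source`): the mean annual income (lost production) or income times
#' years of life lost (premature death, human capital approach).
#'
#' @param x A data frame with columns `id`, `label`, `category` (one of
#'   direct/indirect/intangible), `unit_cost_usd`, `count_base`,
#'   `eligibility`, `eligibility_value`; optionally `unit_source`,
#'   `native_amount`, `native_currency`, `note`.
#' @return The validated schedule as a tibble (missing optional columns
#'   filled with defaults).
#' @export
cost_schedule <- function(x) {
  x <- as_tibble(x)
  required <- c("id", "label", "category", "count_base", "eligibility")
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    abort_config(sprintf("cost schedule is missing column(s): %s.", paste(missing, collapse = ", ")))
  }
  if (!"unit_source" %in% names(x)) x$unit_source <- "config"
  x$unit_source[is.na(x$unit_source)] <- "config"
  if (!"unit_cost_usd" %in% names(x)) x$unit_cost_usd <- NA_real_
  if (!"eligibility_value" %in% names(x)) x$eligibility_value <- NA_real_
  for (opt in c("native_amount", "native_currency", "note")) {
    if (!opt %in% names(x)) x[[opt]] <- NA
  }
  if (anyDuplicated(x$id)) abort_config("cost component ids must be unique.")
  bad <- setdiff(x$category, COST_CATEGORIES)
  if (length(bad)) abort_config(sprintf("unknown cost category: %s.", paste(bad, collapse = ", ")))
  bad <- setdiff(x$count_base, COUNT_BASES)
  if (length(bad)) abort_config(sprintf("unknown count_base: %s.", paste(bad, collapse = ", ")))
  bad <- setdiff(x$eligibility, ELIGIBILITIES)
  if (length(bad)) abort_config(sprintf("unknown eligibility: %s.", paste(bad, collapse = ", ")))
  bad <- setdiff(x$unit_source, UNIT_SOURCES)
  if (length(bad)) abort_config(sprintf("unknown unit_source: %s.", paste(bad, collapse = ", ")))

  for (i in seq_len(nrow(x))) {
    row <- x[i, ]
    if (row$unit_source == "config") {
      if (row$category != "intangible" &&
          (is.na(row$unit_cost_usd) || row$unit_cost_usd < 0)) {
        abort_validation(sprintf("component `%s`: `unit_cost_usd` must be a non-negative number.", row$id))
      }
    }
    if (row$eligibility == "fraction") {
      if (is.na(row$eligibility_value) || row$eligibility_value < 0 || row$eligibility_value > 1) {
        abort_validation(sprintf("component `%s`: fraction eligibility needs a value in [0, 1].", row$id))
      }
    }
    if (row$eligibility == "absolute") {
      v <- row$eligibility_value
      if (is.na(v) || v < 0 || v != floor(v)) {
        abort_validation(sprintf("component `%s`: absolute eligibility needs a non-negative integer count.", row$id))
      }
    }
  }
  x[c("id", "label", "category", "count_base", "eligibility", "eligibility_value",
      "unit_source", "unit_cost_usd", "native_amount", "native_currency", "note")]
}
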