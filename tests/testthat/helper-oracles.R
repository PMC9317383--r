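# Independent oracles used across the suite.

# Floor of base * rate via modular integer arithmetic — a different route
# from the division-with-repair used inside the package.
oracle_floor <- function(base, rate, digits = 6L) {
  num <- round(rate * 10^digits)
  den <- 10^digits
  stopifnot(num / den == rate, base * num <= 2^53)
  p <- base * num
  (p - p %% den) / den
}

# Brute-force human-capital cost: per person, per year, income added one
# year at a time with the fractional final year added once. Only viable for
# tiny instances.
oracle_human_capital <- function(deaths, income, yll) {
  full <- floor(yll)
  frac <- yll - full
  total <- 0
  for (d in seq_len(deaths)) {
    for (y in seq_len(full)) total <- total + income
    total <- total + income * frac
  }
  total
}

# A minimal schedule with no absolute counts, for cascades over arbitrary
# profiles (fractions and full cohorts scale with the cascade).
fractional_schedule <- function() {
  cost_schedule(tibble::tibble(
    id = c("treatment", "surgery", "lost_production", "premature_death", "inability_to_marry"),
    label = c("Treatment", "Surgery", "Lost production", "Premature death", "Inability to marry"),
    category = c("direct", "direct", "indirect", "indirect", "indirect"),
    count_base = c("treated", "treated", "working_age", "deaths", "female_marriageable"),
    eligibility = c("all", "fraction", "all", "all", "all"),
    eligibility_value = c(NA, 0.6, NA, NA, NA),
    unit_source = c("config", "config", "mean_annual_income", "income_times_yll", "config"),
    unit_cost_usd = c(345, 400, NA, NA, 1000)
  ))
}
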