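# Exact integer-ratio arithmetic.
#
# Every head count in the prevalence cascade is floor(base * rate) where the
# rate is a short decimal (6.4 per 1000, a 10% care-seeking fraction, a 90%
# case-fatality proportion).  Binary floating point cannot represent 0.0064,
# and products such as 4,042,188 * 0.0064 = 25,870.0032 sit close enough to
# an integer that a naive floor() can come out one unit low.  The package
# therefore rewrites every rate as an exact integer ratio num / 10^k and does
# the floor purely in integer arithmetic (doubles are exact integers up to
# 2^53, which every intermediate product is checked against).  The same
# machinery gives dollar totals that match published tables to the unit,
# e.g. 86,049 * 750 * 55.2 = 3,562,428,600 computed as (86,049 * 750 * 552) / 10.

MAX_EXACT <- 2^53

#' Rewrite a short decimal as an exact integer ratio
#'
#' Finds the smallest `k <= max_digits` such that `x == num / 10^k` holds
#' exactly in double precision, i.e. `x` is a decimal with at most
#' `max_digits` fractional digits. Rates and monetary factors throughout the
#' package are required to be such short decimals; this is what makes the
#' floor convention and the dollar totals exactly reproducible.
#'
#' @param x A single non-negative number with at most `max_digits` decimal
#'   digits.
#' @param max_digits Maximum number of decimal digits to try (default 9).
#' @return A list with integer components `num` and `den` (`den = 10^k`).
#' @examples
#' decimal_to_ratio(0.0064) # 64 / 10000
#' decimal_to_ratio(55.2)   # 552 / 10
#' @export
decimal_to_ratio <- function(x, max_digits = 9L) {
  check_scalar_number(x, "x", min = 0)
  for (k in 0:max_digits) {
    den <- 10^k
    num <- round(x * den)
    if (num / den == x) {
      return(list(num = num, den = den))
    }
  }
  abort_validation(sprintf(
    "%s is not a decimal with at most %d fractional digits; exact arithmetic is impossible. Round the value first.",
    format(x, digits = 17), max_digits
  ))
}

#' Exact floor of a count times a decimal rate
#'
#' Computes `floor(base * rate)` with integer arithmetic only: the rate is
#' rewritten as `num / 10^k` and the quotient `(base * num) %/% 10^k` is
#' repaired against the exact products, so the result is immune to binary
#' rounding even when `base * rate` is an exact integer.
#'
#' @param base Non-negative integer count (vectorised).
#' @param rate A single non-negative short-decimal rate.
#' @return `floor(base * rate)`, exactly.
#' @examples
#' floor_count(16540452, 0.0064) # 105858, not 105859
#' @export
floor_count <- function(base, rate) {
  if (length(base) == 0L) return(numeric(0))
  if (!is.numeric(base) || any(!is.finite(base)) || any(base < 0) || any(base != floor(base))) {
    abort_validation("`base` must contain non-negative integers.")
  }
  r <- decimal_to_ratio(rate)
  p <- as.numeric(base) * r$num # doubles: exact up to 2^53, no 32-bit overflow
  if (any(p > MAX_EXACT)) {
    abort_validation("`base * rate` exceeds the exact-integer range (2^53); reduce the rate's decimal digits.")
  }
  q <- p %/% r$den
  q <- q + ((q + 1) * r$den <= p) # repair a quotient the FPU rounded low
  q - (q * r$den > p)             # ... or high
}

# exact product of integer quantities (counts, whole-dollar unit costs)
exact_product <- function(a, b) {
  p <- as.numeric(a) * as.numeric(b)
  if (any(p > MAX_EXACT)) {
    abort_validation("product exceeds the exact-integer range (2^53).")
  }
  p
}

# count * unit * factor with a short-decimal factor, e.g. deaths * income * YLL
scaled_product <- function(count, unit, factor, max_digits = 6L) {
  r <- decimal_to_ratio(factor, max_digits = max_digits)
  p <- as.numeric(count) * as.numeric(unit) * r$num
  if (any(p > MAX_EXACT)) {
    abort_validation("product exceeds the exact-integer range (2^53).")
  }
  p / r$den
}
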