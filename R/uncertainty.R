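# One-way and Monte-Carlo sensitivity analysis over the model's uncertain
# parameters.
#
# Uncertainty propagates THROUGH the integer cascade, not around it: each
# evaluation rebuilds the full deterministic model with the perturbed
# configuration, so the floor convention applies inside every scenario and
# replicate.  Sampled values are rounded to 7 decimal digits first, because
# the exact-ratio floor is defined for short decimals only.

MC_DIGITS <- 7L

#' Declare an uncertain parameter
#'
#' @param parameter_path Dotted configuration path (see
#'   [get_config_value()]), e.g. `"epidemiology.incidence_rate"`.
#' @param kind `"point"`, `"uniform"` or `"triangular"`.
#' @param lo,hi Interval bounds in the parameter's native units (for
#'   `"point"`, both default to `mode`).
#' @param mode Most likely value (triangular mode / point value); defaults
#'   to the interval midpoint for `"uniform"`.
#' @return A one-row tibble describing the distribution.
#' @examples
#' param_dist("epidemiology.care_fraction", "uniform", 0.10, 0.15)
#' @export
param_dist <- function(parameter_path, kind = c("point", "uniform", "triangular"),
                       lo = NULL, hi = NULL, mode = NULL) {
  kind <- match.arg(kind)
  if (kind == "point") {
    if (is.null(mode)) mode <- lo %||% hi
    if (is.null(mode)) abort_config("a point distribution needs a value.")
    lo <- hi <- mode
  }
  if (is.null(lo) || is.null(hi)) abort_config("`lo` and `hi` are required.")
  if (is.null(mode)) mode <- (lo + hi) / 2
  if (!(lo <= mode && mode <= hi)) {
    abort_validation(sprintf("need lo <= mode <= hi; got (%s, %s, %s).", lo, mode, hi))
  }
  tibble(parameter_path = parameter_path, kind = kind, lo = lo, mode = mode, hi = hi)
}

#' Default uncertainty ranges shipped with the package
#'
#' The annual incidence is triangular over the span reported across field
#' studies (8.3 per 100,000 up to 7 per 1000, mode at the 6.4 per 1000 the
#' model uses) and the care-seeking fraction is uniform on 10-15%, the
#' range reported for survivors seeking care. Unit costs have no published
#' ranges and stay at their point values unless the user supplies ranges.
#'
#' @return A tibble of [param_dist()] rows.
#' @export
default_distributions <- function() {
  bind_rows(
    param_dist("epidemiology.incidence_rate", "triangular",
               lo = 8.3e-5, mode = 0.0064, hi = 0.007),
    param_dist("epidemiology.care_fraction", "uniform", lo = 0.10, hi = 0.15)
  )
}

# Fixed absolute sub-cohort counts cannot follow a perturbed cascade (and
# would violate their base bound under a smaller incidence), so sensitivity
# runs convert them to equivalent fractions of their baseline base cohort.
# The fraction is ceiled at 1e-7 so the baseline counts are reproduced
# exactly by the floor rule.
rescale_absolute_counts <- function(config) {
  cascade <- run_cascade(as_country_profile(config), as_epi_params(config),
                         config$cost_schedule)
  sched <- config$cost_schedule
  for (i in which(sched$eligibility == "absolute")) {
    base <- cascade_count(cascade, BASE_COHORT_ROW[[sched$count_base[[i]]]])
    if (base <= 0) next
    f <- min(1, ceiling(sched$eligibility_value[[i]] / base * 10^MC_DIGITS) / 10^MC_DIGITS)
    sched$eligibility[i] <- "fraction"
    sched$eligibility_value[i] <- f
  }
  config$cost_schedule <- sched
  as_noma_config(unclass_config(config), source = config$source)
}

sensitivity_result <- function(method, target, baseline, ...) {
  structure(
    c(list(method = method, target = target, baseline = baseline), list(...)),
    class = "noma_sensitivity"
  )
}

#' One-way (tornado) sensitivity analysis
#'
#' Recomputes the target output at each parameter's low and high bound
#' while all other parameters stay at baseline, and ranks parameters by the
#' width of the resulting swing (widest first).
#'
#' @param config A `noma_config` (the baseline).
#' @param distributions A tibble of [param_dist()] rows; default
#'   [default_distributions()].
#' @param target Output selector, see [report_target()].
#' @param rescale_counts Convert absolute sub-cohort counts to equivalent
#'   fractions of their baseline base so they follow the perturbed cascade
#'   (default `TRUE`).
#' @return A `noma_sensitivity` object whose `tornado` element has one row
#'   per parameter: bounds, outputs at the bounds, and the swing.
#' @examples
#' sens <- one_way(noma_example_config("burkina_faso_2018"),
#'                 target = "grand_total")
#' tidy(sens)
#' @export
one_way <- function(config, distributions = default_distributions(),
                    target = "grand_total", rescale_counts = TRUE) {
  stopifnot(inherits(config, "noma_config"))
  if (rescale_counts) config <- rescale_absolute_counts(config)
  baseline <- report_target(build_report(config), target)
  at <- function(path, value) {
    report_target(build_report(set_config_value(config, path, value)), target)
  }
  tornado <- bind_rows(pmap(
    distributions[c("parameter_path", "lo", "hi")],
    function(parameter_path, lo, hi) {
      out_lo <- at(parameter_path, lo)
      out_hi <- at(parameter_path, hi)
      tibble(parameter_path = parameter_path, lo = lo, hi = hi,
             output_lo = out_lo, output_hi = out_hi,
             swing = abs(out_hi - out_lo))
    }
  ))
  if (nrow(tornado)) tornado <- arrange(tornado, desc(.data$swing))
  sensitivity_result("one_way", target, baseline, tornado = tornado)
}

sample_dist <- function(row, n) {
  x <- switch(row$kind,
    point = rep(row$mode, n),
    uniform = runif(n, row$lo, row$hi),
    triangular = {
      u <- runif(n)
      span <- row$hi - row$lo
      cut <- if (span == 0) 0.5 else (row$mode - row$lo) / span
      ifelse(u < cut,
             row$lo + sqrt(u * span * (row$mode - row$lo)),
             row$hi - sqrt((1 - u) * span * (row$hi - row$mode)))
    }
  )
  round(x, MC_DIGITS)
}

#' Monte-Carlo sensitivity analysis
#'
#' Samples every declared distribution independently in each replicate,
#' reruns the full deterministic model, and summarises the target output
#' sample. Deterministic given `(seed, replicates)`: the generator is
#' seeded explicitly and the seed is recorded in the result.
#'
#' @inheritParams one_way
#' @param replicates Number of Monte-Carlo replicates.
#' @param seed Integer seed for the sampler.
#' @return A `noma_sensitivity` object with elements `samples` (a tibble of
#'   replicate parameter draws and outputs), `percentiles` (2.5/50/97.5),
#'   `seed` and `replicates`.
#' @examples
#' mc <- monte_carlo(noma_example_config("niger_2018"),
#'                   replicates = 50, seed = 1)
#' glance(mc)
#' @export
monte_carlo <- function(config, distributions = default_distributions(),
                        target = "grand_total", replicates = 1000, seed = 1,
                        rescale_counts = TRUE) {
  stopifnot(inherits(config, "noma_config"))
  check_count(replicates, "replicates")
  if (replicates < 1) abort_validation("`replicates` must be at least 1.")
  if (rescale_counts) config <- rescale_absolute_counts(config)
  baseline <- report_target(build_report(config), target)

  draws <- withr::with_seed(seed, {
    map(seq_len(nrow(distributions)),
        function(i) sample_dist(distributions[i, ], replicates))
  })
  names(draws) <- distributions$parameter_path

  values <- map_dbl(seq_len(replicates), function(rep) {
    cfg <- config
    for (path in names(draws)) {
      cfg <- set_config_value(cfg, path, draws[[path]][[rep]])
    }
    report_target(build_report(cfg), target)
  })
  samples <- as_tibble(c(list(replicate = seq_len(replicates)), draws,
                         list(value = values)))
  sensitivity_result(
    "monte_carlo", target, baseline,
    samples = samples,
    percentiles = quantile(values, c(0.025, 0.5, 0.975), names = TRUE),
    seed = seed, replicates = replicates
  )
}

#' @export
print.noma_sensitivity <- function(x, ...) {
  cat(sprintf("<noma_sensitivity> %s on `%s`\n", x$method, x$target))
  cat(sprintf("  baseline: %s\n", format(x$baseline, big.mark = ",", scientific = FALSE)))
  if (x$method == "one_way") {
    print(x$tornado)
  } else {
    cat(sprintf("  %d replicates, seed %d\n", x$replicates, x$seed))
    print(x$percentiles)
  }
  invisible(x)
}

#' Tidy a sensitivity result
#'
#' @param x A `noma_sensitivity`.
#' @param ... Unused.
#' @return For one-way results, the tornado tibble; for Monte-Carlo
#'   results, the replicate sample tibble.
#' @export
tidy.noma_sensitivity <- function(x, ...) {
  if (x$method == "one_way") x$tornado else x$samples
}

#' One-row summary of a sensitivity result
#'
#' @param x A `noma_sensitivity`.
#' @param ... Unused.
#' @return A one-row tibble: method, target, baseline, and either the
#'   widest swing (one-way) or the percentile summary (Monte-Carlo).
#' @export
glance.noma_sensitivity <- function(x, ...) {
  base <- tibble(method = x$method, target = x$target, baseline = x$baseline)
  if (x$method == "one_way") {
    base$widest_swing <- if (nrow(x$tornado)) x$tornado$swing[[1]] else 0
    base$widest_parameter <- if (nrow(x$tornado)) x$tornado$parameter_path[[1]] else NA_character_
  } else {
    base$replicates <- x$replicates
    base$seed <- x$seed
    base$p2.5 <- x$percentiles[[1]]
    base$median <- x$percentiles[[2]]
    base$p97.5 <- x$percentiles[[3]]
  }
  base
}
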