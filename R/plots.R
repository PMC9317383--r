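# ggplot2 views of reports and sensitivity results.

#' Plot a country cost report
#'
#' Horizontal bars of every monetised cost line on a log10 dollar axis
#' (costs span five orders of magnitude between schooling and premature
#' death), coloured by category. The intangible marker is not plotted — it
#' has no number.
#'
#' @param object A `noma_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.noma_report <- function(object, ...) {
  lines <- tidy(object)
  lines <- filter(lines, .data$category != "intangible", .data$total_usd > 0)
  ggplot2::ggplot(lines, ggplot2::aes(
    x = .data$total_usd,
    y = stats::reorder(.data$label, .data$total_usd),
    fill = .data$category
  )) +
    ggplot2::geom_col() +
    ggplot2::scale_x_log10(labels = function(x) format(x, big.mark = ",", scientific = FALSE)) +
    ggplot2::labs(
      title = sprintf("Economic and social costs of noma, %s (%d)", object$country, object$year),
      x = "Cost (USD, log scale)", y = NULL, fill = "Category"
    )
}

#' Plot a sensitivity result
#'
#' One-way results draw a tornado diagram (one bar per parameter, from the
#' low-bound output to the high-bound output, widest swing on top, baseline
#' as a dashed line); Monte-Carlo results draw the sampled output
#' distribution with its 2.5/50/97.5 percentiles.
#'
#' @param object A `noma_sensitivity`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.noma_sensitivity <- function(object, ...) {
  if (object$method == "one_way") {
    tor <- object$tornado
    tor$parameter_path <- stats::reorder(tor$parameter_path, tor$swing)
    ggplot2::ggplot(tor, ggplot2::aes(y = .data$parameter_path)) +
      ggplot2::geom_segment(
        ggplot2::aes(x = .data$output_lo, xend = .data$output_hi, yend = .data$parameter_path),
        linewidth = 6, colour = "steelblue"
      ) +
      ggplot2::geom_vline(xintercept = object$baseline, linetype = "dashed") +
      ggplot2::labs(
        title = sprintf("One-way sensitivity of %s", object$target),
        x = "Output (USD)", y = NULL
      )
  } else {
    ggplot2::ggplot(object$samples, ggplot2::aes(x = .data$value)) +
      ggplot2::geom_histogram(bins = 40, fill = "steelblue", colour = "white") +
      ggplot2::geom_vline(xintercept = unname(object$percentiles), linetype = c("dotted", "dashed", "dotted")) +
      ggplot2::labs(
        title = sprintf("Monte-Carlo distribution of %s (%d replicates, seed %d)",
                        object$target, object$replicates, object$seed),
        x = "Output (USD)", y = "Replicates"
      )
  }
}
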