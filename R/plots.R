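#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a standard-addition fit
#'
#' Linearized blend points with the fitted least-squares line; the intercept
#' at x = 0 carries the sample signal, the slope the reference additions.
#'
#' @param object An [fit_addition()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.addition_fit <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_abline(intercept = object$a0, slope = object$a1,
                         colour = "steelblue") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = expression(m[z] / m[x]),
      y = expression((m[y] / m[x]) %.% r),
      title = sprintf("a0 = %.4f, a1 = %.4f, a0/a1 = %.4f, r² = %.4f",
                      object$a0, object$a1, object$a0 / object$a1, object$r2)
    )
}

#' Plot a Monte Carlo output distribution
#'
#' Histogram of the retained draws for one output with the 2.5/50/97.5
#' percentiles marked; run [monte_carlo()] with `retain_samples = TRUE`.
#'
#' @param object An [monte_carlo()] result with retained samples.
#' @param output Which output to plot (default: the first).
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mcs_result <- function(object, output = NULL, bins = 60, ...) {
  if (is.null(object$samples)) {
    stop("no retained samples; rerun monte_carlo() with retain_samples = TRUE",
         call. = FALSE)
  }
  output <- output %||% colnames(object$samples)[1]
  s <- tibble::tibble(value = object$samples[, output])
  qs <- object$summary[object$summary$output == output, ]
  ggplot2::ggplot(s, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = c(qs$q2.5, qs$median, qs$q97.5),
                        linetype = c("dashed", "solid", "dashed"),
                        colour = "steelblue") +
    ggplot2::labs(x = output, y = "draws",
                  title = sprintf("%s: median %.4g, 95%% interval [%.4g, %.4g]",
                                  output, qs$median, qs$q2.5, qs$q97.5))
}

#' Plot a GUM budget
#'
#' Contribution indices (shares of the combined variance) per input, one
#' panel per model output.
#'
#' @param object A [gum_budget()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gum_budget <- function(object, ...) {
  ggplot2::ggplot(object$terms,
                  ggplot2::aes(x = stats::reorder(.data$term, .data$index),
                               y = .data$index)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~output) +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::labs(x = NULL, y = "contribution index")
}
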