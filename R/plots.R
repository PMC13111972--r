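# ggplot2 views of the three result types: offset scores, the null fit,
# and the simulation study.

#' Plot alignment score against offset
#'
#' Scatter plot of every enumerated offset's score; offsets significant
#' under the Gumbel null (when p-values are present) are highlighted. The
#' two isolated high points of a length-variant heterozygote stand out
#' against the flat baseline.
#'
#' @param object A [rank_offsets()] tibble (p-values optional).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tp_offsets <- function(object, ...) {
  df <- as_tibble(object)
  df$significant <- if (all(is.na(df$p_value))) FALSE else {
    thr <- 0.05 / nrow(df)
    !is.na(df$p_value) & df$p_value < thr
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$offset, y = .data$score)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$significant), size = 1.5) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "red"),
                                 guide = "none") +
    ggplot2::labs(x = "offset (forward start in reverse coordinates)",
                  y = paste0("alignment score (", df$scheme[1], ")")) +
    ggplot2::theme_minimal()
}

#' Plot the shuffle null with the fitted Gumbel curves
#'
#' Histogram of the shuffled alignment scores with the moment-matched Gumbel
#' density and its upper-tail function overlaid; observed offset scores can
#' be added as a rug to spot outliers.
#'
#' @param object A [fit_gumbel()] object.
#' @param ranked Optional [rank_offsets()] tibble whose scores are drawn as
#'   a rug.
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gumbel_fit <- function(object, ranked = NULL, bins = 30L, ...) {
  h <- null_histogram(object, bins = bins)
  p <- ggplot2::ggplot(h) +
    ggplot2::geom_col(ggplot2::aes(x = .data$mid, y = .data$density),
                      width = h$upper - h$lower, fill = "grey80",
                      colour = "grey60") +
    ggplot2::geom_line(ggplot2::aes(x = .data$mid, y = .data$fit_density),
                       colour = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(x = .data$mid,
                                    y = .data$fit_tail * max(.data$density)),
                       colour = "firebrick", linetype = "dashed") +
    ggplot2::labs(x = "alignment score", y = "density",
                  subtitle = "Gumbel fit (solid) and scaled tail function (dashed)") +
    ggplot2::theme_minimal()
  if (!is.null(ranked)) {
    p <- p + ggplot2::geom_rug(data = as_tibble(ranked),
                               ggplot2::aes(x = .data$score),
                               inherit.aes = FALSE)
  }
  p
}

#' @rdname autoplot.tp_offsets
#' @export
autoplot.trace_report <- function(object, ...) {
  autoplot(object$ranked) +
    ggplot2::labs(title = sprintf("Outcome: %s (%d outlier(s))",
                                  object$outcome$category,
                                  object$outcome$n_outliers))
}

#' Plot offset-recovery proportions from a simulation study
#'
#' One line per scoring scheme, proportion of correctly detected offset
#' pairs against template length, faceted by GC fraction and error rate,
#' line type by padding.
#'
#' @param object A [run_study()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tp_study <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$L, y = .data$prop_correct,
                                   colour = .data$scheme,
                                   linetype = factor(.data$padding))) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_grid(ggplot2::vars(.data$gc), ggplot2::vars(.data$error_rate),
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "template length (bp)",
                  y = "proportion of correct offset pairs",
                  linetype = "padding") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
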