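# ggplot2 methods for result types.

#' Plot a haplogroup frequency table
#'
#' Stacked per-group bars of category fractions.
#'
#' @param object A `frequency_table` from [frequency_table()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.frequency_table <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$group, y = .data$fraction,
                               fill = .data$category)) +
    ggplot2::geom_col(width = 0.7) +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = NULL, y = "fraction of records",
                  fill = "haplogroup") +
    ggplot2::theme_minimal()
}

#' Plot a maternal-ancestry partition
#'
#' @param object An `admixture_estimate` from [ancestry_partition()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.admixture_estimate <- function(object, ...) {
  long <- tibble(
    ancestry = factor(c("south_asian", "west_eurasian", "sub_saharan", "other"),
                      levels = c("south_asian", "west_eurasian",
                                 "sub_saharan", "other")),
    fraction = c(object$south_asian, object$west_eurasian,
                 object$sub_saharan, object$other)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = "", y = .data$fraction,
                                     fill = .data$ancestry)) +
    ggplot2::geom_col(width = 0.5) +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = NULL, y = "fraction of maternal lineages") +
    ggplot2::theme_minimal()
}

#' Plot a dating report
#'
#' Point estimates with 95% CIs, in thousands of years.
#'
#' @param report Tibble from [date_clades()] (or a bound set of
#'   [tidy()] rows from [estimate_age()]).
#' @return A ggplot.
#' @export
plot_dating <- function(report) {
  ggplot2::ggplot(report,
                  ggplot2::aes(x = .data$t_years / 1000, y = .data$clade)) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_lower / 1000,
                                         xmax = .data$ci_upper / 1000),
                            height = 0.15) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "age (kya)", y = NULL) +
    ggplot2::theme_minimal()
}
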