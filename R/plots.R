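#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   geom_pointrange facet_wrap labs theme_minimal scale_y_continuous
#'   position_dodge
#' @export
ggplot2::autoplot

#' Item-probability profile plot of a measurement fit
#'
#' Line-and-point profile of the class-conditional service probabilities,
#' the standard display for comparing utilization classes.
#'
#' @param object An `mlca_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mlca_fit <- function(object, ...) {
  d <- tidy(object)
  d$indicator <- factor(d$indicator, levels = unique(d$indicator))
  ggplot(d, aes(x = .data$indicator, y = .data$probability,
                colour = .data$class, group = .data$class)) +
    geom_line() +
    geom_point(size = 2) +
    scale_y_continuous(limits = c(0, 1)) +
    labs(x = NULL, y = "P(service received | class)", colour = "Class") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Information-criterion curves from a class-count sweep
#'
#' @param object An `mlca_selection`.
#' @param criterion Which column to plot (default the selection's own).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mlca_selection <- function(object, criterion = NULL, ...) {
  crit <- criterion %||% switch(object$criterion, AIC = "AIC", BIC = "BIC_low",
                                ICL = "ICL_BIC_high")
  d <- object$table
  d$M <- factor(d$M)
  ggplot(d, aes(x = .data$K, y = .data[[crit]], colour = .data$M, group = .data$M)) +
    geom_line() +
    geom_point() +
    labs(x = "Individual-level classes (K)", y = crit,
         colour = "Country-level\nclasses (M)") +
    theme_minimal()
}

#' Point-and-interval display of an equity table
#'
#' @param equity Tibble from [equity_table()] or rows of
#'   [cluster_bootstrap_ci()] output (needs `dimension` column).
#' @return A ggplot.
#' @export
plot_equity <- function(equity) {
  ggplot(equity, aes(x = .data$measure, y = .data$estimate,
                     ymin = .data$CI_low, ymax = .data$CI_high)) +
    geom_pointrange(position = position_dodge(width = 0.4)) +
    facet_wrap(~ dimension, scales = "free_y") +
    labs(x = NULL, y = "Estimate (95% bootstrap CI)") +
    theme_minimal()
}
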