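#' Plot a hybrid forecast comparison
#'
#' Line plot of the verification window: observed values against the rolling
#' one-step forecasts of the plain and the refined model.
#'
#' @param object `hybrid_forecast` from [hybrid_pipeline()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hybrid_forecast <- function(object, ...) {
  long <- tidyr_pivot(object$forecasts)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$step, y = .data$value,
                                     colour = .data$series, linetype = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "verification step", y = "value", colour = NULL, linetype = NULL,
                  title = "Rolling one-step forecasts over the verification window") +
    ggplot2::theme_minimal()
}

tidyr_pivot <- function(fc) {
  dplyr::bind_rows(
    tibble(step = fc$step, value = fc$actual, series = "actual"),
    tibble(step = fc$step, value = fc$arima, series = "arima"),
    tibble(step = fc$step, value = fc$hybrid, series = "hybrid")
  )
}

#' Plot the refinement error trace
#'
#' Round-by-round mean absolute error of the steepest-descent coefficient
#' refinement.
#'
#' @param object `hybrid_refit` from [refine_arima()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hybrid_refit <- function(object, ...) {
  ggplot2::ggplot(object$trace, ggplot2::aes(x = .data$round, y = .data$mae)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "iteration round", y = "round MAE",
                  title = "Refinement error convergence") +
    ggplot2::theme_minimal()
}

#' Plot an adaptive-filter fit trace
#'
#' @param object `adaptive_filter` from [fit_adaptive_filter()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.adaptive_filter <- function(object, ...) {
  ggplot2::ggplot(object$trace, ggplot2::aes(x = .data$round, y = .data$mae)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "iteration round", y = "round MAE",
                  title = "LMS weight-search convergence") +
    ggplot2::theme_minimal()
}

#' Plot an order-selection grid
#'
#' Criterion values as a tile map over the (p, q) grid, with the selected
#' cell outlined.
#'
#' @param object `order_grid` from [select_order()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.order_grid <- function(object, ...) {
  df <- tidy(object)
  df$criterion[!is.finite(df$criterion)] <- NA_real_
  ggplot2::ggplot(df, ggplot2::aes(x = .data$q, y = .data$p, fill = .data$criterion)) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(data = df[df$selected, ], fill = NA, colour = "red", linewidth = 1) +
    ggplot2::scale_y_reverse(breaks = unique(df$p)) +
    ggplot2::scale_x_continuous(breaks = unique(df$q), position = "top") +
    ggplot2::labs(title = sprintf("%s grid (red = selected)", toupper(object$criterion))) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
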