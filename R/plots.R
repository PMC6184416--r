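#' @export
autoplot.sensitivity_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$factor, .data$importance),
    y = .data$importance
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(0, .data$importance - .data$sd_across_restarts),
                   ymax = .data$importance + .data$sd_across_restarts),
      width = 0.25
    ) +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "Mean Garson importance",
      title = sprintf("Connection-weight sensitivity (%d restarts)",
                      object$n_restarts)
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.learning_curve <- function(object, ...) {
  df <- tidyr::pivot_longer(object, c("train_mse", "cv_mse"),
                            names_to = "set", values_to = "mse")
  df$set <- c(train_mse = "training", cv_mse = "cross-validation")[df$set]
  ggplot2::ggplot(df, ggplot2::aes(.data$n_train, .data$mse,
                                   colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Training-set size", y = "Mean squared error",
                  colour = NULL, title = "Learning curve") +
    ggplot2::theme_minimal()
}

#' Bar chart of a dimensional expenditure table
#'
#' @param table A tibble with a grouping column first and an `expenditure`
#'   or `cce` column.
#' @param units Axis label units.
#' @return A ggplot object.
#' @export
plot_dimension <- function(table, units = "RMB") {
  value_col <- intersect(c("expenditure", "cce"), names(table))[1]
  group_col <- names(table)[1]
  ggplot2::ggplot(table, ggplot2::aes(
    x = stats::reorder(.data[[group_col]], .data[[value_col]]),
    y = .data[[value_col]]
  )) +
    ggplot2::geom_col(fill = "darkseagreen4") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = sprintf("Curative care expenditure (%s)",
                                        units)) +
    ggplot2::theme_minimal()
}
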