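# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a context coverage profile
#'
#' Per-position read counts (`c_m`) across the context window, the quantity
#' the coverage score summarises.
#'
#' @param object A [coverage_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.coverage_profile <- function(object, ...) {
  df <- tibble(position = seq(object$window_start,
                              object$window_end - 1L),
               c_m = object$cov)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$c_m)) +
    ggplot2::geom_area(fill = "grey70") +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::labs(x = "genomic position (bp)", y = "reads per position") +
    ggplot2::theme_minimal()
}

#' Plot mapping accuracy
#'
#' Exact and relaxed accuracy per read class; when the evaluation was binned
#' by expression level, one panel per coverage bin.
#'
#' @param object An `eval_result` from [evaluate_mapping()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.eval_result <- function(object, ...) {
  df <- tidy(object) |>
    tidyr::pivot_longer(c("exact_accuracy", "relaxed_accuracy"),
                        names_to = "measure", values_to = "accuracy") |>
    dplyr::mutate(measure = sub("_accuracy", "", .data$measure))
  p <- ggplot2::ggplot(
    df[is.na(df$bin), ],
    ggplot2::aes(x = .data$class, y = .data$accuracy, fill = .data$measure)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "read class", y = "accuracy", fill = NULL) +
    ggplot2::theme_minimal()
  if (any(!is.na(df$bin))) {
    p <- ggplot2::ggplot(
      df[!is.na(df$bin), ],
      ggplot2::aes(x = factor(.data$bin), y = .data$accuracy,
                   fill = .data$measure)) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::facet_wrap(~class) +
      ggplot2::scale_y_continuous(limits = c(0, 1)) +
      ggplot2::labs(x = "expression bin (1 = lowest coverage)",
                    y = "accuracy", fill = NULL) +
      ggplot2::theme_minimal()
  }
  p
}
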