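#' Plot ROC curves
#'
#' Draws one or more ROC curves in the conventional unit square with the
#' chance diagonal. Accepts a `rate_table` (possibly row-bound across
#' procedures), an `roc_curve`, or any data frame with `F` and `H` columns;
#' curves are grouped and coloured by procedure, rule and lineup size when
#' those columns are present.
#'
#' @param rates Data frame with `F` and `H` (and optionally `criterion`,
#'   `procedure`, `rule`, `lineup_size`).
#' @param f_limit Optional upper limit for the false-alarm axis (e.g. 0.2 to
#'   zoom on the policy-relevant low-F region).
#' @return A ggplot object.
#' @export
plot_roc <- function(rates, f_limit = NULL) {
  stopifnot(all(c("F", "H") %in% names(rates)))
  df <- tibble::as_tibble(rates)
  label_cols <- intersect(c("procedure", "rule", "lineup_size"), names(df))
  df$curve <- if (length(label_cols)) {
    interaction(df[label_cols], drop = TRUE, sep = " / ")
  } else {
    factor("ROC")
  }
  if ("criterion" %in% names(df)) {
    df <- dplyr::arrange(df, .data$curve, dplyr::desc(.data$criterion))
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$F, y = .data$H,
                                        colour = .data$curve)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey60") +
    ggplot2::geom_path(linewidth = 0.6) +
    ggplot2::coord_cartesian(xlim = c(0, if (is.null(f_limit)) 1 else f_limit),
                             ylim = c(0, 1)) +
    ggplot2::labs(x = "False alarm rate (innocent-suspect IDs)",
                  y = "Hit rate (guilty-suspect IDs)", colour = NULL) +
    ggplot2::theme_minimal()
  p
}

#' @rdname plot_roc
#' @param object An `roc_curve` object.
#' @param ... Unused.
#' @export
autoplot.roc_curve <- function(object, ...) {
  plot_roc(object)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot information-gain curves
#'
#' Information gain (posterior probability of guilt minus base rate) after a
#' suspect identification (solid) and after a non-identification (dashed),
#' across the target-present base rate, one colour per (d', offset) family.
#'
#' @param curves A `bayes_curve` tibble from [information_gain_curve()]
#'   (row-bind several for multi-family plots).
#' @return A ggplot object.
#' @export
plot_information_gain <- function(curves) {
  stopifnot(all(c("base_rate", "gain_id", "gain_no_id") %in% names(curves)))
  df <- tibble::as_tibble(curves) |>
    dplyr::mutate(family = sprintf("d' = %g, k = %+g", .data$d_prime, .data$k)) |>
    tidyr::pivot_longer(c("gain_id", "gain_no_id"),
                        names_to = "response", values_to = "gain") |>
    dplyr::mutate(response = dplyr::recode(.data$response,
                                           gain_id = "suspect ID",
                                           gain_no_id = "no ID"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$base_rate, y = .data$gain,
                                   colour = .data$family,
                                   linetype = .data$response)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_line(linewidth = 0.6) +
    ggplot2::labs(x = "Base rate of target-present lineups",
                  y = "Information gain", colour = NULL, linetype = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_information_gain
#' @param object A `bayes_curve` object.
#' @param ... Unused.
#' @export
autoplot.bayes_curve <- function(object, ...) {
  plot_information_gain(object)
}

#' Plot diagnosticity against response bias at fixed accuracy
#'
#' One curve per AUC level from [diagnosticity_bias_curves()]; along each
#' curve true accuracy is constant while the diagnosticity ratio varies with
#' the bias statistic `c` alone.
#'
#' @param curves Output of [diagnosticity_bias_curves()].
#' @param x Bias axis: the signal-detection statistic `"c"` or the false
#'   alarm rate `"F"`.
#' @return A ggplot object.
#' @export
plot_diagnosticity <- function(curves, x = c("c", "F")) {
  x <- match.arg(x)
  stopifnot(all(c("auc", "D", x) %in% names(curves)))
  ggplot2::ggplot(tibble::as_tibble(curves),
                  ggplot2::aes(x = .data[[x]], y = .data$D,
                               colour = factor(.data$auc))) +
    ggplot2::geom_line(linewidth = 0.6) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = if (x == "c") "Response bias c (conservative →)" else
                    "False alarm rate",
                  y = "Diagnosticity ratio H/F (log scale)",
                  colour = "AUC") +
    ggplot2::theme_minimal()
}
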