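#' Plot a Pareto front
#'
#' Ultimate stress against energy absorption, colored by SA/VR, shaped by
#' surface family.
#'
#' @param object A `pareto_front` (from [optimize_group()]).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pareto_front <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$ultimate_stress,
                               y = .data$energy_absorption,
                               colour = .data$sa_vr,
                               shape = .data$surface_type)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Ultimate stress U (MPa)",
                  y = expression("Energy absorption EA (MJ/m"^3*")"),
                  colour = "SA/VR (1/mm)", shape = "Type",
                  title = paste("Pareto front,", object$size_class[1], "implants")) +
    ggplot2::theme_minimal()
}

#' Plot surrogate loss curves
#'
#' Training and validation MSE per epoch.
#'
#' @param object A fitted `tpms_surrogate`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tpms_surrogate <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$epoch, y = .data$loss,
                               colour = .data$partition)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Epoch", y = "MSE (z-scored targets)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Boxplot-style group comparison of a property
#'
#' @param dataset Tibble with `size_class` and the property column.
#' @param property Column name to compare.
#' @return A ggplot.
#' @export
plot_group_property <- function(dataset, property) {
  ggplot2::ggplot(dataset,
                  ggplot2::aes(x = .data$size_class, y = .data[[property]],
                               fill = .data$size_class)) +
    ggplot2::geom_boxplot(outlier.alpha = 0.4, show.legend = FALSE) +
    ggplot2::labs(x = "Implant size group", y = property) +
    ggplot2::theme_minimal()
}

#' Plot an OFAT sensitivity curve
#'
#' @param curve Output of [ofat_sensitivity()].
#' @return A ggplot.
#' @export
plot_sensitivity <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$value, y = .data$response)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = curve$feature[1], y = "Predicted response") +
    ggplot2::theme_minimal()
}

#' Beeswarm-style attribution summary plot
#'
#' Per-sample Shapley values by feature, ordered by mean absolute
#' attribution, colored by the (numeric) feature value.
#'
#' @param summary Output of [summary_attributions()].
#' @return A ggplot.
#' @export
plot_attributions <- function(summary) {
  att <- summary$attributions %>%
    dplyr::mutate(feature = factor(.data$feature,
                                   levels = rev(summary$ranking$feature)))
  ggplot2::ggplot(att, ggplot2::aes(x = .data$phi, y = .data$feature,
                                    colour = .data$feature_value)) +
    ggplot2::geom_jitter(height = 0.2, width = 0, alpha = 0.7) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, linewidth = 0.3) +
    ggplot2::labs(x = "Shapley value (target units)", y = NULL,
                  colour = "Feature value") +
    ggplot2::theme_minimal()
}
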