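# ggplot2 autoplot methods for the package's result objects.

#' Plot an ECDF difference curve with its KS confidence band
#'
#' @param object an [ecdf_difference()] result.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot ecdf_diff
#' @export
autoplot.ecdf_diff <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$value,
                                             y = .data$delta)) +
    ggplot2::geom_hline(yintercept = c(-object$band, object$band),
                        linetype = "dotted") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_step() +
    ggplot2::labs(
      x = "value", y = expression(Delta ~ "ECDF"),
      title = sprintf("ECDF difference (D = %.3f, %d%% KS band = %.3f)",
                      object$D, round(100 * object$confidence),
                      object$band)) +
    ggplot2::theme_minimal()
}

#' Plot a ROC curve
#'
#' @param object a [roc_curve()] result.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot speck_roc
#' @export
autoplot.speck_roc <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("ROC (AUC = %.1f%%)",
                                  100 * attr(object, "auc"))) +
    ggplot2::theme_minimal()
}

#' Plot a denaturation fit
#'
#' Observed counts, the fitted exponential decay, and the N0/e level at
#' c_e.
#'
#' @param object a [fit_denaturation()] result.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot denat_fit
#' @export
autoplot.denat_fit <- function(object, ...) {
  grid <- tibble::tibble(
    conc_M = seq(min(object$data$conc_M), max(object$data$conc_M),
                 length.out = 100))
  grid$count <- predict(object, grid)
  p <- ggplot2::ggplot(object$data, ggplot2::aes(x = .data$conc_M,
                                                 y = .data$count)) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "denaturant concentration (M)",
                  y = "aggregates per FOV") +
    ggplot2::theme_minimal()
  if (object$decaying) {
    p <- p +
      ggplot2::geom_hline(yintercept = object$n0 / exp(1),
                          linetype = "dotted") +
      ggplot2::geom_vline(xintercept = object$c_e, linetype = "dotted") +
      ggplot2::labs(title = sprintf("c_e = %.3g M (count falls to N0/e)",
                                    object$c_e))
  }
  p
}

#' Plot the threshold-search grid
#'
#' Heatmap of the group fraction difference over the (area, circularity)
#' threshold grid, with the selected cell marked.
#'
#' @param object a [threshold_search()] result.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot morph_threshold
#' @export
autoplot.morph_threshold <- function(object, ...) {
  ggplot2::ggplot(object$grid,
                  ggplot2::aes(x = .data$area_max, y = .data$circ_min,
                               fill = .data$delta_f)) +
    ggplot2::geom_tile() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::annotate("point", x = object$area_max, y = object$circ_min,
                      shape = 4, size = 3, stroke = 1.2) +
    ggplot2::labs(x = expression("area threshold (" * mu * m^2 * ")"),
                  y = "circularity threshold",
                  fill = expression(Delta * "fraction"),
                  title = sprintf(
                    "Selected: area <= %.3g, circularity >= %.2f (p = %.3g)",
                    object$area_max, object$circ_min, object$p_value)) +
    ggplot2::theme_minimal()
}

#' Scatter plot of aggregate morphology
#'
#' Area versus circularity of segmented aggregates, optionally coloured
#' by group, with optional threshold guides.
#'
#' @param aggregates tibble with `area_um2` and `circularity` (and
#'   optionally `group`).
#' @param area_max,circ_min optional threshold guides to draw.
#' @return A ggplot.
#' @export
plot_morphology <- function(aggregates, area_max = NULL, circ_min = NULL) {
  aes <- if ("group" %in% names(aggregates)) {
    ggplot2::aes(x = .data$area_um2, y = .data$circularity,
                 colour = .data$group)
  } else {
    ggplot2::aes(x = .data$area_um2, y = .data$circularity)
  }
  p <- ggplot2::ggplot(aggregates, aes) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression("area (" * mu * m^2 * ")"),
                  y = "circularity") +
    ggplot2::theme_minimal()
  if (!is.null(area_max)) {
    p <- p + ggplot2::geom_vline(xintercept = area_max, linetype = "dotted")
  }
  if (!is.null(circ_min)) {
    p <- p + ggplot2::geom_hline(yintercept = circ_min, linetype = "dotted")
  }
  p
}
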