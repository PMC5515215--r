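# ggplot2 visualisations for the main result types.

#' @describeIn fit_first_order Plot the observed series with the fitted
#'   decay curve.
#' @param object A `kinetic_fit` with retained data.
#' @method autoplot kinetic_fit
#' @export
autoplot.kinetic_fit <- function(object, ...) {
  if (is.null(object$data) || object$status == "failed") {
    abort("nothing to plot: fit failed or carries no data")
  }
  d <- object$data
  grid <- tibble(time_h = seq(min(d$time_h), max(d$time_h), length.out = 200))
  grid$fit <- if (object$order == 1) {
    object$c0_hat * exp(-object$rate_k * grid$time_h)
  } else {
    pmax(0, object$c0_hat - object$rate_k * grid$time_h)
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_h, y = .data$concentration)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$fit),
                       colour = "steelblue") +
    ggplot2::labs(
      x = "Time (h)", y = "Concentration (µM)",
      title = sprintf("Order-%d fit: t½ = %.2f h, R² = %.3f",
                      object$order, object$half_life, object$r_squared)
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn fit_calibration Plot the calibration points, fitted line and
#'   LOD/LOQ markers.
#' @param object A `calibration_curve`.
#' @method autoplot calibration_curve
#' @export
autoplot.calibration_curve <- function(object, ...) {
  if (object$status != "ok") abort("cannot plot a failed calibration")
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$level_ugL, y = .data$area)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         colour = "steelblue") +
    ggplot2::geom_vline(xintercept = c(object$lod, object$loq),
                        linetype = c("dotted", "dashed"),
                        colour = "firebrick") +
    ggplot2::labs(x = "Standard concentration (µg/l)", y = "Peak area",
                  title = sprintf("LOD %.3g, LOQ %.3g µg/l",
                                  object$lod, object$loq)) +
    ggplot2::theme_minimal()
}

#' @describeIn correlate_community Heatmap of the correlation matrix with
#'   taxa ordered by the complete-linkage dendrogram (green positive, red
#'   negative) and significance stars.
#' @param object A `community_correlation`.
#' @method autoplot community_correlation
#' @export
autoplot.community_correlation <- function(object, ...) {
  ord <- if (nrow(object$r) >= 2) cluster_taxa(object)$leaf_order else
    rownames(object$r)
  long <- tidy(object) |>
    mutate(taxon = factor(.data$taxon, levels = rev(ord)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$ahl, y = .data$taxon,
                                     fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$stars), size = 2.5) +
    ggplot2::scale_fill_gradient2(low = "red", mid = "black",
                                  high = "green", limits = c(-1, 1),
                                  na.value = "grey80") +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 6))
}

#' Bar chart of isolate QS/QQ category percentages
#'
#' @param summary Output of [summarize_categories()].
#' @return A ggplot.
#' @export
plot_category_summary <- function(summary) {
  assert_columns(summary, c("producer_any", "quencher_any", "both", "neither"),
                 "summary")
  long <- summary |>
    select("producer_any", "quencher_any", "both", "neither") |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "category",
                        values_to = "percent")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$category, y = .data$percent)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f%%", .data$percent)),
                       vjust = -0.3, size = 3) +
    ggplot2::labs(x = NULL, y = "Isolates (%)") +
    ggplot2::theme_minimal()
}
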