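# ggplot2 views of the main result types

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an in vitro-in vivo regression
#'
#' Scatter of `E_in vivo` against `E_predict` with the fitted line;
#' the excluded outlier, if any, is drawn hollow and labelled.
#'
#' @param object A `fibro_ivivc` fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fibro_ivivc <- function(object, ...) {
  d <- object$data |>
    mutate(excluded = .data$drug_id %in% object$excluded_drug)
  ggplot2::ggplot(d, ggplot2::aes(.data$e_predict, .data$e_invivo)) +
    ggplot2::geom_abline(
      intercept = object$intercept, slope = object$slope,
      linetype = 2, colour = "grey40"
    ) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$excluded), size = 2.5) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1), guide = "none") +
    ggplot2::geom_text(
      data = d[d$excluded, , drop = FALSE],
      ggplot2::aes(label = .data$drug_id),
      vjust = -1, size = 3
    ) +
    ggplot2::labs(
      x = "E_predict", y = "E_in vivo",
      subtitle = sprintf("R² = %.2f (n = %d)", object$r_squared, object$n_points)
    ) +
    ggplot2::theme_minimal()
}

#' Plot the variance profile of a SAUC PCA
#'
#' @param object A `fibro_pca` object.
#' @param ... Unused.
#' @return A ggplot object (scree plot with cumulative variance line).
#' @export
autoplot.fibro_pca <- function(object, ...) {
  d <- tidy.fibro_pca(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$component, .data$variance_ratio)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_line(ggplot2::aes(y = .data$cumulative_variance)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$cumulative_variance)) +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::labs(x = "Principal component", y = "Variance explained") +
    ggplot2::theme_minimal()
}

#' Plot per-marker weight frequencies of the rho = 1 set
#'
#' Stacked view of how often each weight value occurs among the weight
#' vectors achieving perfect rank concordance — the evidence behind each
#' marker's modal (optimised) weight.
#'
#' @param weights A `fibro_weights` object.
#' @return A ggplot object.
#' @export
plot_weight_frequency <- function(weights) {
  d <- tidy.fibro_weights(weights) |>
    pivot_longer(c("n_weight_0", "n_weight_1", "n_weight_2"),
      names_to = "w", values_to = "count"
    ) |>
    mutate(w = sub("n_weight_", "", .data$w))
  ggplot2::ggplot(d, ggplot2::aes(.data$marker, .data$count, fill = .data$w)) +
    ggplot2::geom_col(position = "fill") +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::labs(x = NULL, y = "Share of rho = 1 vectors", fill = "Weight") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot KR dose-response series for one drug
#'
#' KR versus concentration, one line per feature, facetted by marker —
#' the line-plot equivalent of the per-drug KR heatmap.
#'
#' @param profile KR profile from [compute_kr_profile()].
#' @param drug Drug id to display.
#' @return A ggplot object.
#' @export
plot_kr_profile <- function(profile, drug) {
  d <- profile |> filter(.data$drug_id == !!drug)
  if (nrow(d) == 0) abort(paste0("Drug '", drug, "' not in profile."))
  ggplot2::ggplot(d, ggplot2::aes(.data$concentration_um, .data$kr,
    group = .data$feature
  )) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey80") +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::facet_wrap(~marker) +
    ggplot2::scale_x_continuous(trans = "log1p") +
    ggplot2::coord_cartesian(ylim = c(-1, 1)) +
    ggplot2::labs(
      x = "Concentration (µM)", y = "KR",
      title = drug
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-group marker intensity summaries
#'
#' Boxplot-style view of [group_intensity_summary()] output: one box per
#' efficacy group and marker, whiskers at 1.5 x IQR.
#'
#' @param summary Output of [group_intensity_summary()].
#' @return A ggplot object.
#' @export
plot_group_summary <- function(summary) {
  ggplot2::ggplot(summary, ggplot2::aes(x = .data$marker)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
      width = 0.2, colour = "grey50"
    ) +
    ggplot2::geom_crossbar(
      ggplot2::aes(y = .data$median, ymin = .data$q1, ymax = .data$q3),
      fill = "grey85", width = 0.6
    ) +
    ggplot2::facet_wrap(~group, ncol = 1) +
    ggplot2::labs(x = NULL, y = "Mean intensity KR") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
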