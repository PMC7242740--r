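#' @import ggplot2
NULL

#' Effect-size heatmap data and plot
#'
#' `delta_heatmap_data()` reshapes a [response_report()] into the patients x
#' treatments matrix of OMI-index Glass's delta values, marking cells at or
#' above the responder cutoff (the asterisk convention);
#' `plot_delta_heatmap()` renders it. The data twin contains exactly the
#' plotted numbers and can be written as the CSV companion of the figure.
#'
#' @param report A [response_report()] tibble.
#' @param endpoint Endpoint to display (default `"omi_index"`).
#' @param threshold Marking cutoff (default 0.75).
#' @return `delta_heatmap_data()`: tibble `patient_id`, `treatment`,
#'   `timepoint_h`, `glass_delta`, `marked`. `plot_delta_heatmap()`: a
#'   ggplot object.
#' @export
delta_heatmap_data <- function(report, endpoint = "omi_index",
                               threshold = 0.75) {
  report |>
    dplyr::filter(.data$endpoint == !!endpoint) |>
    dplyr::transmute(.data$patient_id, .data$treatment, .data$timepoint_h,
                     .data$glass_delta, marked = .data$glass_delta >= threshold)
}

#' @rdname delta_heatmap_data
#' @export
plot_delta_heatmap <- function(report, endpoint = "omi_index",
                               threshold = 0.75) {
  d <- delta_heatmap_data(report, endpoint, threshold)
  ggplot(d, aes(x = .data$treatment, y = .data$patient_id,
                fill = .data$glass_delta)) +
    geom_tile(color = "grey30") +
    geom_text(aes(label = ifelse(.data$marked, "*", "")), size = 6,
              vjust = 0.75) +
    scale_fill_gradient2(low = "#2166AC", mid = "white", high = "#B2182B",
                         midpoint = 0, name = "Glass's Δ") +
    labs(x = "Treatment", y = "Patient",
         title = sprintf("OMI index effect size (* Δ ≥ %.2f)",
                         threshold)) +
    theme_minimal()
}

#' Overlaid control vs. treated subpopulation densities
#'
#' Evaluates both mixtures' area-normalized density curves on a common grid
#' and overlays them, annotating each group with its selected subpopulation
#' count (the bracketed-number convention). `density_comparison_data()` is
#' the CSV twin.
#'
#' @param control_model,treated_model `omihet_gmm` fits.
#' @param labels Group labels.
#' @return `density_comparison_data()`: tibble `group`, `x`, `component`,
#'   `density`, `g`; `plot_density_comparison()`: a ggplot object.
#' @export
density_comparison_data <- function(control_model, treated_model,
                                    labels = c("control", "treated")) {
  s1 <- sqrt(control_model$V); s2 <- sqrt(treated_model$V)
  lo <- min(control_model$mu - 8 * s1, treated_model$mu - 8 * s2)
  hi <- max(control_model$mu + 8 * s1, treated_model$mu + 8 * s2)
  grid <- seq(lo, hi, length.out = 512)
  dplyr::bind_rows(
    dplyr::mutate(density_curves(control_model, grid), group = labels[1],
                  g = control_model$g),
    dplyr::mutate(density_curves(treated_model, grid), group = labels[2],
                  g = treated_model$g))
}

#' @rdname density_comparison_data
#' @export
plot_density_comparison <- function(control_model, treated_model,
                                    labels = c("control", "treated")) {
  d <- density_comparison_data(control_model, treated_model, labels)
  totals <- dplyr::filter(d, .data$component == "total")
  comps <- dplyr::filter(d, .data$component != "total")
  ann <- totals |>
    dplyr::group_by(.data$group, .data$g) |>
    dplyr::summarise(x = .data$x[which.max(.data$density)],
                     density = max(.data$density), .groups = "drop")
  ggplot(totals, aes(x = .data$x, y = .data$density, color = .data$group)) +
    geom_line(data = comps,
              aes(group = interaction(.data$group, .data$component)),
              linetype = "dashed", linewidth = 0.4, alpha = 0.7) +
    geom_line(linewidth = 1) +
    geom_text(data = ann, aes(label = sprintf("[%d]", .data$g)),
              vjust = -0.5, show.legend = FALSE) +
    labs(x = "OMI index", y = "Normalized density", color = NULL) +
    theme_minimal()
}

#' @rdname delta_heatmap_data
#' @param object An `omihet_gmm` (for `autoplot`).
#' @param ... Unused.
#' @method autoplot omihet_gmm
#' @export
autoplot.omihet_gmm <- function(object, ...) {
  d <- density_curves(object)
  ggplot(dplyr::filter(d, .data$component == "total"),
         aes(x = .data$x, y = .data$density)) +
    geom_line(data = dplyr::filter(d, .data$component != "total"),
              aes(group = .data$component), linetype = "dashed",
              alpha = 0.7) +
    geom_line(linewidth = 1) +
    labs(x = "value", y = "density",
         title = sprintf("Gaussian mixture (g = %d)", object$g)) +
    theme_minimal()
}
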