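#' Density plot of pseudo-maturation scores, control vs perturbed
#'
#' @param comparison a [score_and_compare()] result.
#' @param scaled plot min-max scaled scores instead of raw.
#' @return A ggplot.
#' @export
plot_pseudotime_density <- function(comparison, scaled = TRUE) {
  stopifnot(inherits(comparison, "pseudotime_comparison"))
  col <- if (scaled) "scaled_score" else "raw_score"
  ggplot2::ggplot(
    comparison$scores,
    ggplot2::aes(x = .data[[col]], fill = .data$group)
  ) +
    ggplot2::geom_density(alpha = 0.4) +
    ggplot2::labs(
      x = if (scaled) "pseudotime (scaled to control)" else "pseudotime score",
      y = "density",
      subtitle = sprintf(
        "shift = %.3f, p = %.2g", comparison$shift, comparison$p_value
      )
    ) +
    ggplot2::theme_minimal()
}

#' Bar plot of per-cell-type perturbation AUCs
#'
#' @param scores a [score_cell_types()] tibble.
#' @return A ggplot.
#' @export
plot_celltype_auc <- function(scores) {
  ggplot2::ggplot(
    dplyr::filter(scores, !.data$skipped),
    ggplot2::aes(
      x = factor(.data$cell_type, levels = unique(.data$cell_type)),
      y = .data$auc
    )
  ) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "cross-validated AUC") +
    ggplot2::theme_minimal()
}

#' Mean laminar bin distribution with SEM error bars
#'
#' @param bins a [bin_positions()] result.
#' @return A ggplot.
#' @export
plot_bin_distribution <- function(bins) {
  ggplot2::ggplot(
    bins$summary,
    ggplot2::aes(x = factor(.data$bin), y = .data$mean_frequency)
  ) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data$mean_frequency - .data$sem,
        ymax = .data$mean_frequency + .data$sem
      ),
      width = 0.3
    ) +
    ggplot2::labs(x = "bin (WM -> pial)", y = "mean frequency") +
    ggplot2::theme_minimal()
}

#' Spatial plot of migration tracks coloured by morphology
#'
#' @param tracks a `track_set`.
#' @param max_tracks cap on plotted tracks for legibility.
#' @return A ggplot.
#' @export
plot_tracks <- function(tracks, max_tracks = 50) {
  df <- tibble::as_tibble(tracks)
  ids <- head(unique(df$cell_id), max_tracks)
  df <- dplyr::filter(df, .data$cell_id %in% ids)
  p <- ggplot2::ggplot(
    df,
    ggplot2::aes(
      x = .data$x_um, y = .data$y_um, group = .data$cell_id,
      colour = .data$morphology
    )
  ) +
    ggplot2::geom_path(alpha = 0.6) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um, pial side up)") +
    ggplot2::theme_minimal()
  roi <- attr(tracks, "roi")
  if (!is.null(roi)) {
    p <- p + ggplot2::annotate(
      "rect",
      xmin = roi$xmin, xmax = roi$xmax, ymin = roi$ymin, ymax = roi$ymax,
      fill = NA, colour = "black", linetype = "dashed"
    )
  }
  p
}
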