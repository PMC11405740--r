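#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot cluster centroid trajectories
#'
#' Centroid pupil trajectories (z-units) across the task, with level
#' boundaries and deceptive-feedback cells shaded when a schedule is
#' supplied.
#'
#' @param object A `pupil_kmeans`.
#' @param schedule Optional `task_schedule` for block/deception annotation.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pupil_kmeans
#' @export
autoplot.pupil_kmeans <- function(object, schedule = NULL, ...) {
  cent <- tibble::as_tibble(t(object$centroids), .name_repair = "minimal") |>
    rlang::set_names(paste0("cluster ", seq_len(object$k) - 1L)) |>
    dplyr::mutate(trial = dplyr::row_number() - 1L) |>
    tidyr::pivot_longer(-"trial", names_to = "cluster", values_to = "value")
  p <- ggplot2::ggplot(cent, ggplot2::aes(.data$trial, .data$value,
                                          color = .data$cluster))
  if (!is.null(schedule)) {
    win <- level_windows(schedule)
    shade <- win[win$deceptive, ]
    if (nrow(shade) > 0) {
      p <- p + ggplot2::geom_rect(
        data = shade,
        ggplot2::aes(xmin = .data$first_trial, xmax = .data$last_trial,
                     ymin = -Inf, ymax = Inf),
        inherit.aes = FALSE, fill = "grey85"
      )
    }
    blocks <- win$first_trial[win$level == 1][-1]
    if (length(blocks) > 0) {
      p <- p + ggplot2::geom_vline(xintercept = blocks, linetype = "dashed",
                                   color = "grey55")
    }
  }
  p + ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "trial", y = "normalized pupil size (z)",
                  color = NULL,
                  title = "Cluster centroid pupil trajectories") +
    ggplot2::theme_minimal()
}

#' Effect-size profile of a comparison report
#'
#' Plots the per-segment effect size (d on the parametric branch, rank-
#' biserial correlation otherwise) for selected metrics from a
#' [report_levels()] or [report_blocks()] table, marking segments
#' significant at `alpha`.
#'
#' @param report A comparison report tibble.
#' @param metrics Metrics to show (default: all in the report).
#' @param alpha Significance threshold for the marker.
#' @return A ggplot.
#' @export
plot_effects <- function(report, metrics = unique(report$metric), alpha = 0.05) {
  df <- report |>
    dplyr::filter(.data$metric %in% metrics) |>
    dplyr::mutate(
      effect = dplyr::coalesce(.data$d, .data$rbc),
      segment = if ("level" %in% names(report)) {
        sprintf("B%dL%d", .data$block, .data$level)
      } else {
        sprintf("B%d", .data$block)
      },
      significant = .data$p_value < alpha
    )
  ggplot2::ggplot(df, ggplot2::aes(.data$segment, .data$effect)) +
    ggplot2::geom_hline(yintercept = 0, color = "grey60") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$significant)) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1)) +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::labs(x = NULL, y = "effect size (d or RBC, cluster 1 vs 0)",
                  shape = sprintf("p < %.2g", alpha)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
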