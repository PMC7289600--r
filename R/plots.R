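#' Plot single-cell ratio traces
#'
#' Spaghetti plot of per-cell (normalized or raw) ratio traces with the
#' per-condition mean overlaid and the stimulus time marked.
#'
#' @param traces Long tibble with `cell_id`, `time_min`, `ratio` and
#'   optionally `condition`.
#' @param stim_time_min Stimulus time to mark (minutes); omit for none.
#' @return A ggplot object.
#' @export
plot_traces <- function(traces, stim_time_min = NULL) {
  if (!"condition" %in% names(traces)) traces$condition <- "all"
  mean_tr <- traces |>
    dplyr::group_by(.data$condition, .data$time_min) |>
    dplyr::summarise(ratio = mean(.data$ratio), .groups = "drop")
  p <- ggplot2::ggplot(traces,
                       ggplot2::aes(.data$time_min, .data$ratio,
                                    group = .data$cell_id)) +
    ggplot2::geom_line(alpha = 0.25, linewidth = 0.3, colour = "grey40") +
    ggplot2::geom_line(data = mean_tr,
                       ggplot2::aes(group = .data$condition),
                       colour = "firebrick", linewidth = 1) +
    ggplot2::facet_wrap(~condition) +
    ggplot2::labs(x = "time (min)", y = "emission ratio (R/R0)") +
    ggplot2::theme_minimal()
  if (!is.null(stim_time_min)) {
    p <- p + ggplot2::geom_vline(xintercept = stim_time_min,
                                 linetype = "dashed", colour = "steelblue")
  }
  p
}

#' Plot per-cell metric distributions by condition
#'
#' Jittered per-cell values with the condition mean and SEM overlaid — the
#' standard presentation for single-cell response metrics such as SAM40.
#'
#' @param table Per-cell tibble with `condition` and the metric column.
#' @param metric Metric column name (string).
#' @return A ggplot object.
#' @export
plot_population <- function(table, metric = "sam40") {
  summ <- summarize_population(table, metric)
  ggplot2::ggplot(table, ggplot2::aes(.data$condition, .data[[metric]])) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 1) +
    ggplot2::geom_pointrange(
      data = summ,
      ggplot2::aes(.data$condition, .data$mean,
                   ymin = .data$mean - .data$sem,
                   ymax = .data$mean + .data$sem),
      colour = "firebrick", linewidth = 1) +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_minimal()
}

#' @describeIn build_kymograph Display a kymograph as a distance-time
#'   raster (micrometres against minutes).
#' @param object A `fret_kymograph`.
#' @param ... Unused.
#' @export
autoplot.fret_kymograph <- function(object, ...) {
  px <- attr(object, "pixel_size_um")
  dt <- attr(object, "frame_interval_s") / 60
  df <- tidyr::expand_grid(i = seq_len(nrow(object)),
                           t = seq_len(ncol(object)))
  df$value <- object[cbind(df$i, df$t)]
  ggplot2::ggplot(df, ggplot2::aes((.data$i - 1) * px, (.data$t - 1) * dt,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(guide = "none") +
    ggplot2::labs(x = "distance (µm)", y = "time (min)") +
    ggplot2::theme_minimal()
}
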