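# ggplot2 visualization methods for the main result types.

#' @export
autoplot.melspec <- function(object, db_floor = -60, ...) {
  m <- unclass(object)
  ref <- max(m)
  df <- tidyr::expand_grid(band = seq_len(nrow(m)),
                           frame = seq_len(ncol(m))) |>
    dplyr::mutate(db = 20 * log10(pmax(m[cbind(.data$band, .data$frame)] /
                                         max(ref, 1e-12), 10^(db_floor / 20))),
                  time = attr(object, "frame_times")[.data$frame])
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$band,
                                   fill = .data$db)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "dB") +
    ggplot2::labs(x = "time (s)", y = "mel band") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.f0_contour <- function(object, ...) {
  ggplot2::ggplot(dplyr::filter(object, .data$voiced),
                  ggplot2::aes(.data$time, .data$f0_hz)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::labs(x = "time (s)", y = "f0 (Hz)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.k_selection <- function(object, ...) {
  df <- tidyr::pivot_longer(object$curve, c("silhouette", "inertia"),
                            names_to = "metric")
  ggplot2::ggplot(df, ggplot2::aes(.data$k, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = object$k_best, linetype = "dashed") +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "k", y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.dist_matrix <- function(object, ...) {
  df <- tidy(object)
  df2 <- dplyr::bind_rows(
    df,
    dplyr::rename(df, item1 = "item2", item2 = "item1"),
    tibble(item1 = rownames(object), item2 = rownames(object), distance = 0)
  )
  ggplot2::ggplot(df2, ggplot2::aes(.data$item1, .data$item2,
                                    fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = attr(object, "kind")) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.group_contrast <- function(object, ...) {
  ggplot2::ggplot(object$pairs, ggplot2::aes(.data$group, .data$distance)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(x = NULL, y = "DTW distance") +
    ggplot2::theme_minimal()
}

#' Plot a DTW alignment path over its cost matrix
#'
#' @param result A `dtw_result` from [dtw_distance()].
#' @param d The local-cost matrix the result was computed from.
#' @return A ggplot object.
#' @export
plot_dtw_path <- function(result, d) {
  df <- tidyr::expand_grid(i = seq_len(nrow(d)), j = seq_len(ncol(d))) |>
    dplyr::mutate(cost = d[cbind(.data$i, .data$j)])
  path <- tibble(i = result$path[, 1], j = result$path[, 2])
  ggplot2::ggplot(df, ggplot2::aes(.data$j, .data$i)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$cost)) +
    ggplot2::geom_path(data = path, color = "red") +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "frames of Y", y = "frames of X") +
    ggplot2::theme_minimal()
}
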