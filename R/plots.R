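#' Plot tracked trajectories
#'
#' Paths of all animals over the pen, coloured by identity, in image
#' coordinates (y axis reversed so the origin is top-left, matching the
#' video).
#'
#' @param object A trajectory tibble from [track_sequence()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pentrack_traj
#' @export
autoplot.pentrack_traj <- function(object, ...) {
  fs <- attr(object, "frame_size")
  p <- ggplot2::ggplot(
    tibble::as_tibble(object),
    ggplot2::aes(x = .data$x, y = .data$y, colour = factor(.data$animal))
  ) +
    ggplot2::geom_path(alpha = 0.8) +
    ggplot2::geom_point(
      data = function(d) d[d$supervised, , drop = FALSE],
      shape = 4, size = 3, colour = "black"
    ) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      x = "x (px)", y = "y (px)", colour = "animal",
      title = "Tracked trajectories",
      subtitle = "crosses mark human supervision events"
    )
  if (!is.null(fs)) {
    p <- p + ggplot2::expand_limits(x = c(0, fs[["W"]]), y = c(0, fs[["H"]]))
  }
  p
}

#' Plot a spatial activity heat map
#'
#' @param object A heat map from [activity_heatmap()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pentrack_heatmap
#' @export
autoplot.pentrack_heatmap <- function(object, ...) {
  m <- unclass(object)
  df <- tibble::tibble(
    x = rep(seq_len(ncol(m)) - 1, each = nrow(m)),
    y = rep(seq_len(nrow(m)) - 1, times = ncol(m)),
    activity = as.vector(m)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$activity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(option = "inferno") +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      x = "x (px)", y = "y (px)", fill = "activity",
      title = "Spatial activity heat map"
    )
}

#' Plot per-frame and accumulated movement
#'
#' @param traj Trajectory tibble.
#' @param ids Animal ids to include (default: all).
#' @return A ggplot object of accumulated movement over time.
#' @export
plot_movement <- function(traj, ids = NULL) {
  traj <- validate_trajectories(traj)
  if (is.null(ids)) ids <- sort(unique(traj$animal))
  acc <- dplyr::bind_rows(lapply(ids, function(a) {
    dplyr::mutate(accumulated_movement(traj, a), animal = a)
  }))
  ggplot2::ggplot(
    acc,
    ggplot2::aes(.data$frame, .data$accumulated, colour = factor(.data$animal))
  ) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "frame", y = "accumulated movement (px)", colour = "animal",
      title = "Accumulated movement"
    )
}

#' Plot the inter-animal distance series
#'
#' @inheritParams pairwise_distance
#' @return A ggplot object.
#' @export
plot_distance <- function(traj, id_a = 0, id_b = 1, scale = NULL) {
  d <- pairwise_distance(traj, id_a, id_b, scale)
  unit <- if (is.null(scale)) "px" else "cm"
  ggplot2::ggplot(d, ggplot2::aes(.data$frame, .data$distance)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(
      x = "frame", y = paste0("distance (", unit, ")"),
      title = sprintf("Distance between animals %d and %d", id_a, id_b)
    )
}
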