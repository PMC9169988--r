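#' Tidy a tracked trajectory
#'
#' Returns the trajectory as a plain tibble, one row per frame per animal.
#'
#' @param x A trajectory tibble from [track_sequence()].
#' @param ... Unused.
#' @return A tibble with columns `frame`, `animal`, `x`, `y`,
#'   `confidence`, `supervised`.
#' @method tidy pentrack_traj
#' @export
tidy.pentrack_traj <- function(x, ...) {
  tibble::as_tibble(x[, c("frame", "animal", "x", "y", "confidence", "supervised")])
}

#' One-row summary of a tracking run
#'
#' @param x A trajectory tibble from [track_sequence()].
#' @param ... Unused.
#' @return A one-row tibble: `n_frames`, `n_animals`, `n_supervisions`,
#'   `mean_confidence`, `frac_lost` (fraction of rows below the
#'   confidence floor, when the tracker config is attached).
#' @method glance pentrack_traj
#' @export
glance.pentrack_traj <- function(x, ...) {
  floor <- attr(x, "config")$confidence_floor
  lost <- if (is.null(floor)) NA_real_ else mean(x$confidence < floor, na.rm = TRUE)
  tibble::tibble(
    n_frames = length(unique(x$frame)),
    n_animals = length(unique(x$animal)),
    n_supervisions = count_supervisions(x),
    mean_confidence = mean(x$confidence, na.rm = TRUE),
    frac_lost = lost
  )
}

#' @export
print.track_state <- function(x, ...) {
  cat(sprintf(
    "<track_state> animal %d at (%.1f, %.1f), confidence %.3f%s\n",
    x$animal, x$center[1], x$center[2], x$confidence,
    if (isTRUE(x$lost)) " [LOST]" else ""
  ))
  invisible(x)
}

#' @export
print.tracker_config <- function(x, ...) {
  cat(sprintf(
    "<tracker_config> %s, box %dx%d px, search radius %d px, floor %.2f\n",
    x$tracker, x$box[1], x$box[2], x$search_radius, x$confidence_floor
  ))
  invisible(x)
}

#' @export
print.calibration_scale <- function(x, ...) {
  cat(sprintf(
    "<calibration_scale> %.4g cm per standardized unit (%.4g cm/px over a %.4g px diagonal)\n",
    x$cm_per_standardized_unit, x$cm_per_px, x$frame_diagonal_px
  ))
  invisible(x)
}

#' @export
print.pen_scene <- function(x, ...) {
  cat(sprintf(
    "<pen_scene> %d x %d px, %d frames @ %g fps, %d agents, %d noise events, seed %d\n",
    x$frame_size[1], x$frame_size[2], x$n_frames, x$fps, length(x$agents),
    if (is.null(x$noise_events)) 0L else nrow(x$noise_events), x$seed
  ))
  invisible(x)
}
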