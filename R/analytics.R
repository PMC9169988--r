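#' Centimeter calibration for standardized errors
#'
#' Tracking errors are standardized by the frame diagonal, so a single
#' scalar converts them to centimeters for a fixed camera geometry. The
#' default (262.9 cm per standardized unit, i.e., 26.29 cm per 0.1) is the
#' calibration for an 848 x 480 camera mounted 2.25 m above the pen; it is
#' a configuration value, not estimated from images.
#'
#' @param cm_per_standardized_unit Centimeters per unit of standardized
#'   error (default 262.9).
#' @param frame_size Frame `c(W, H)` in pixels (default `c(848, 480)`).
#' @return List of class `calibration_scale` with
#'   `cm_per_standardized_unit`, `frame_diagonal_px`, `cm_per_px`.
#' @export
calibration_scale <- function(cm_per_standardized_unit = 262.9,
                              frame_size = c(848, 480)) {
  stopifnot(cm_per_standardized_unit > 0, all(frame_size > 0))
  diag_px <- sqrt(sum(frame_size^2))
  structure(
    list(
      cm_per_standardized_unit = cm_per_standardized_unit,
      frame_diagonal_px = diag_px,
      cm_per_px = cm_per_standardized_unit / diag_px
    ),
    class = "calibration_scale"
  )
}

#' Convert standardized error to centimeters
#'
#' Linear in the error: `error * cm_per_standardized_unit`.
#'
#' @param error Standardized error(s), >= 0.
#' @param scale A [calibration_scale()].
#' @return Centimeters, same length as `error`.
#' @examples
#' to_cm(0.1) # 26.29 with the default calibration
#' @export
to_cm <- function(error, scale = calibration_scale()) {
  stopifnot(inherits(scale, "calibration_scale"), all(error >= 0))
  error * scale$cm_per_standardized_unit
}

#' Standardized tracking error against ground truth
#'
#' Per-frame, per-animal Euclidean distance between predicted and true
#' centres, divided by the frame diagonal `sqrt(W^2 + H^2)`. The result is
#' dimensionless in `[0, 1]` (both points in-frame) and comparable across
#' resolutions.
#'
#' @param pred Predicted trajectory tibble.
#' @param truth Ground-truth tibble (same schema; `confidence` and
#'   `supervised` optional).
#' @param frame_size Frame `c(W, H)` in pixels; taken from
#'   `attr(pred, "frame_size")` when omitted.
#' @return Tibble with `frame`, `animal`, `error` (standardized).
#' @export
standardized_error <- function(pred, truth, frame_size = NULL) {
  pred <- validate_trajectories(pred)
  if (is.null(frame_size)) frame_size <- attr(pred, "frame_size")
  if (is.null(frame_size)) stop("`frame_size` required", call. = FALSE)
  truth <- validate_trajectories(truth)
  j <- dplyr::full_join(
    dplyr::select(tibble::as_tibble(pred), "frame", "animal", px = "x", py = "y"),
    dplyr::select(tibble::as_tibble(truth), "frame", "animal", tx = "x", ty = "y"),
    by = c("frame", "animal")
  )
  bad <- is.na(j$px) | is.na(j$tx)
  if (any(bad)) {
    miss <- j[bad, c("frame", "animal")]
    stop(
      "trajectory/ground-truth mismatch at (frame, animal): ",
      paste(sprintf("(%d, %d)", head(miss$frame, 5), head(miss$animal, 5)),
        collapse = ", "
      ),
      call. = FALSE
    )
  }
  diag_px <- sqrt(sum(as.numeric(frame_size)^2))
  dplyr::transmute(j,
    frame = .data$frame, animal = .data$animal,
    error = sqrt((.data$px - .data$tx)^2 + (.data$py - .data$ty)^2) / diag_px
  )
}

lost_frames <- function(traj, id) {
  floor <- attr(traj, "config")$confidence_floor
  rows <- traj[traj$animal == id, ]
  if (is.null(floor)) {
    return(rep(FALSE, nrow(rows)))
  }
  !is.na(rows$confidence) & rows$confidence < floor
}

traj_animal <- function(traj, id) {
  traj <- validate_trajectories(traj)
  rows <- dplyr::arrange(traj[traj$animal == id, ], .data$frame)
  if (nrow(rows) == 0) stop("unknown animal: ", id, call. = FALSE)
  rows
}

#' Inter-animal distance series
#'
#' Per-frame Euclidean distance between two animals' tracked centres — the
#' basic proximity signal for social-interaction studies. Distances are in
#' pixels, or centimeters when a [calibration_scale()] is supplied. Frames
#' where either tracker was lost are returned as `NA`.
#'
#' @param traj Trajectory tibble.
#' @param id_a,id_b Animal ids.
#' @param scale Optional [calibration_scale()] for centimeter output.
#' @return Tibble with `frame`, `distance`.
#' @export
pairwise_distance <- function(traj, id_a, id_b, scale = NULL) {
  a <- traj_animal(traj, id_a)
  b <- traj_animal(traj, id_b)
  if (!identical(a$frame, b$frame)) {
    stop("animals ", id_a, " and ", id_b, " do not cover the same frames",
      call. = FALSE
    )
  }
  d <- sqrt((a$x - b$x)^2 + (a$y - b$y)^2)
  if (!is.null(scale)) {
    stopifnot(inherits(scale, "calibration_scale"))
    d <- d * scale$cm_per_px
  }
  d[lost_frames(traj, id_a) | lost_frames(traj, id_b)] <- NA_real_
  tibble::tibble(frame = a$frame, distance = d)
}

#' Per-frame movement of one animal
#'
#' Euclidean displacement of the tracked centre between consecutive frames
#' (length `T - 1`); its sum is the animal's total path length, a proxy for
#' individual activity.
#'
#' @inheritParams pairwise_distance
#' @param id Animal id.
#' @return Tibble with `frame` (the step's starting frame) and `movement`
#'   in px.
#' @export
movement_per_frame <- function(traj, id) {
  rows <- traj_animal(traj, id)
  if (nrow(rows) < 2) stop("need at least 2 frames", call. = FALSE)
  mv <- sqrt(diff(rows$x)^2 + diff(rows$y)^2)
  lost <- lost_frames(traj, id)
  mv[lost[-length(lost)] | lost[-1]] <- NA_real_
  tibble::tibble(frame = rows$frame[-nrow(rows)], movement = mv)
}

#' Accumulated movement of one animal
#'
#' Running sum of [movement_per_frame()]; the final value is the total path
#' length over the clip.
#'
#' @inheritParams movement_per_frame
#' @return Tibble with `frame`, `movement`, `accumulated`.
#' @export
accumulated_movement <- function(traj, id) {
  mv <- movement_per_frame(traj, id)
  filled <- tidyr::replace_na(mv$movement, 0)
  dplyr::mutate(mv, accumulated = cumsum(filled))
}

#' Movement synchrony between two animals
#'
#' Sample Pearson correlation of the two per-frame movement series, with
#' the two-sided p-value from the t transform. Frames where either series
#' is missing (lost tracker) are excluded pairwise. A positive r indicates
#' the animals tend to move (and rest) at the same times.
#'
#' @inheritParams pairwise_distance
#' @return One-row tibble with `estimate` (r), `p.value`, `n` (frames
#'   used).
#' @export
movement_correlation <- function(traj, id_a, id_b) {
  ma <- movement_per_frame(traj, id_a)$movement
  mb <- movement_per_frame(traj, id_b)$movement
  keep <- !is.na(ma) & !is.na(mb)
  ma <- ma[keep]
  mb <- mb[keep]
  if (length(ma) < 3) stop("need at least 3 paired movement values", call. = FALSE)
  if (var(ma) == 0 || var(mb) == 0) {
    stop("degenerate movement series (zero variance)", call. = FALSE)
  }
  ct <- cor.test(ma, mb, method = "pearson")
  tibble::tibble(
    estimate = unname(ct$estimate), p.value = ct$p.value, n = length(ma)
  )
}

#' Spatial activity heat map
#'
#' Per-pixel variation of intensity across all frames, min-max scaled to
#' `[0, 1]`: bright regions are the pen hot spots the animals visit and
#' stir most. Variation is the per-pixel variance by default, or the mean
#' absolute deviation with `method = "mad"`. A constant map (e.g., a static
#' video) scales to all zeros.
#'
#' @param seq A [frame_sequence()] with at least 2 frames.
#' @param method `"variance"` (default) or `"mad"`.
#' @return `H x W` matrix in `[0, 1]` of class `pentrack_heatmap`.
#' @export
activity_heatmap <- function(seq, method = c("variance", "mad")) {
  stopifnot(inherits(seq, "frame_sequence"))
  method <- match.arg(method)
  T <- length(seq$frames)
  if (T < 2) stop("cannot compute variation of one frame", call. = FALSE)
  m <- Reduce(`+`, seq$frames) / T
  if (method == "variance") {
    acc <- Reduce(`+`, lapply(seq$frames, function(f) (f - m)^2)) / (T - 1)
  } else {
    acc <- Reduce(`+`, lapply(seq$frames, function(f) abs(f - m))) / T
  }
  rng <- range(acc)
  out <- if (diff(rng) > 0) (acc - rng[1]) / diff(rng) else acc * 0
  structure(out, class = c("pentrack_heatmap", "matrix"))
}

#' Summarize tracking precision against ground truth
#'
#' Convenience wrapper combining [standardized_error()] with the
#' centimeter calibration: per-animal and overall mean/median errors in
#' standardized units, pixels, and centimeters.
#'
#' @inheritParams standardized_error
#' @param scale A [calibration_scale()]; its `cm_per_px` uses `frame_size`.
#' @return Tibble with one row per animal plus an `"all"` row: `animal`,
#'   `mean_std`, `median_std`, `mean_px`, `median_px`, `mean_cm`,
#'   `median_cm`, `n_frames`.
#' @export
evaluate_tracking <- function(pred, truth, frame_size = NULL, scale = NULL) {
  pred <- validate_trajectories(pred)
  if (is.null(frame_size)) frame_size <- attr(pred, "frame_size")
  err <- standardized_error(pred, truth, frame_size)
  diag_px <- sqrt(sum(as.numeric(frame_size)^2))
  if (is.null(scale)) scale <- calibration_scale(frame_size = frame_size)
  summarize_one <- function(e, label) {
    tibble::tibble(
      animal = label,
      mean_std = mean(e), median_std = median(e),
      mean_px = mean(e) * diag_px, median_px = median(e) * diag_px,
      mean_cm = to_cm(mean(e), scale), median_cm = to_cm(median(e), scale),
      n_frames = length(e)
    )
  }
  per <- dplyr::group_modify(
    dplyr::group_by(err, .data$animal),
    ~ summarize_one(.x$error, as.character(.y$animal))[, -1]
  )
  per$animal <- as.character(per$animal)
  dplyr::bind_rows(dplyr::ungroup(per), summarize_one(err$error, "all"))
}
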