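#' Tracker configuration
#'
#' The trackers need only two user-facing parameters: the starting
#' positions (one per animal) and the size of the bounding box covering the
#' tracked body area. Everything else has conservative defaults.
#'
#' @param tracker `"template_ncc"` (fixed-template normalized
#'   cross-correlation), `"sparse_flow"` (sparse optical flow with
#'   median-displacement aggregation), or the name of a tracker registered
#'   with [register_tracker()].
#' @param box Bounding-box size `c(w, h)` in pixels (each >= 3). Should
#'   cover diverse body texture (contour edges) for best performance.
#' @param search_radius Search window radius in pixels; default
#'   `max(box)`, so an animal moving less than one box per frame stays in
#'   the window at low frame rates.
#' @param confidence_floor Confidence below which a tracker is flagged
#'   lost and frozen until a supervision event (default 0.5).
#' @param template_alpha Exponential template-update rate in `[0, 1)`;
#'   0 (default) keeps the drift-free fixed initial template.
#' @param n_points Feature points per box for `sparse_flow` (default 25).
#' @return A list of class `tracker_config`.
#' @export
tracker_config <- function(tracker = c("template_ncc", "sparse_flow"),
                           box = c(31, 31), search_radius = NULL,
                           confidence_floor = 0.5, template_alpha = 0,
                           n_points = 25) {
  if (is.character(tracker) && length(tracker) == 1 &&
    !tracker %in% c("template_ncc", "sparse_flow")) {
    if (!tracker %in% ls(.tracker_registry)) {
      stop("unknown tracker: ", tracker, call. = FALSE)
    }
  } else {
    tracker <- match.arg(tracker)
  }
  box <- as.integer(round(box))
  if (length(box) == 1) box <- c(box, box)
  if (any(box < 3)) stop("box size must be >= 3 px", call. = FALSE)
  if (is.null(search_radius)) search_radius <- max(box)
  if (search_radius < 1) stop("search_radius must be >= 1", call. = FALSE)
  if (confidence_floor < 0 || confidence_floor > 1) {
    stop("confidence_floor must be in [0, 1]", call. = FALSE)
  }
  structure(
    list(
      tracker = tracker, box = box, search_radius = as.integer(search_radius),
      confidence_floor = confidence_floor, template_alpha = template_alpha,
      n_points = n_points
    ),
    class = "tracker_config"
  )
}

.tracker_registry <- new.env(parent = emptyenv())

#' Register an external tracker adapter
#'
#' Third-party trackers (e.g., correlation-filter or multiple-instance
#' trackers) attach through the same contract as the built-ins: an `init`
#' function `(frame, center, config, animal_id) -> state` and a `step`
#' function `(state, frame, config) -> state`, where `state` is a list with
#' at least `center` (c(x, y)), `confidence` in `[0, 1]`, and `lost`.
#' [track_sequence()] then runs unchanged with `tracker = name`.
#'
#' @param name Adapter name.
#' @param init,step Functions implementing the contract.
#' @return Invisibly, `name`.
#' @export
register_tracker <- function(name, init, step) {
  stopifnot(is.character(name), is.function(init), is.function(step))
  assign(name, list(init = init, step = step), envir = .tracker_registry)
  invisible(name)
}

box_crop <- function(frame, center, box) {
  H <- nrow(frame)
  W <- ncol(frame)
  hw <- box[1] %/% 2
  hh <- box[2] %/% 2
  cx <- round(center[1])
  cy <- round(center[2])
  c0 <- max(0, cx - hw)
  c1 <- min(W - 1, cx + hw)
  r0 <- max(0, cy - hh)
  r1 <- min(H - 1, cy + hh)
  list(
    crop = frame[(r0 + 1):(r1 + 1), (c0 + 1):(c1 + 1), drop = FALSE],
    off_r = r0 - cy, off_c = c0 - cx
  )
}

#' Initialize a tracker at a starting position
#'
#' Captures the tracker payload from the bounding box around `center`: the
#' template crop for `template_ncc`, a grid of high-gradient feature points
#' for `sparse_flow`. Boxes extending past the frame are clipped.
#'
#' @param frame `H x W` intensity matrix.
#' @param center Starting position `c(x, y)` (0-based pixels), inside the
#'   frame.
#' @param config A [tracker_config()].
#' @param animal_id 0-based animal id.
#' @return A list of class `track_state` with `animal`, `center`, `box`,
#'   `payload`, `confidence` (1), `lost` (FALSE).
#' @export
init_tracker <- function(frame, center, config = tracker_config(), animal_id = 0L) {
  stopifnot(is.matrix(frame))
  H <- nrow(frame)
  W <- ncol(frame)
  if (center[1] < 0 || center[1] >= W || center[2] < 0 || center[2] >= H) {
    stop("start position out of bounds: (", center[1], ", ", center[2], ")",
      call. = FALSE
    )
  }
  payload <- switch(config$tracker,
    template_ncc = box_crop(frame, center, config$box),
    sparse_flow = flow_init_payload(frame, center, config),
    .tracker_registry[[config$tracker]]$init(frame, center, config, animal_id)$payload
  )
  structure(
    list(
      animal = as.integer(animal_id), center = as.numeric(center),
      box = config$box, payload = payload, confidence = 1, lost = FALSE
    ),
    class = "track_state"
  )
}

#' Advance a tracker by one frame
#'
#' `template_ncc`: places the fixed template at every offset within
#' `search_radius` of the previous centre, scores each placement by
#' normalized cross-correlation, and moves to the best match; confidence is
#' the best correlation clamped to `[0, 1]`. `sparse_flow`: advances each
#' feature point by iterative local least-squares optical flow, moves the
#' centre by the median point displacement, and reports the fraction of
#' points whose flow converged as confidence. Either way the state is
#' flagged `lost` when confidence drops below the configured floor; a lost
#' state passes through unchanged (frozen centre) until a supervision event
#' re-seeds it — it never silently re-acquires.
#'
#' @param state A `track_state` from [init_tracker()].
#' @param frame The next `H x W` intensity matrix.
#' @param config The [tracker_config()] used at initialization.
#' @return Updated `track_state`.
#' @export
step_tracker <- function(state, frame, config = tracker_config()) {
  stopifnot(inherits(state, "track_state"), is.matrix(frame))
  if (isTRUE(state$lost)) {
    return(state)
  }
  state <- switch(config$tracker,
    template_ncc = ncc_step(state, frame, config),
    sparse_flow = flow_step(state, frame, config),
    .tracker_registry[[config$tracker]]$step(state, frame, config)
  )
  H <- nrow(frame)
  W <- ncol(frame)
  state$center <- c(
    min(max(state$center[1], 0), W - 1),
    min(max(state$center[2], 0), H - 1)
  )
  state$confidence <- min(max(state$confidence, 0), 1)
  if (state$confidence < config$confidence_floor) state$lost <- TRUE
  state
}

ncc_step <- function(state, frame, config) {
  p <- state$payload
  row0 <- round(state$center[2]) + p$off_r
  col0 <- round(state$center[1]) + p$off_c
  res <- ncc_best_match(frame, p$crop, row0, col0, config$search_radius)
  state$center <- c(res[2] - p$off_c, res[1] - p$off_r)
  state$confidence <- res[3]
  if (config$template_alpha > 0) {
    new_crop <- box_crop(frame, state$center, state$box)
    if (identical(dim(new_crop$crop), dim(p$crop))) {
      state$payload$crop <- (1 - config$template_alpha) * p$crop +
        config$template_alpha * new_crop$crop
    }
  }
  state
}

# --- sparse optical flow ----------------------------------------------------

flow_init_payload <- function(frame, center, config) {
  H <- nrow(frame)
  W <- ncol(frame)
  hw <- config$box[1] %/% 2
  hh <- config$box[2] %/% 2
  g <- ceiling(sqrt(config$n_points))
  xs <- round(seq(center[1] - hw + 2, center[1] + hw - 2, length.out = g))
  ys <- round(seq(center[2] - hh + 2, center[2] + hh - 2, length.out = g))
  pts <- expand.grid(x = xs, y = ys)
  pts <- pts[pts$x >= 3 & pts$x < W - 3 & pts$y >= 3 & pts$y < H - 3, ]
  # keep the points with the strongest local gradient (trackable texture)
  score <- vapply(seq_len(nrow(pts)), function(i) {
    r <- pts$y[i] + 1
    c <- pts$x[i] + 1
    gx <- frame[r, c + 1] - frame[r, c - 1]
    gy <- frame[r + 1, c] - frame[r - 1, c]
    gx^2 + gy^2
  }, numeric(1))
  keep <- head(order(score, decreasing = TRUE), config$n_points)
  keep <- keep[score[keep] > 0]
  if (length(keep) == 0) keep <- seq_len(min(nrow(pts), config$n_points))
  list(points = as.matrix(pts[sort(keep), , drop = FALSE]), prev = frame)
}

bilinear <- function(frame, x, y) {
  # x, y are 0-based; callers keep them >= 1 px inside the frame
  x0 <- floor(x)
  y0 <- floor(y)
  fx <- x - x0
  fy <- y - y0
  r <- y0 + 1
  c <- x0 + 1
  (1 - fy) * ((1 - fx) * frame[r, c] + fx * frame[r, c + 1]) +
    fy * ((1 - fx) * frame[r + 1, c] + fx * frame[r + 1, c + 1])
}

lk_point <- function(prev, curr, x, y, half = 3, max_iter = 10) {
  H <- nrow(prev)
  W <- ncol(prev)
  if (x < half + 1 || x >= W - half - 2 || y < half + 1 || y >= H - half - 2) {
    return(list(v = c(0, 0), ok = FALSE))
  }
  dx <- seq(-half, half)
  win <- expand.grid(wx = x + dx, wy = y + dx)
  ix <- (bilinear(prev, win$wx + 1, win$wy) - bilinear(prev, win$wx - 1, win$wy)) / 2
  iy <- (bilinear(prev, win$wx, win$wy + 1) - bilinear(prev, win$wx, win$wy - 1)) / 2
  g <- matrix(c(sum(ix^2), sum(ix * iy), sum(ix * iy), sum(iy^2)), 2, 2)
  if (abs(det(g)) < 1e-6) {
    return(list(v = c(0, 0), ok = FALSE))
  }
  i0 <- bilinear(prev, win$wx, win$wy)
  v <- c(0, 0)
  step <- c(Inf, Inf)
  for (it in seq_len(max_iter)) {
    nx <- win$wx + v[1]
    ny <- win$wy + v[2]
    if (min(nx) < 1 || max(nx) >= W - 2 || min(ny) < 1 || max(ny) >= H - 2) {
      return(list(v = v, ok = FALSE))
    }
    di <- i0 - bilinear(curr, nx, ny)
    b <- c(sum(di * ix), sum(di * iy))
    step <- solve(g, b)
    v <- v + step
    if (sqrt(sum(step^2)) < 0.01) break
  }
  list(v = v, ok = sqrt(sum(step^2)) < 0.5)
}

flow_step <- function(state, frame, config) {
  p <- state$payload
  n <- nrow(p$points)
  if (is.null(n) || n == 0) {
    state$confidence <- 0
    return(state)
  }
  flows <- matrix(0, n, 2)
  ok <- logical(n)
  for (i in seq_len(n)) {
    res <- lk_point(p$prev, frame, p$points[i, 1], p$points[i, 2])
    flows[i, ] <- res$v
    ok[i] <- res$ok
  }
  state$confidence <- mean(ok)
  if (any(ok)) {
    med <- c(median(flows[ok, 1]), median(flows[ok, 2]))
    state$center <- state$center + med
    pts <- p$points
    pts[ok, ] <- pts[ok, ] + flows[ok, , drop = FALSE]
    state$payload$points <- pts
  }
  state$payload$prev <- frame
  state
}

#' Track all animals through a frame sequence
#'
#' Initializes one tracker per animal at its starting position on frame 0,
#' steps every tracker through the remaining frames, and applies human
#' supervision events: at each event the matching tracker is re-initialized
#' at the corrected centre on that frame and the row is marked supervised.
#' A tracker whose confidence falls below the floor freezes in place until
#' its next supervision event.
#'
#' @param seq A [frame_sequence()].
#' @param starts Data frame with columns `x`, `y` (one row per animal,
#'   row order = animal id), e.g., from [propose_start_points()].
#' @param config A [tracker_config()].
#' @param supervisions Optional data frame of supervision events with
#'   columns `frame`, `animal`, `x`, `y`, sorted by frame.
#' @return Trajectory tibble (see [trajectory_table()]) with `K` rows per
#'   frame and attributes `frame_size`, `config`.
#' @export
track_sequence <- function(seq, starts, config = tracker_config(),
                           supervisions = NULL) {
  stopifnot(inherits(seq, "frame_sequence"))
  starts <- tibble::as_tibble(starts)
  stopifnot(all(c("x", "y") %in% names(starts)), nrow(starts) >= 1)
  K <- nrow(starts)
  T <- length(seq$frames)
  d <- dim(seq$frames[[1]])
  if (!is.null(supervisions) && nrow(supervisions) > 0) {
    supervisions <- tibble::as_tibble(supervisions)
    if (any(supervisions$animal < 0 | supervisions$animal >= K)) {
      stop("unknown animal in supervision events", call. = FALSE)
    }
    supervisions <- dplyr::arrange(supervisions, .data$frame)
  }
  states <- lapply(seq_len(K), function(a) {
    init_tracker(seq$frames[[1]], c(starts$x[a], starts$y[a]), config, a - 1L)
  })
  rows <- vector("list", T)
  for (t in seq_len(T) - 1L) {
    frame <- seq$frames[[t + 1]]
    if (t > 0) {
      states <- lapply(states, step_tracker, frame = frame, config = config)
    }
    sup_flag <- rep(FALSE, K)
    if (!is.null(supervisions) && nrow(supervisions) > 0) {
      ev <- supervisions[supervisions$frame == t, , drop = FALSE]
      for (i in seq_len(nrow(ev))) {
        a <- ev$animal[i] + 1L
        states[[a]] <- init_tracker(frame, c(ev$x[i], ev$y[i]), config, ev$animal[i])
        sup_flag[a] <- TRUE
      }
    }
    rows[[t + 1]] <- tibble::tibble(
      frame = t, animal = seq_len(K) - 1L,
      x = vapply(states, function(s) s$center[1], numeric(1)),
      y = vapply(states, function(s) s$center[2], numeric(1)),
      confidence = vapply(states, function(s) s$confidence, numeric(1)),
      supervised = sup_flag
    )
  }
  out <- validate_trajectories(dplyr::bind_rows(rows))
  attr(out, "frame_size") <- c(W = d[2], H = d[1])
  attr(out, "config") <- config
  out
}
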