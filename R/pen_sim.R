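#' Specify a synthetic animal agent
#'
#' Agents are textured ellipses moving over a textured static background,
#' emulating the appearance of an animal body in top-view grayscale pen
#' footage. The body texture is attached to the agent (it translates
#' rigidly), giving the trackers realistic persistent appearance.
#'
#' @param center Initial centre `c(x, y)` in pixels (0-based).
#' @param axes Ellipse semi-axes `c(a, b)` in pixels (each >= 3).
#' @param orientation Body orientation in radians (fixed over the clip).
#' @param intensity Offset from the background base intensity; must
#'   contrast by at least 20 levels (negative = darker animal).
#' @param texture_amplitude Amplitude of the body texture in levels.
#' @param kinematics List: `list(type = "random_walk", sigma = 1.5)`
#'   (per-axis Gaussian step, px/frame), `list(type = "scripted",
#'   waypoints = <frame, x, y data frame>)` (linear interpolation), or
#'   `list(type = "circular", radius = , omega = )`. A random walk may
#'   carry `dash_frame`/`dash` for one scripted large jump.
#' @param max_speed Clamp on per-frame displacement, px/frame.
#' @return List of class `agent_spec`.
#' @export
agent_spec <- function(center, axes = c(16, 10), orientation = 0,
                       intensity = -60, texture_amplitude = 12,
                       kinematics = list(type = "random_walk", sigma = 1.5),
                       max_speed = 3) {
  stopifnot(length(center) == 2, length(axes) == 2)
  if (any(axes < 3)) stop("ellipse semi-axes must be >= 3 px", call. = FALSE)
  if (abs(intensity) < 20) {
    stop("agent intensity must contrast with background by >= 20 levels",
      call. = FALSE
    )
  }
  structure(
    list(
      center = as.numeric(center), axes = as.numeric(axes),
      orientation = orientation, intensity = intensity,
      texture_amplitude = texture_amplitude, kinematics = kinematics,
      max_speed = max_speed
    ),
    class = "agent_spec"
  )
}

#' Specify a synthetic pen scene
#'
#' A full description of a synthetic top-view clip: frame geometry, static
#' textured background, agents, transient noise flickers, and the seed that
#' makes rendering deterministic. Each agent consumes its own fixed-offset
#' substream of the seed, so adding an agent does not perturb the others'
#' paths.
#'
#' @param frame_size Frame `c(W, H)` in pixels, each >= 32.
#' @param n_frames Number of frames T >= 2 (default 300, a typical daily
#'   clip).
#' @param fps Frame rate (default 6).
#' @param background List with `base` intensity and `texture_amplitude`.
#' @param agents List of [agent_spec()]s; all must fit inside the frame at
#'   start.
#' @param noise_events Data frame of transient flickers with columns
#'   `frame`, `x`, `y`, `size` (square side, px), `delta` (intensity
#'   change); or NULL.
#' @param seed Integer seed.
#' @return List of class `pen_scene`.
#' @export
pen_scene <- function(frame_size = c(424, 240), n_frames = 300, fps = 6,
                      background = list(base = 150, texture_amplitude = 8),
                      agents = list(), noise_events = NULL, seed = 1) {
  stopifnot(all(frame_size >= 32), n_frames >= 2)
  W <- frame_size[1]
  H <- frame_size[2]
  for (ag in agents) {
    stopifnot(inherits(ag, "agent_spec"))
    a <- max(ag$axes)
    if (ag$center[1] - a < 0 || ag$center[1] + a >= W ||
      ag$center[2] - a < 0 || ag$center[2] + a >= H) {
      stop("agent outside pen at start", call. = FALSE)
    }
  }
  if (!is.null(noise_events)) noise_events <- tibble::as_tibble(noise_events)
  structure(
    list(
      frame_size = as.integer(frame_size), n_frames = as.integer(n_frames),
      fps = fps, background = background, agents = agents,
      noise_events = noise_events, seed = as.integer(seed)
    ),
    class = "pen_scene"
  )
}

with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

reflect_coord <- function(v, lo, hi) {
  span <- hi - lo
  v <- (v - lo) %% (2 * span)
  ifelse(v > span, 2 * span - v, v) + lo
}

agent_path <- function(ag, scene, agent_index) {
  T <- scene$n_frames
  W <- scene$frame_size[1]
  H <- scene$frame_size[2]
  kin <- ag$kinematics
  margin <- if (!is.null(kin$margin)) kin$margin else max(ag$axes) + 2
  if (kin$type == "random_walk") {
    path <- with_local_seed(scene$seed + 7919L * agent_index, {
      steps <- cbind(stats::rnorm(T - 1, 0, kin$sigma), stats::rnorm(T - 1, 0, kin$sigma))
      spd <- sqrt(rowSums(steps^2))
      too_fast <- spd > ag$max_speed
      steps[too_fast, ] <- steps[too_fast, , drop = FALSE] * (ag$max_speed / spd[too_fast])
      if (!is.null(kin$dash_frame) && kin$dash_frame <= nrow(steps)) {
        steps[kin$dash_frame, ] <- kin$dash
      }
      apply(rbind(ag$center, steps), 2, cumsum)
    })
  } else if (kin$type == "scripted") {
    wp <- kin$waypoints
    path <- cbind(
      stats::approx(wp$frame, wp$x, xout = seq_len(T) - 1, rule = 2)$y,
      stats::approx(wp$frame, wp$y, xout = seq_len(T) - 1, rule = 2)$y
    )
  } else if (kin$type == "circular") {
    th <- kin$omega * (seq_len(T) - 1)
    path <- cbind(
      ag$center[1] + kin$radius * cos(th),
      ag$center[2] + kin$radius * sin(th)
    )
  } else {
    stop("unknown kinematics type: ", kin$type, call. = FALSE)
  }
  path[, 1] <- reflect_coord(path[, 1], margin, W - 1 - margin)
  path[, 2] <- reflect_coord(path[, 2], margin, H - 1 - margin)
  path
}

agent_stamp <- function(ag, scene, agent_index) {
  a <- ag$axes[1]
  b <- ag$axes[2]
  dx <- seq(-ceiling(a), ceiling(a))
  dy <- seq(-ceiling(b), ceiling(b))
  gx <- outer(rep(1, length(dy)), dx)
  gy <- outer(dy, rep(1, length(dx)))
  u <- (gx * cos(ag$orientation) + gy * sin(ag$orientation)) / a
  v <- (-gx * sin(ag$orientation) + gy * cos(ag$orientation)) / b
  mask <- (u^2 + v^2) <= 1
  tex <- with_local_seed(scene$seed + 7919L * agent_index + 31L, {
    t0 <- matrix(stats::runif(length(mask), -1, 1), nrow(mask), ncol(mask))
    conv2_reflect(t0, matrix(1 / 9, 3, 3)) * ag$texture_amplitude * 2
  })
  list(mask = mask, tex = tex, dx = dx, dy = dy)
}

#' Render a synthetic pen scene
#'
#' Produces the frame sequence and the exact ground-truth trajectories.
#' Rendering is deterministic given the scene seed: the same scene renders
#' bit-identical frames and truth. Agents reflect off the pen walls; noise
#' events add transient square flickers for testing the noise-rejection
#' stages.
#'
#' @param scene A [pen_scene()].
#' @return List with `frames` (a [frame_sequence()]) and `truth` (a
#'   trajectory tibble of true centres, one row per frame per agent).
#' @export
render_scene <- function(scene) {
  stopifnot(inherits(scene, "pen_scene"))
  W <- scene$frame_size[1]
  H <- scene$frame_size[2]
  T <- scene$n_frames
  bg <- with_local_seed(scene$seed + 104729L, {
    t0 <- matrix(stats::runif(H * W, -1, 1), H, W)
    scene$background$base +
      conv2_reflect(t0, matrix(1 / 9, 3, 3)) * scene$background$texture_amplitude * 2
  })
  bg <- pmin(pmax(bg, 0), 255)
  K <- length(scene$agents)
  paths <- lapply(seq_len(K), function(i) agent_path(scene$agents[[i]], scene, i))
  stamps <- lapply(seq_len(K), function(i) agent_stamp(scene$agents[[i]], scene, i))
  frames <- vector("list", T)
  for (t in seq_len(T)) {
    f <- bg
    for (i in seq_len(K)) {
      ag <- scene$agents[[i]]
      st <- stamps[[i]]
      cx <- round(paths[[i]][t, 1])
      cy <- round(paths[[i]][t, 2])
      cols <- cx + st$dx + 1
      rows <- cy + st$dy + 1
      okc <- cols >= 1 & cols <= W
      okr <- rows >= 1 & rows <= H
      sub <- f[rows[okr], cols[okc], drop = FALSE]
      m <- st$mask[okr, okc, drop = FALSE]
      val <- scene$background$base + ag$intensity + st$tex[okr, okc, drop = FALSE]
      sub[m] <- val[m]
      f[rows[okr], cols[okc]] <- sub
    }
    if (!is.null(scene$noise_events)) {
      ev <- scene$noise_events[scene$noise_events$frame == t - 1, , drop = FALSE]
      for (j in seq_len(nrow(ev))) {
        half <- (ev$size[j] - 1) %/% 2
        cols <- (ev$x[j] - half):(ev$x[j] + half) + 1
        rows <- (ev$y[j] - half):(ev$y[j] + half) + 1
        cols <- cols[cols >= 1 & cols <= W]
        rows <- rows[rows >= 1 & rows <= H]
        f[rows, cols] <- f[rows, cols] + ev$delta[j]
      }
    }
    frames[[t]] <- pmin(pmax(f, 0), 255)
  }
  truth <- tidyr::expand_grid(frame = seq_len(T) - 1L, animal = seq_len(K) - 1L)
  truth$x <- purrr::map2_dbl(truth$frame, truth$animal, ~ paths[[.y + 1]][.x + 1, 1])
  truth$y <- purrr::map2_dbl(truth$frame, truth$animal, ~ paths[[.y + 1]][.x + 1, 2])
  list(
    frames = frame_sequence(frames, fps = scene$fps,
      origin_label = sprintf("pen_scene(seed=%d)", scene$seed)
    ),
    truth = validate_trajectories(truth)
  )
}

#' Standard synthetic presets
#'
#' Named scene presets exercising the pipeline end to end: `one_blob`,
#' `two_blob`, `three_blob` (calm random walks, <= 3 px/frame),
#' `two_blob_fast` (fast walks around 8-10 px/frame plus one scripted
#' 60 px dash at frame 150, which exceeds the default tracker search
#' radius and forces a tracker loss), and `noisy_two_blob` (the calm
#' two-animal scene plus 12 single-pixel transient flickers). All presets
#' are 300 frames at 424 x 240 (half of the reference 848 x 480 camera,
#' keeping tests fast) and 6 fps, with fixed seeds.
#'
#' @param name Preset name.
#' @param seed Override the preset's fixed seed (paths and textures
#'   change; geometry does not).
#' @param n_frames Override the clip length.
#' @param full_scale If TRUE, doubles geometry to the reference 848 x 480.
#' @return A [pen_scene()].
#' @export
pen_preset <- function(name = c(
                         "one_blob", "two_blob", "three_blob",
                         "two_blob_fast", "noisy_two_blob"
                       ),
                       seed = NULL, n_frames = 300, full_scale = FALSE) {
  name <- match.arg(name)
  sc <- if (full_scale) 2 else 1
  fsz <- c(424, 240) * sc
  ax <- c(16, 10) * sc
  calm <- function(center, intensity, orient, margin = NULL) {
    kin <- list(type = "random_walk", sigma = 1.5 * sc)
    if (!is.null(margin)) kin$margin <- margin
    agent_spec(center * sc,
      axes = ax, orientation = orient, intensity = intensity,
      kinematics = kin, max_speed = 3 * sc
    )
  }
  default_seed <- c(
    one_blob = 101L, two_blob = 202L, three_blob = 303L,
    two_blob_fast = 404L, noisy_two_blob = 505L
  )[[name]]
  if (is.null(seed)) seed <- default_seed
  agents <- switch(name,
    one_blob = list(calm(c(212, 120), -60, 0.3)),
    two_blob = list(calm(c(120, 120), -60, 0.3), calm(c(300, 120), -45, -0.8)),
    noisy_two_blob = list(
      calm(c(120, 120), -60, 0.3, margin = 40 * sc),
      calm(c(300, 120), -45, -0.8, margin = 40 * sc)
    ),
    three_blob = list(
      calm(c(90, 120), -60, 0.3), calm(c(212, 70), -45, -0.8),
      calm(c(330, 160), -70, 1.2)
    ),
    two_blob_fast = list(
      agent_spec(c(120, 120) * sc,
        axes = ax, orientation = 0.3, intensity = -60,
        kinematics = list(
          type = "random_walk", sigma = 6 * sc,
          dash_frame = 150, dash = c(60, 0) * sc
        ),
        max_speed = 10 * sc
      ),
      agent_spec(c(300, 120) * sc,
        axes = ax, orientation = -0.8, intensity = -45,
        kinematics = list(type = "random_walk", sigma = 6 * sc),
        max_speed = 10 * sc
      )
    )
  )
  noise <- NULL
  if (name == "noisy_two_blob") {
    noise <- with_local_seed(seed + 15485863L, tibble::tibble(
      frame = sort(sample(10:(n_frames - 10), 12)),
      x = sample(10:(fsz[1] - 10), 12),
      y = sample(c(5:25, (fsz[2] - 25):(fsz[2] - 5)), 12),
      size = 1L,
      delta = sample(c(-90, 90), 12, replace = TRUE)
    ))
  }
  pen_scene(
    frame_size = fsz, n_frames = n_frames, agents = agents,
    noise_events = noise, seed = seed
  )
}

#' @rdname pen_preset
#' @return For `standard_fixtures()`, a named list of all preset scenes.
#' @export
standard_fixtures <- function() {
  names <- c("one_blob", "two_blob", "three_blob", "two_blob_fast", "noisy_two_blob")
  setNames(lapply(names, pen_preset), names)
}
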