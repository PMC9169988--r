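#' Run the end-to-end semi-supervised tracking pipeline
#'
#' Executes the full workflow from a single configuration: obtain frames
#' (from a directory or by rendering a synthetic preset), propose starting
#' positions from motion (unless starts are given), track all animals,
#' derive the activity analytics, and — when ground truth is available —
#' evaluate precision. All artifacts are written to the output directory
#' together with a reproducible run manifest.
#'
#' Configuration keys (YAML file or list): `frames` (directory) or
#' `preset`/`seed`; `k` (number of animals); `out` (output directory);
#' optional `starts` (list of `[x, y]`), `start_frame` (proposal frame,
#' default 10), `tracker` (`kind`, `box`, `search_radius`,
#' `confidence_floor`, `template_alpha`), `motion` (`k_max`, `quantile`,
#' `deviation`), `refine` (`half_width`, `sigma`), `proposal`
#' (`connectivity_neighbors`, `min_cluster_pixels`), `supervisions` (list
#' of `{frame, animal, x, y}`), `truth` (ground-truth CSV path).
#'
#' @param config Path to a YAML configuration file, or an equivalent named
#'   list.
#' @param quiet Suppress stage logging (default FALSE).
#' @return The run manifest (list of class `pentrack_manifest`),
#'   invisibly. On failure the offending stage is named in the error and a
#'   `<out>/.partial` marker is left next to any partial outputs.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (is.null(cfg$out)) stop("config key `out` is required", call. = FALSE)
  dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
  marker <- file.path(cfg$out, ".partial")
  file.create(marker)
  log_stage <- function(stage, ...) {
    if (!quiet) message(sprintf("[%s] %s", stage, paste0(...)))
  }
  stage <- "config"
  outputs <- character()
  timings <- list()
  run_stage <- function(name, expr) {
    stage <<- name
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      stop("stage `", name, "` failed: ", conditionMessage(e), call. = FALSE)
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  truth <- NULL
  sim <- NULL
  frames <- run_stage("input", {
    if (!is.null(cfg$preset)) {
      log_stage("input", "rendering preset ", cfg$preset)
      scene <- pen_preset(cfg$preset,
        seed = cfg$seed,
        n_frames = cfg$n_frames %||% 300
      )
      sim <- render_scene(scene)
      truth <- sim$truth
      sim$frames
    } else {
      log_stage("input", "reading frames from ", cfg$frames)
      read_frames(cfg$frames, cfg$pattern %||% "*.png")
    }
  })
  if (!is.null(cfg$truth)) truth <- read_trajectories(cfg$truth)
  k <- cfg$k %||% length(unique(truth$animal))
  if (is.null(k)) stop("config key `k` is required", call. = FALSE)

  tcfg <- tracker_config(
    tracker = cfg$tracker$kind %||% "template_ncc",
    box = unlist(cfg$tracker$box %||% c(31, 31)),
    search_radius = cfg$tracker$search_radius,
    confidence_floor = cfg$tracker$confidence_floor %||% 0.5,
    template_alpha = cfg$tracker$template_alpha %||% 0
  )

  starts <- run_stage("propose", {
    if (!is.null(cfg$starts)) {
      s <- do.call(rbind, lapply(cfg$starts, as.numeric))
      tibble::tibble(animal = seq_len(nrow(s)) - 1L, x = s[, 1], y = s[, 2])
    } else {
      t0 <- cfg$start_frame %||% 10
      log_stage("propose", "proposing ", k, " start points at frame ", t0)
      st <- propose_start_points(frames, t0, k,
        k_max = cfg$motion$k_max %||% 2,
        quantile = cfg$motion$quantile %||% 0.99,
        deviation = cfg$motion$deviation %||% "absolute",
        gaussian = make_gaussian_kernel(
          cfg$refine$half_width %||% 2, cfg$refine$sigma %||% 1
        ),
        connectivity_neighbors = cfg$proposal$connectivity_neighbors %||% 5,
        min_cluster_pixels = cfg$proposal$min_cluster_pixels %||% 5
      )
      st
    }
  })

  traj <- run_stage("track", {
    sup <- NULL
    if (!is.null(cfg$supervisions)) {
      sup <- dplyr::bind_rows(lapply(cfg$supervisions, tibble::as_tibble))
    }
    log_stage("track", "tracking ", k, " animals over ", n_frames(frames), " frames")
    track_sequence(frames, starts, tcfg, supervisions = sup)
  })
  traj_path <- file.path(cfg$out, "traj.csv")
  write_trajectories(traj, traj_path)
  outputs <- c(outputs, traj_path)

  run_stage("analyze", {
    log_stage("analyze", "deriving activity analytics")
    hm <- activity_heatmap(frames)
    p <- file.path(cfg$out, "heatmap.png")
    write_map_png(unclass(hm), p)
    outputs <- c(outputs, p)
    mv <- dplyr::bind_rows(lapply(seq_len(k) - 1L, function(a) {
      dplyr::mutate(accumulated_movement(traj, a), animal = a)
    }))
    p <- file.path(cfg$out, "movement.csv")
    readr::write_csv(mv[, c("animal", "frame", "movement", "accumulated")], p)
    outputs <- c(outputs, p)
    if (k >= 2) {
      pairs <- utils::combn(seq_len(k) - 1L, 2)
      dist <- dplyr::bind_rows(lapply(seq_len(ncol(pairs)), function(j) {
        dplyr::mutate(pairwise_distance(traj, pairs[1, j], pairs[2, j]),
          animal_a = pairs[1, j], animal_b = pairs[2, j]
        )
      }))
      p <- file.path(cfg$out, "distance.csv")
      readr::write_csv(dist[, c("animal_a", "animal_b", "frame", "distance")], p)
      outputs <- c(outputs, p)
      corr <- dplyr::bind_rows(lapply(seq_len(ncol(pairs)), function(j) {
        ct <- tryCatch(movement_correlation(traj, pairs[1, j], pairs[2, j]),
          error = function(e) tibble::tibble(estimate = NA_real_, p.value = NA_real_, n = 0L)
        )
        dplyr::mutate(ct, animal_a = pairs[1, j], animal_b = pairs[2, j])
      }))
      p <- file.path(cfg$out, "correlation.csv")
      readr::write_csv(corr[, c("animal_a", "animal_b", "estimate", "p.value", "n")], p)
      outputs <- c(outputs, p)
    }
  })

  if (!is.null(truth)) {
    run_stage("evaluate", {
      log_stage("evaluate", "evaluating against ground truth")
      p <- file.path(cfg$out, "truth.csv")
      write_trajectories(truth, p)
      outputs <- c(outputs, p)
      err <- standardized_error(traj, truth)
      p <- file.path(cfg$out, "errors.csv")
      readr::write_csv(err, p)
      outputs <- c(outputs, p)
      p <- file.path(cfg$out, "evaluation.csv")
      readr::write_csv(evaluate_tracking(traj, truth), p)
      outputs <- c(outputs, p)
    })
  }

  stage <- "manifest"
  manifest <- list(
    tool = "pentrack", version = as.character(utils::packageVersion("pentrack")),
    config = cfg,
    seed = cfg$seed,
    input_checksums = as.list(tools::md5sum(traj_path)),
    outputs = basename(outputs),
    timings_s = timings,
    supervisions = count_supervisions(traj)
  )
  manifest_path <- file.path(cfg$out, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  unlink(marker)
  log_stage("done", "wrote ", length(outputs) + 1, " artifacts to ", cfg$out)
  invisible(structure(manifest, class = "pentrack_manifest"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
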