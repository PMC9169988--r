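#' Trajectory tables
#'
#' Tracking output is a tibble with one row per (frame, animal): columns
#' `frame` (0-based frame index), `animal` (0-based animal id), `x`, `y`
#' (pixel coordinates of the tracked centre, `x` along width, `y` along
#' height, origin top-left), `confidence` in `[0, 1]` (or `NA`), and
#' `supervised` (whether a human supplied this position).
#'
#' @param frame,animal Integer vectors.
#' @param x,y Numeric pixel coordinates.
#' @param confidence Numeric in `[0, 1]` or `NA`.
#' @param supervised Logical.
#' @return A tibble with class `pentrack_traj`.
#' @export
trajectory_table <- function(frame = integer(), animal = integer(),
                             x = numeric(), y = numeric(),
                             confidence = NA_real_, supervised = FALSE) {
  tbl <- tibble::tibble(
    frame = as.integer(frame), animal = as.integer(animal),
    x = as.numeric(x), y = as.numeric(y),
    confidence = as.numeric(confidence), supervised = as.logical(supervised)
  )
  validate_trajectories(tbl)
}

validate_trajectories <- function(tbl, frame_size = NULL) {
  need <- c("frame", "animal", "x", "y")
  miss <- setdiff(need, names(tbl))
  if (length(miss) > 0) {
    stop("trajectory table lacks columns: ", paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  if (!"confidence" %in% names(tbl)) tbl$confidence <- NA_real_
  if (!"supervised" %in% names(tbl)) tbl$supervised <- FALSE
  if (anyDuplicated(tbl[, c("frame", "animal")]) > 0) {
    dup <- tbl[duplicated(tbl[, c("frame", "animal")]), c("frame", "animal")]
    stop("duplicate trajectory entry: frame ", dup$frame[1], ", animal ",
      dup$animal[1],
      call. = FALSE
    )
  }
  if (!is.null(frame_size)) {
    ok <- tbl$x >= 0 & tbl$x < frame_size[1] & tbl$y >= 0 & tbl$y < frame_size[2]
    if (any(!ok, na.rm = TRUE)) {
      stop("trajectory coordinates outside frame bounds", call. = FALSE)
    }
  }
  class(tbl) <- unique(c("pentrack_traj", class(tbl)))
  tbl
}

#' Write trajectories to CSV
#'
#' Writes the standard trajectory schema (`frame,animal,x,y,confidence,`
#' `supervised`) as UTF-8 CSV with "." decimal separator and LF line
#' endings. [read_trajectories()] round-trips the table.
#'
#' @param table A trajectory tibble (see [trajectory_table()]).
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_trajectories <- function(table, path) {
  table <- validate_trajectories(table)
  out <- tibble::as_tibble(table[, c("frame", "animal", "x", "y", "confidence", "supervised")])
  readr::write_csv(out, path, eol = "\n")
  invisible(path)
}

#' Read trajectories from CSV
#'
#' @param path CSV path with the schema written by [write_trajectories()].
#'   `confidence`/`supervised` columns are optional (e.g., ground-truth
#'   tables).
#' @return A trajectory tibble.
#' @export
read_trajectories <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  names(tbl)[names(tbl) == "frame_index"] <- "frame"
  names(tbl)[names(tbl) == "animal_id"] <- "animal"
  tbl <- validate_trajectories(tbl)
  tbl$frame <- as.integer(tbl$frame)
  tbl$animal <- as.integer(tbl$animal)
  tbl$supervised <- as.logical(tbl$supervised)
  tbl
}

#' Count human supervision events in a tracked trajectory
#'
#' The number of rows whose position was supplied by a human rather than the
#' tracker; the effort metric for semi-supervised tracking (how many times a
#' person had to step in to complete the clip).
#'
#' @param table A trajectory tibble.
#' @return Integer count of supervised rows.
#' @export
count_supervisions <- function(table) {
  table <- validate_trajectories(table)
  sum(table$supervised, na.rm = TRUE)
}
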