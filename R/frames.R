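#' Frame sequences
#'
#' A `frame_sequence` is the single in-memory representation of a grayscale
#' video used throughout pentrack: an ordered list of `H x W` numeric
#' matrices with intensities in `[0, 255]`, plus the frame rate. Frames are
#' indexed 0-based; pixel coordinates are 0-based with `x` indexing columns
#' (width), `y` indexing rows (height), origin at the top-left corner.
#'
#' @param frames List of numeric matrices, all with identical dimensions,
#'   values in `[0, 255]`.
#' @param fps Frames per second (positive real, default 6, the typical
#'   low-power farm recording rate).
#' @param origin_label Identifier string for provenance.
#'
#' @return An object of class `frame_sequence` with elements `frames`,
#'   `fps`, `origin_label`.
#' @examples
#' fs <- frame_sequence(list(matrix(0, 4, 5), matrix(255, 4, 5)))
#' dim(fs)   # T, H, W
#' @export
frame_sequence <- function(frames, fps = 6, origin_label = "memory") {
  if (!is.list(frames) || length(frames) < 1) {
    stop("`frames` must be a non-empty list of matrices", call. = FALSE)
  }
  frames <- lapply(frames, function(f) {
    if (!is.matrix(f)) stop("each frame must be a matrix", call. = FALSE)
    storage.mode(f) <- "double"
    f
  })
  d1 <- dim(frames[[1]])
  for (i in seq_along(frames)) {
    if (!identical(dim(frames[[i]]), d1)) {
      stop("inconsistent frame size at frame ", i - 1, call. = FALSE)
    }
    v <- frames[[i]]
    if (anyNA(v) || any(!is.finite(v)) || any(v < 0) || any(v > 255)) {
      stop("pixel values must be finite and within [0, 255]", call. = FALSE)
    }
  }
  if (!is.numeric(fps) || length(fps) != 1 || fps <= 0) {
    stop("`fps` must be a positive number", call. = FALSE)
  }
  structure(
    list(frames = frames, fps = fps, origin_label = as.character(origin_label)),
    class = "frame_sequence"
  )
}

#' @export
dim.frame_sequence <- function(x) {
  c(length(x$frames), nrow(x$frames[[1]]), ncol(x$frames[[1]]))
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "<frame_sequence> %d frames of %d x %d px (H x W), %.3g fps, origin: %s\n",
    d[1], d[2], d[3], x$fps, x$origin_label
  ))
  invisible(x)
}

#' Number of frames
#' @param seq A [frame_sequence()].
#' @return Integer frame count.
#' @export
n_frames <- function(seq) {
  stopifnot(inherits(seq, "frame_sequence"))
  length(seq$frames)
}

#' Extract one frame as a matrix
#' @param seq A [frame_sequence()].
#' @param t 0-based frame index.
#' @return `H x W` numeric matrix.
#' @export
get_frame <- function(seq, t) {
  stopifnot(inherits(seq, "frame_sequence"))
  if (t < 0 || t >= length(seq$frames)) {
    stop("frame index ", t, " out of range", call. = FALSE)
  }
  seq$frames[[t + 1]]
}

natural_order <- function(paths) {
  base <- basename(paths)
  # numeric-aware sort: frame_2 < frame_10
  num <- suppressWarnings(as.numeric(gsub("\\D", "", base)))
  ord <- order(is.na(num), num, base)
  paths[ord]
}

read_one_frame <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    jpg = ,
    jpeg = {
      if (!requireNamespace("EBImage", quietly = TRUE)) {
        stop("JPEG input requires the EBImage package", call. = FALSE)
      }
      img <- EBImage::imageData(EBImage::readImage(path))
      # EBImage stores x (width) as the first dimension
      if (length(dim(img)) == 2) t(img) else aperm(img, c(2, 1, 3))
    },
    stop("unsupported frame format: ", ext, call. = FALSE)
  )
  if (length(dim(img)) == 3) {
    # collapse colour to grayscale by channel mean
    img <- apply(img[, , seq_len(min(3, dim(img)[3])), drop = FALSE], c(1, 2), mean)
  }
  img * 255
}

#' Read an image sequence as a frame sequence
#'
#' Reads an ordered directory of PNG/TIFF (and, with EBImage installed, JPEG)
#' frames as 8-bit grayscale. Colour frames are collapsed to grayscale by the
#' channel mean. Files are ordered by natural (numeric-aware) sort of their
#' names so that `frame_10` follows `frame_9`, not `frame_1`.
#'
#' @param path Directory containing the frames.
#' @param pattern Filename glob, default `"*.png"`.
#' @param fps Frame rate to record on the sequence (default 6).
#' @return A [frame_sequence()].
#' @export
read_frames <- function(path, pattern = "*.png", fps = 6) {
  if (!dir.exists(path)) stop("no such directory: ", path, call. = FALSE)
  files <- Sys.glob(file.path(path, pattern))
  if (length(files) == 0) stop("no frames found in ", path, call. = FALSE)
  files <- natural_order(files)
  frames <- lapply(files, read_one_frame)
  d1 <- dim(frames[[1]])
  for (i in seq_along(frames)) {
    if (!identical(dim(frames[[i]]), d1)) {
      stop("inconsistent frame size: ", basename(files[i]), call. = FALSE)
    }
  }
  frame_sequence(frames, fps = fps, origin_label = path)
}

#' Write a frame sequence as PNG files
#'
#' Inverse of [read_frames()] for 8-bit grayscale PNG; the round trip is
#' lossless after rounding intensities to integers.
#'
#' @param seq A [frame_sequence()].
#' @param path Output directory (created if absent).
#' @param prefix Filename prefix; frames are written as
#'   `<prefix>_%04d.png`.
#' @return Invisibly, the vector of file paths written.
#' @export
write_frames <- function(seq, path, prefix = "frame") {
  stopifnot(inherits(seq, "frame_sequence"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(seq$frames))
  for (i in seq_along(seq$frames)) {
    paths[i] <- file.path(path, sprintf("%s_%04d.png", prefix, i - 1))
    png::writePNG(round(seq$frames[[i]]) / 255, paths[i])
  }
  invisible(paths)
}

#' Export a score or binary map as a PNG image
#'
#' Min-max scales the map to `[0, 255]` for visual inspection of the motion
#' detection stages.
#'
#' @param map Numeric matrix (score map, binary map, or heat map).
#' @param path Output PNG path.
#' @return Invisibly, `path`.
#' @export
write_map_png <- function(map, path) {
  stopifnot(is.matrix(map))
  rng <- range(map)
  scaled <- if (diff(rng) > 0) (map - rng[1]) / diff(rng) else map * 0
  png::writePNG(scaled, path)
  invisible(path)
}
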