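#' Per-pixel motion over a frame window
#'
#' Motion at a pixel is quantified as the mean absolute deviation of its
#' intensity from the window mean: for the inclusive window `[t_b, t_l]`,
#' `m(x, y) = sum_t |p(x, y, t) - pbar(x, y)| / (t_l - t_b)`. A pixel that an
#' animal enters or leaves during the window changes between background and
#' body texture and therefore scores high; static background scores zero.
#' With `deviation = "squared"` the summand is the squared deviation, making
#' `m` the sample variance over the window.
#'
#' @param seq A [frame_sequence()].
#' @param t_b,t_l First and last frame of the inclusive window (0-based,
#'   `t_b < t_l`).
#' @param deviation `"absolute"` (default) or `"squared"`.
#' @return `H x W` non-negative matrix with attribute `window = c(t_b, t_l)`.
#' @examples
#' fs <- frame_sequence(list(
#'   matrix(10, 1, 1), matrix(10, 1, 1), matrix(40, 1, 1)
#' ))
#' motion_map(fs, 0, 2) # (|10-20| + |10-20| + |40-20|) / 2 = 20
#' @export
motion_map <- function(seq, t_b, t_l, deviation = c("absolute", "squared")) {
  stopifnot(inherits(seq, "frame_sequence"))
  deviation <- match.arg(deviation)
  T <- length(seq$frames)
  if (t_b >= t_l) stop("empty time range: t_b must be < t_l", call. = FALSE)
  if (t_b < 0 || t_l > T - 1) {
    stop("window [", t_b, ", ", t_l, "] outside sequence 0..", T - 1, call. = FALSE)
  }
  idx <- seq.int(t_b, t_l) + 1L
  pbar <- Reduce(`+`, seq$frames[idx]) / length(idx)
  dev_fun <- if (deviation == "absolute") abs else function(d) d * d
  acc <- Reduce(`+`, lapply(seq$frames[idx], function(f) dev_fun(f - pbar)))
  structure(acc / (t_l - t_b), window = c(t_b, t_l))
}

#' Motion score map at a frame
#'
#' Sums motion maps over flanking windows around the observed frame `t0`:
#' for `k = 1..k_max`, the backward window `[t0 - k, t0]` and the forward
#' window `[t0, t0 + k]`. High scores mark pixels likely occupied by a
#' moving animal at `t0`. Windows that would extend past the sequence ends
#' are clamped to `[0, T - 1]` and skipped when they collapse to a single
#' frame, so boundary frames remain scorable from one side.
#'
#' @inheritParams motion_map
#' @param t0 Observed frame (0-based).
#' @param k_max Flanking half-width in frames (default 2).
#' @return `H x W` non-negative matrix with attributes `center_frame`,
#'   `half_width`.
#' @export
score_map <- function(seq, t0, k_max = 2, deviation = c("absolute", "squared")) {
  stopifnot(inherits(seq, "frame_sequence"))
  deviation <- match.arg(deviation)
  T <- length(seq$frames)
  if (T < 2) stop("cannot score a single-frame sequence", call. = FALSE)
  if (t0 < 0 || t0 > T - 1) stop("t0 outside sequence", call. = FALSE)
  d <- dim(seq$frames[[1]])
  acc <- matrix(0, d[1], d[2])
  for (k in seq_len(k_max)) {
    tb <- max(0L, t0 - k)
    if (tb < t0) acc <- acc + motion_map(seq, tb, t0, deviation)
    tl <- min(T - 1L, t0 + k)
    if (tl > t0) acc <- acc + motion_map(seq, t0, tl, deviation)
  }
  structure(acc, center_frame = t0, half_width = k_max)
}

#' Binarize a score map at a per-frame quantile
#'
#' Scores are assumed to follow a skewed distribution in which most pixels
#' (background) score low; the pixels of interest (POI) are those strictly
#' above the 99th quantile of all scores in the frame. The quantile uses
#' linear interpolation between order statistics.
#'
#' @param score Score matrix from [score_map()].
#' @param quantile Threshold quantile in (0, 1), default 0.99.
#' @return `H x W` 0/1 matrix with attribute `stage = "raw"`.
#' @export
binarize <- function(score, quantile = 0.99) {
  stopifnot(is.matrix(score))
  if (quantile <= 0 || quantile >= 1) {
    stop("`quantile` must be in (0, 1)", call. = FALSE)
  }
  thr <- stats::quantile(as.vector(score), probs = quantile, type = 7, names = FALSE)
  out <- (score > thr) + 0
  structure(out, stage = "raw", dim = dim(score))
}

#' Normalized Gaussian blurring kernel
#'
#' The kernel used to "blur" the raw POI map so that isolated noise pixels
#' (vibrations, activity outside the pen) fall below the 0.5 re-threshold
#' while compact animal blobs survive.
#'
#' @param half_width Kernel half-width in pixels (kernel is
#'   `(2 * half_width + 1)` squared), default 2.
#' @param sigma Gaussian standard deviation in pixels, default 1.
#' @return Weight matrix summing to 1, with attributes `kind = "gaussian"`,
#'   `sigma`.
#' @export
make_gaussian_kernel <- function(half_width = 2, sigma = 1.0) {
  if (half_width < 1) stop("`half_width` must be >= 1", call. = FALSE)
  if (sigma <= 0) stop("invalid sigma", call. = FALSE)
  d <- seq.int(-half_width, half_width)
  g1 <- exp(-d^2 / (2 * sigma^2))
  w <- outer(g1, g1)
  structure(w / sum(w), kind = "gaussian", sigma = sigma)
}

#' Edge-detection kernel
#'
#' Default 3x3 Laplacian-style kernel (centre -4, edge neighbours 1,
#' corners 0); its response is zero on constant regions, so only boundary
#' pixels of POI regions respond.
#'
#' @param weights Optional custom odd-dimension matrix whose weights sum
#'   to 0.
#' @return Weight matrix with attribute `kind = "edge"`.
#' @export
make_edge_kernel <- function(weights = NULL) {
  if (is.null(weights)) {
    weights <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  }
  stopifnot(is.matrix(weights))
  if (abs(sum(weights)) > 1e-9) {
    stop("edge kernel weights must sum to 0", call. = FALSE)
  }
  structure(weights, kind = "edge")
}

#' Refine a raw POI map by Gaussian blurring
#'
#' Convolves the 0/1 POI map with the Gaussian kernel (reflect padding at
#' the borders) and re-thresholds at 0.5. Small isolated noise responses
#' (a single flicker pixel peaks at the kernel's centre weight, about 0.16
#' for the default kernel) are removed; pixels well inside compact blobs
#' keep a response of ~1.
#'
#' @param binary Raw 0/1 POI matrix from [binarize()].
#' @param kernel Gaussian kernel from [make_gaussian_kernel()].
#' @return `H x W` 0/1 matrix with attribute `stage = "refined"`.
#' @export
refine <- function(binary, kernel = make_gaussian_kernel()) {
  stopifnot(is.matrix(binary))
  if (!identical(attr(kernel, "kind"), "gaussian")) {
    stop("`kernel` must be a gaussian kernel", call. = FALSE)
  }
  resp <- conv2_reflect(unclass_map(binary), unclass_map(kernel))
  structure((resp >= 0.5) + 0, stage = "refined", dim = dim(binary))
}

#' Extract POI contours from a refined map
#'
#' Applies the edge kernel to the refined map and keeps pixels where the
#' response is non-zero *and* the refined map is 1: the boundaries of the
#' POI regions. Tracking contours instead of filled regions keeps the
#' point set small and concentrates it on texture-rich body outlines.
#'
#' @param refined Refined 0/1 matrix from [refine()].
#' @param kernel Edge kernel from [make_edge_kernel()].
#' @return `H x W` 0/1 matrix with attribute `stage = "contour"`.
#' @export
poi_contour <- function(refined, kernel = make_edge_kernel()) {
  stopifnot(is.matrix(refined))
  if (!identical(attr(kernel, "kind"), "edge")) {
    stop("`kernel` must be an edge kernel", call. = FALSE)
  }
  resp <- conv2_reflect(unclass_map(refined), unclass_map(kernel))
  out <- ((abs(resp) > 1e-9) & (refined == 1)) + 0
  structure(out, stage = "contour", dim = dim(refined))
}

# strip pentrack attributes so Rcpp sees a plain matrix
unclass_map <- function(x) {
  matrix(as.numeric(x), nrow(x), ncol(x))
}

#' POI pixel coordinates of a binary map
#'
#' @param binary A 0/1 matrix.
#' @return Tibble with 0-based `x` (column) and `y` (row) of each 1-pixel.
#' @export
poi_coords <- function(binary) {
  idx <- which(binary == 1, arr.ind = TRUE)
  tibble::tibble(x = as.numeric(idx[, 2] - 1), y = as.numeric(idx[, 1] - 1))
}
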