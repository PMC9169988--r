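#' Label connected components of a binary map
#'
#' 8-connected component labelling by breadth-first search; used to discard
#' residual noise components before clustering.
#'
#' @param binary A 0/1 matrix.
#' @return Integer matrix of the same shape: 0 for background, 1..n for
#'   components.
#' @keywords internal
label_components <- function(binary) {
  H <- nrow(binary)
  W <- ncol(binary)
  labels <- matrix(0L, H, W)
  seeds <- which(binary == 1)
  lab <- 0L
  off <- c(-1L, 1L, -H, H, -H - 1L, -H + 1L, H - 1L, H + 1L)
  for (s in seeds) {
    if (labels[s] != 0L) next
    lab <- lab + 1L
    queue <- s
    labels[s] <- lab
    while (length(queue) > 0) {
      cur <- queue
      queue <- integer()
      for (p in cur) {
        r <- (p - 1L) %% H + 1L
        cand <- p + off
        # drop wrap-arounds at the top/bottom edges and out-of-range cells
        keep <- cand >= 1L & cand <= H * W
        if (r == 1L) keep <- keep & !(cand %in% (p + c(-1L, -H - 1L, H - 1L)))
        if (r == H) keep <- keep & !(cand %in% (p + c(1L, -H + 1L, H + 1L)))
        cand <- cand[keep]
        hit <- cand[binary[cand] == 1 & labels[cand] == 0L]
        labels[hit] <- lab
        queue <- c(queue, hit)
      }
    }
  }
  labels
}

#' Cluster contour pixels into animal identities
#'
#' Groups the POI contour pixels of one frame into `k` clusters, one per
#' animal, by agglomerative hierarchical clustering with Ward linkage on
#' Euclidean pixel coordinates, constrained by a symmetric nearest-neighbour
#' connectivity graph (each pixel connected to its
#' `connectivity_neighbors` nearest POI pixels). The constraint keeps merges
#' spatially local, so spatially coherent blobs are grouped before distant
#' ones. Connected components smaller than `min_cluster_pixels` are
#' discarded first as residual noise. Cluster labels 0..k-1 are assigned by
#' ascending centroid x (ties by ascending y), giving deterministic
#' identities.
#'
#' @param contour Contour 0/1 matrix from [poi_contour()].
#' @param k Number of animals.
#' @param connectivity_neighbors Nearest neighbours per pixel in the
#'   connectivity graph (default 5).
#' @param min_cluster_pixels Minimum connected-component size kept
#'   (default 5).
#' @return Tibble with one row per kept POI pixel: `x`, `y`, `label`
#'   (0-based cluster id).
#' @export
cluster_poi <- function(contour, k, connectivity_neighbors = 5,
                        min_cluster_pixels = 5) {
  stopifnot(is.matrix(contour), k >= 1)
  if (min_cluster_pixels > 0 && any(contour == 1)) {
    comp <- label_components(contour)
    sizes <- tabulate(comp[comp > 0])
    drop <- which(sizes < min_cluster_pixels)
    if (length(drop) > 0) {
      contour[comp %in% drop] <- 0
    }
  }
  pts <- poi_coords(contour)
  n <- nrow(pts)
  if (n < k) {
    stop("insufficient POI for ", k, " animals (", n, " pixels)", call. = FALSE)
  }
  if (k == 1 || n == k) {
    labs0 <- if (n == k) seq_len(n) else rep(1L, n)
  } else {
    coords <- cbind(pts$x, pts$y)
    d2 <- as.matrix(stats::dist(coords))^2
    kk <- min(connectivity_neighbors, n - 1)
    nn <- t(apply(d2, 1, function(row) order(row)[2:(kk + 1)])) - 1L
    if (kk == 1) nn <- matrix(nn, ncol = 1)
    labs0 <- ward_connected(coords, matrix(as.integer(nn), nrow = n), as.integer(k))
    labs0 <- match(labs0, sort(unique(labs0)))
  }
  pts$label <- labs0
  cen <- dplyr::arrange(
    dplyr::summarise(dplyr::group_by(pts, .data$label),
      cx = mean(.data$x), cy = mean(.data$y), .groups = "drop"
    ),
    .data$cx, .data$cy
  )
  relabel <- setNames(seq_len(nrow(cen)) - 1L, cen$label)
  pts$label <- as.integer(relabel[as.character(pts$label)])
  dplyr::arrange(pts, .data$label, .data$y, .data$x)
}

#' Centroids of POI clusters
#'
#' @param clusters Tibble from [cluster_poi()].
#' @return Tibble with `label`, `x`, `y` (arithmetic mean of member
#'   pixels), ordered by label.
#' @export
cluster_centroids <- function(clusters) {
  dplyr::arrange(
    dplyr::summarise(dplyr::group_by(clusters, .data$label),
      x = mean(.data$x), y = mean(.data$y), .groups = "drop"
    ),
    .data$label
  )
}

#' Propose tracker starting positions from motion
#'
#' Runs the full motion-detection stack at one frame — score map,
#' 99th-quantile binarization, Gaussian refinement, contour extraction,
#' constrained clustering — and returns the `k` cluster centroids as
#' starting positions for the trackers. This is the automatic alternative
#' to clicking start positions by hand.
#'
#' @inheritParams score_map
#' @param k Number of animals.
#' @param quantile Binarization quantile (default 0.99).
#' @param gaussian Gaussian kernel for [refine()].
#' @param edge Edge kernel for [poi_contour()].
#' @param connectivity_neighbors,min_cluster_pixels See [cluster_poi()].
#' @return Tibble with `animal` (0-based), `x`, `y` centroids.
#' @export
propose_start_points <- function(seq, t0, k, k_max = 2, quantile = 0.99,
                                 deviation = c("absolute", "squared"),
                                 gaussian = make_gaussian_kernel(),
                                 edge = make_edge_kernel(),
                                 connectivity_neighbors = 5,
                                 min_cluster_pixels = 5) {
  deviation <- match.arg(deviation)
  s <- score_map(seq, t0, k_max = k_max, deviation = deviation)
  b <- binarize(s, quantile = quantile)
  br <- refine(b, gaussian)
  bc <- poi_contour(br, edge)
  cl <- cluster_poi(bc, k,
    connectivity_neighbors = connectivity_neighbors,
    min_cluster_pixels = min_cluster_pixels
  )
  cen <- cluster_centroids(cl)
  tibble::tibble(animal = cen$label, x = cen$x, y = cen$y)
}
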