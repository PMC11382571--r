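#' Construct a point cloud
#'
#' The central container shared by all modules: an N x 3 matrix of coordinates
#' in meters, with optional per-point 8-bit RGB color. A cloud plays either
#' role in an evaluation — reconstruction or ground truth.
#'
#' @param points numeric matrix (or coercible) with 3 columns, one row per
#'   point; coordinates in meters, all finite.
#' @param colors optional integer matrix with 3 columns (red, green, blue),
#'   one row per point, each channel in 0..255.
#' @return an object of class `point_cloud` with elements `points` and
#'   `colors` (`NULL` when absent).
#' @examples
#' pc <- point_cloud(rbind(c(0, 0, 0), c(1, 0, 0)))
#' n_points(pc)
#' @export
point_cloud <- function(points, colors = NULL) {
  points <- as.matrix(points)
  if (ncol(points) != 3L)
    abort_input("points must have exactly 3 columns (x, y, z)")
  if (nrow(points) < 1L)
    abort_input("a point cloud must contain at least one point")
  storage.mode(points) <- "double"
  if (!all(is.finite(points)))
    abort_input("all coordinates must be finite")
  dimnames(points) <- NULL
  if (!is.null(colors)) {
    colors <- as.matrix(colors)
    if (!identical(dim(colors), c(nrow(points), 3L)))
      abort_input("colors must be an n x 3 matrix matching the point count")
    if (anyNA(colors) || any(colors < 0) || any(colors > 255))
      abort_input("color channels must lie in [0, 255]")
    if (any(colors != round(colors)))
      abort_input("color channels must be integers")
    storage.mode(colors) <- "integer"
    dimnames(colors) <- NULL
  }
  structure(list(points = points, colors = colors), class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud> %d points%s\n", nrow(x$points),
              if (is.null(x$colors)) "" else ", RGB"))
  rng <- apply(x$points, 2, range)
  cat(sprintf("  extent x [%.4g, %.4g]  y [%.4g, %.4g]  z [%.4g, %.4g] m\n",
              rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  invisible(x)
}

#' Number of points in a cloud
#' @param cloud a `point_cloud`.
#' @return integer count.
#' @export
n_points <- function(cloud) {
  stopifnot(inherits(cloud, "point_cloud"))
  nrow(cloud$points)
}

#' Axis-aligned bounding volume
#'
#' The evaluation region of an assessment: points outside the box are ignored.
#' Membership is closed (boundary points are kept).
#'
#' @param min_corner,max_corner numeric length-3 vectors (meters);
#'   `min_corner` must be strictly below `max_corner` in every axis.
#' @return object of class `bounding_volume`.
#' @export
bounding_volume <- function(min_corner, max_corner) {
  min_corner <- as.numeric(min_corner)
  max_corner <- as.numeric(max_corner)
  if (length(min_corner) != 3L || length(max_corner) != 3L)
    abort_input("corners must be length-3 numeric vectors")
  if (!all(is.finite(min_corner)) || !all(is.finite(max_corner)))
    abort_input("corners must be finite")
  if (!all(min_corner < max_corner))
    abort_input("min_corner must be strictly less than max_corner in every axis")
  structure(list(min_corner = min_corner, max_corner = max_corner),
            class = "bounding_volume")
}

#' Read a bounding volume from JSON
#'
#' Schema: `{"min": [x,y,z], "max": [x,y,z]}`.
#' @param path file path.
#' @return a `bounding_volume`.
#' @export
read_bounds_json <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("bounds file not found: %s", path))
  b <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(b$min) || is.null(b$max))
    abort_input(sprintf("bounds JSON %s must contain 'min' and 'max'", path))
  bounding_volume(b$min, b$max)
}

#' Crop a cloud to a bounding volume
#'
#' Keeps exactly the points whose coordinates lie inside the closed box;
#' colors are carried along and point order is preserved. Cropping is
#' idempotent and always returns a subset of the input.
#'
#' @param cloud a `point_cloud`.
#' @param bounds a `bounding_volume`.
#' @return the cropped `point_cloud`.
#' @export
crop_to_bounds <- function(cloud, bounds) {
  stopifnot(inherits(cloud, "point_cloud"), inherits(bounds, "bounding_volume"))
  p <- cloud$points
  keep <- p[, 1] >= bounds$min_corner[1] & p[, 1] <= bounds$max_corner[1] &
          p[, 2] >= bounds$min_corner[2] & p[, 2] <= bounds$max_corner[2] &
          p[, 3] >= bounds$min_corner[3] & p[, 3] <= bounds$max_corner[3]
  if (!any(keep))
    abort_input("crop produced an empty cloud: bounding volume does not intersect the data")
  point_cloud(p[keep, , drop = FALSE],
              if (is.null(cloud$colors)) NULL else cloud$colors[keep, , drop = FALSE])
}

#' Remove duplicate points
#'
#' Greedy deduplication in file order: a point is dropped when a previously
#' kept point lies closer than `epsilon`; the earliest occurrence is always
#' kept. With `epsilon = 0` only exactly coincident points collapse.
#'
#' @param cloud a `point_cloud`.
#' @param epsilon minimum allowed pairwise distance (meters), `>= 0`.
#' @return the deduplicated `point_cloud`.
#' @export
remove_duplicates <- function(cloud, epsilon = 1e-6) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (!is.finite(epsilon) || epsilon < 0) abort_input("epsilon must be >= 0")
  keep <- if (epsilon == 0) {
    !duplicated(cloud$points)
  } else {
    cpp_dedupe(cloud$points, epsilon)
  }
  point_cloud(cloud$points[keep, , drop = FALSE],
              if (is.null(cloud$colors)) NULL else cloud$colors[keep, , drop = FALSE])
}

#' Statistical outlier removal
#'
#' For every point the mean distance to its `k_neighbors` nearest neighbors is
#' computed; points whose statistic exceeds the global mean plus `std_ratio`
#' times the global (sample) standard deviation of that statistic are removed.
#' This is the standard cleanup applied to terrestrial-laser-scan clouds
#' before they are used as ground truth.
#'
#' @param cloud a `point_cloud` with more than `k_neighbors` points.
#' @param k_neighbors number of neighbors entering the per-point statistic.
#' @param std_ratio cutoff multiplier on the standard deviation.
#' @return the retained `point_cloud`; the number of removed points is
#'   attached as attribute `n_removed`.
#' @export
remove_statistical_outliers <- function(cloud, k_neighbors = 20L, std_ratio = 2.0) {
  stopifnot(inherits(cloud, "point_cloud"))
  k_neighbors <- as.integer(k_neighbors)
  if (k_neighbors < 1L) abort_input("k_neighbors must be >= 1")
  if (n_points(cloud) <= k_neighbors)
    abort_input("cloud too small: need more points than k_neighbors")
  if (!is.finite(std_ratio)) abort_input("std_ratio must be finite")
  md <- cpp_knn_mean_dist(cloud$points, k_neighbors)
  cutoff <- mean(md) + std_ratio * stats::sd(md)
  keep <- md <= cutoff
  out <- point_cloud(cloud$points[keep, , drop = FALSE],
                     if (is.null(cloud$colors)) NULL else cloud$colors[keep, , drop = FALSE])
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Voxel-grid downsampling
#'
#' Replaces all points falling in each cubic grid cell of edge `voxel` by
#' their centroid. Cells are reported in order of first occurrence, so the
#' result is deterministic. Used to regularize correspondence search in ICP.
#'
#' @param points numeric n x 3 matrix or a `point_cloud`.
#' @param voxel cell edge length (meters), `> 0`.
#' @return an m x 3 matrix of cell centroids (m <= n).
#' @export
voxel_downsample <- function(points, voxel) {
  if (inherits(points, "point_cloud")) points <- points$points
  if (!is.finite(voxel) || voxel <= 0) abort_input("voxel must be > 0")
  cell <- floor(points / voxel)
  key <- paste(cell[, 1], cell[, 2], cell[, 3])
  f <- as.integer(factor(key, levels = unique(key)))
  sums <- rowsum(points, f)
  counts <- tabulate(f)
  unname(sums / counts)
}
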