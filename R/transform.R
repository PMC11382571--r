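#' Similarity transform (scale, rotation, translation)
#'
#' Maps a point `p` to `scale * rotation %*% p + translation`. Used to carry a
#' reconstruction into the ground-truth frame: scale and orientation come from
#' manually picked correspondence points, the rotation/translation part is then
#' refined rigidly by ICP.
#'
#' @param scale positive scalar.
#' @param rotation 3 x 3 rotation matrix (orthonormal, determinant +1, both
#'   within 1e-9).
#' @param translation numeric length-3 vector (meters).
#' @return object of class `similarity_transform`.
#' @export
similarity_transform <- function(scale = 1, rotation = diag(3),
                                 translation = c(0, 0, 0)) {
  rotation <- unname(as.matrix(rotation))
  translation <- as.numeric(translation)
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) || scale <= 0)
    abort_input("scale must be a positive finite scalar")
  if (!identical(dim(rotation), c(3L, 3L)) || !all(is.finite(rotation)))
    abort_input("rotation must be a finite 3 x 3 matrix")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    abort_input("rotation must be orthonormal within 1e-9")
  if (abs(det(rotation) - 1) > 1e-9)
    abort_input("rotation must be proper (det = +1 within 1e-9)")
  if (length(translation) != 3L || !all(is.finite(translation)))
    abort_input("translation must be a finite length-3 vector")
  structure(list(scale = scale, rotation = rotation, translation = translation),
            class = "similarity_transform")
}

#' @export
print.similarity_transform <- function(x, ...) {
  cat(sprintf("<similarity_transform> scale %.6g, translation (%.4g, %.4g, %.4g)\n",
              x$scale, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Compose two similarity transforms
#'
#' Returns the transform equivalent to applying `b` first, then `a`.
#' @param a,b `similarity_transform` objects.
#' @return their composition `a o b`.
#' @export
compose_transforms <- function(a, b) {
  stopifnot(inherits(a, "similarity_transform"), inherits(b, "similarity_transform"))
  similarity_transform(
    scale = a$scale * b$scale,
    rotation = a$rotation %*% b$rotation,
    translation = as.vector(a$scale * a$rotation %*% b$translation) + a$translation)
}

#' Invert a similarity transform
#' @param transform a `similarity_transform`.
#' @return its inverse.
#' @export
invert_transform <- function(transform) {
  stopifnot(inherits(transform, "similarity_transform"))
  rt <- t(transform$rotation)
  similarity_transform(
    scale = 1 / transform$scale,
    rotation = rt,
    translation = as.vector(-(1 / transform$scale) * rt %*% transform$translation))
}

#' Apply a similarity transform to a cloud
#'
#' Each point `p` is mapped to `scale * rotation %*% p + translation`; colors
#' are unchanged.
#' @param cloud a [point_cloud()] (or a bare n x 3 matrix).
#' @param transform a [similarity_transform()].
#' @return the transformed object, same type as the input.
#' @export
apply_transform <- function(cloud, transform) {
  stopifnot(inherits(transform, "similarity_transform"))
  if (inherits(cloud, "point_cloud")) {
    pts <- transform_points(cloud$points, transform)
    return(point_cloud(pts, cloud$colors))
  }
  transform_points(as.matrix(cloud), transform)
}

transform_points <- function(points, transform) {
  sweep(transform$scale * (points %*% t(transform$rotation)), 2,
        transform$translation, `+`)
}

#' Estimate a similarity transform from point correspondences
#'
#' Least-squares (Umeyama) fit of scale, rotation and translation mapping
#' `source_points` onto `target_points`; exact when the correspondences are
#' noise-free. This is the initial alignment step: a few corresponding points
#' picked in both clouds fix scale and orientation before ICP refinement.
#'
#' @param source_points,target_points n x 3 matrices of paired points, n >= 3,
#'   not collinear.
#' @return a [similarity_transform()].
#' @export
estimate_initial_transform <- function(source_points, target_points) {
  s <- as.matrix(source_points)
  t_ <- as.matrix(target_points)
  if (!identical(dim(s), dim(t_)) || ncol(s) != 3L)
    abort_input("source and target must be equal-size n x 3 matrices")
  n <- nrow(s)
  if (n < 3L)
    abort_degenerate("at least 3 correspondence pairs are required, got %d", n)
  mu_s <- colMeans(s)
  mu_t <- colMeans(t_)
  sc <- sweep(s, 2, mu_s)
  tc <- sweep(t_, 2, mu_t)
  sv <- svd(sc)
  if (sv$d[2] <= 1e-12 * max(sv$d[1], .Machine$double.eps))
    abort_degenerate("correspondence points are collinear; rotation is not determined")
  sigma <- crossprod(tc, sc) / n             # sum (t - mu_t)(s - mu_s)^T / n
  dec <- svd(sigma)
  d_sign <- sign(det(dec$u) * det(dec$v))
  if (d_sign == 0) d_sign <- 1
  S <- diag(c(1, 1, d_sign))
  R <- dec$u %*% S %*% t(dec$v)
  var_s <- sum(sc^2) / n
  scale <- sum(dec$d * diag(S)) / var_s
  if (!is.finite(scale) || scale <= 0)
    abort_degenerate("degenerate correspondence geometry: non-positive scale")
  translation <- mu_t - scale * as.vector(R %*% mu_s)
  similarity_transform(scale = scale, rotation = R, translation = translation)
}

#' Convert a similarity transform to a 4 x 4 homogeneous matrix
#' @param transform a [similarity_transform()].
#' @return 4 x 4 numeric matrix.
#' @export
transform_to_matrix <- function(transform) {
  stopifnot(inherits(transform, "similarity_transform"))
  m <- diag(4)
  m[1:3, 1:3] <- transform$scale * transform$rotation
  m[1:3, 4] <- transform$translation
  m
}

#' Read / write a transform as JSON
#'
#' Schema: `{"scale": s, "rotation": [[..] x3], "translation": [x,y,z]}`.
#' @param path file path.
#' @return [similarity_transform()] for the reader; the path, invisibly, for
#'   the writer.
#' @export
read_transform_json <- function(path) {
  if (!file.exists(path)) abort_input("transform file not found: %s", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(j$scale) || is.null(j$rotation) || is.null(j$translation))
    abort_input("%s: transform JSON needs scale, rotation, translation", path)
  similarity_transform(j$scale, j$rotation, j$translation)
}

#' @rdname read_transform_json
#' @param transform a `similarity_transform` to serialize.
#' @export
write_transform_json <- function(transform, path) {
  stopifnot(inherits(transform, "similarity_transform"))
  jsonlite::write_json(list(scale = transform$scale,
                            rotation = transform$rotation,
                            translation = transform$translation),
                       path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' Read correspondence pairs from JSON
#'
#' Schema: `{"source": [[x,y,z], ...], "target": [[x,y,z], ...]}` with equal
#' counts.
#' @param path file path.
#' @return list with `source` and `target` n x 3 matrices.
#' @export
read_correspondences_json <- function(path) {
  if (!file.exists(path)) abort_input("correspondence file not found: %s", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(j$source) || is.null(j$target))
    abort_input("%s: correspondence JSON needs 'source' and 'target'", path)
  src <- as.matrix(j$source)
  tgt <- as.matrix(j$target)
  if (!identical(dim(src), dim(tgt)) || ncol(src) != 3L)
    abort_input("%s: source/target must be equal-length lists of 3D points", path)
  list(source = src, target = tgt)
}
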