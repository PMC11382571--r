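#' Nearest-neighbor distances between two clouds
#'
#' Element `i` of the result is the Euclidean distance from query point `i`
#' to its nearest reference point. Computed with a kd-tree but bit-equal to
#' exhaustive search.
#'
#' @param query,reference [point_cloud()]s (or n x 3 matrices).
#' @return numeric vector, one distance (meters) per query point.
#' @export
nn_distances <- function(query, reference) {
  q <- if (inherits(query, "point_cloud")) query$points else as.matrix(query)
  r <- if (inherits(reference, "point_cloud")) reference$points else as.matrix(reference)
  if (nrow(r) < 1L) abort_input("reference cloud is empty")
  if (nrow(q) < 1L) abort_input("query cloud is empty")
  cpp_nn(q, r)$dist
}

#' Precision of a reconstruction at threshold d
#'
#' Percentage of reconstruction points whose nearest ground-truth point lies
#' strictly closer than `d`:
#' `P(d) = 100/|R| * sum_r I(min_g ||r - g|| < d)`.
#'
#' @param reconstruction,ground_truth [point_cloud()]s in a common frame.
#' @param d distance threshold (meters), `> 0`.
#' @return percent in \[0, 100\].
#' @export
precision <- function(reconstruction, ground_truth, d) {
  if (!is.finite(d) || d <= 0) abort_input("threshold d must be > 0")
  100 * mean(nn_distances(reconstruction, ground_truth) < d)
}

#' Recall (completeness) of a reconstruction at threshold d
#'
#' Percentage of ground-truth points whose nearest reconstruction point lies
#' strictly closer than `d`:
#' `R(d) = 100/|G| * sum_g I(min_r ||g - r|| < d)`.
#' By symmetry `recall(A, B, d) == precision(B, A, d)`.
#'
#' @inheritParams precision
#' @return percent in \[0, 100\].
#' @export
recall <- function(reconstruction, ground_truth, d) {
  precision(ground_truth, reconstruction, d)
}

#' F-score: harmonic mean of precision and recall
#'
#' `F = 2 P R / (P + R)`, and 0 when `P + R == 0`. The harmonic form drives
#' the score to zero whenever either component collapses, penalizing
#' reconstructions that are accurate but incomplete (or vice versa).
#'
#' @param precision,recall percentages in \[0, 100\].
#' @return percent in \[0, 100\].
#' @export
f_score <- function(precision, recall) {
  stopifnot(is.numeric(precision), is.numeric(recall))
  if (any(precision < 0 | precision > 100 | recall < 0 | recall > 100, na.rm = TRUE))
    abort_input("precision and recall must lie in [0, 100]")
  s <- precision + recall
  ifelse(s == 0, 0, 2 * precision * recall / s)
}

#' Evaluate a reconstruction against ground truth at one threshold
#'
#' @inheritParams precision
#' @return object of class `geometry_report`: `threshold_d`, `precision`,
#'   `recall`, `f1` (percent, full precision), `n_reconstruction`,
#'   `n_ground_truth`.
#' @export
evaluate_reconstruction <- function(reconstruction, ground_truth, d) {
  p <- precision(reconstruction, ground_truth, d)
  r <- recall(reconstruction, ground_truth, d)
  structure(list(threshold_d = d, precision = p, recall = r, f1 = f_score(p, r),
                 n_reconstruction = n_points(reconstruction),
                 n_ground_truth = n_points(ground_truth)),
            class = "geometry_report")
}

#' @export
print.geometry_report <- function(x, ...) {
  cat(sprintf("<geometry_report> d = %g m: P %.2f  R %.2f  F1 %.2f  (|R| = %d, |G| = %d)\n",
              x$threshold_d, x$precision, x$recall, x$f1,
              x$n_reconstruction, x$n_ground_truth))
  invisible(x)
}

#' Precision-recall curve over a threshold sweep
#'
#' The two nearest-neighbor distance lists are computed once and re-thresholded
#' per step, which is identical to re-evaluating at each threshold. Precision
#' and recall are non-decreasing in the threshold.
#'
#' @inheritParams precision
#' @param d_min,d_max sweep bounds (meters), `0 < d_min < d_max`.
#' @param n_steps number of thresholds, `>= 2`.
#' @return object of class `pr_curve`: data frame with columns `threshold`,
#'   `precision`, `recall`, `f1`.
#' @export
pr_curve <- function(reconstruction, ground_truth, d_min, d_max, n_steps = 20L) {
  if (!is.finite(d_min) || !is.finite(d_max) || d_min <= 0 || d_min >= d_max)
    abort_input("need 0 < d_min < d_max")
  n_steps <- as.integer(n_steps)
  if (n_steps < 2L) abort_input("n_steps must be >= 2")
  d_r <- nn_distances(reconstruction, ground_truth)
  d_g <- nn_distances(ground_truth, reconstruction)
  thresholds <- seq(d_min, d_max, length.out = n_steps)
  p <- vapply(thresholds, function(d) 100 * mean(d_r < d), numeric(1))
  r <- vapply(thresholds, function(d) 100 * mean(d_g < d), numeric(1))
  out <- data.frame(threshold = thresholds, precision = p, recall = r,
                    f1 = f_score(p, r))
  class(out) <- c("pr_curve", "data.frame")
  out
}

#' Label points as Correct / Missing / Outlier
#'
#' Per point of the tested cloud, with `nnd` its nearest-neighbor distance to
#' the reference and `sigma` the (population) standard deviation of the `nnd`
#' list over the tested cloud:
#' * `correct` — `nnd < d` (within the evaluation threshold; drawn gray),
#' * `outlier` — `nnd > 3 * sigma` (extreme error; drawn black),
#' * `missing` — otherwise (beyond the threshold but within 3 standard
#'   deviations; drawn red).
#'
#' Edge rule: when `3 * sigma <= d` no `missing` band exists, and every point
#' at or beyond `d` is labeled `outlier`.
#'
#' @param test cloud being labeled (the reconstruction in the precision pass,
#'   the ground truth in the recall pass).
#' @param reference the other cloud.
#' @param d distance threshold (meters), `> 0`.
#' @return object of class `point_labels`: `labels` (factor with levels
#'   correct/missing/outlier), `nn_distance`, `sigma`, `threshold_d`.
#' @export
label_points <- function(test, reference, d) {
  if (!is.finite(d) || d <= 0) abort_input("threshold d must be > 0")
  nnd <- nn_distances(test, reference)
  sigma <- sqrt(mean((nnd - mean(nnd))^2))
  labels <- if (3 * sigma <= d) {
    ifelse(nnd < d, "correct", "outlier")
  } else {
    ifelse(nnd < d, "correct", ifelse(nnd > 3 * sigma, "outlier", "missing"))
  }
  structure(list(labels = factor(labels, levels = c("correct", "missing", "outlier")),
                 nn_distance = nnd, sigma = sigma, threshold_d = d),
            class = "point_labels")
}

#' Color a cloud by evaluation labels
#'
#' Applies the standard visualization color code: gray (128,128,128) for
#' correct, red (255,0,0) for missing, black (0,0,0) for outlier.
#'
#' @param cloud the labeled [point_cloud()].
#' @param labels a [label_points()] result for that cloud.
#' @return the cloud with label colors attached.
#' @export
labeled_cloud <- function(cloud, labels) {
  stopifnot(inherits(cloud, "point_cloud"), inherits(labels, "point_labels"))
  if (length(labels$labels) != n_points(cloud))
    abort_input("labels do not match the cloud size")
  palette <- rbind(correct = c(128L, 128L, 128L),
                   missing = c(255L, 0L, 0L),
                   outlier = c(0L, 0L, 0L))
  point_cloud(cloud$points, palette[as.character(labels$labels), , drop = FALSE])
}

#' Rescale a cloud using a reference object of known size
#'
#' When no ground-truth scan is available, a reference object of known
#' physical size (for example a printed sphere placed in the scene) calibrates
#' the reconstruction scale: all coordinates are multiplied by
#' `true_length / measured_length` about the origin, after which real-world
#' dimensions (such as plant height) can be read off the cloud.
#'
#' @param cloud a [point_cloud()].
#' @param measured_length the reference dimension measured in the cloud (e.g.
#'   sphere diameter), `> 0`.
#' @param true_length the known physical dimension (meters), `> 0`.
#' @return the rescaled cloud.
#' @export
rescale_by_reference <- function(cloud, measured_length, true_length) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (!is.finite(measured_length) || measured_length <= 0 ||
      !is.finite(true_length) || true_length <= 0)
    abort_input("lengths must be positive")
  point_cloud(cloud$points * (true_length / measured_length), cloud$colors)
}

#' Extent of a cloud along one axis
#'
#' `max - min` of the chosen coordinate; e.g. plant height along z.
#' @param cloud a [point_cloud()].
#' @param axis `"x"`, `"y"` or `"z"`.
#' @return extent in meters.
#' @export
measure_extent <- function(cloud, axis = c("z", "x", "y")) {
  stopifnot(inherits(cloud, "point_cloud"))
  axis <- match.arg(axis)
  j <- match(axis, c("x", "y", "z"))
  diff(range(cloud$points[, j]))
}

#' Serialize a geometry report to JSON
#' @param report a `geometry_report`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "geometry_report"))
  jsonlite::write_json(list(threshold = report$threshold_d,
                            precision = report$precision,
                            recall = report$recall,
                            f1 = report$f1,
                            n_reconstruction = report$n_reconstruction,
                            n_ground_truth = report$n_ground_truth),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a precision-recall curve as CSV
#' @param curve a [pr_curve()] result.
#' @param path output path (columns threshold,precision,recall,f1).
#' @return the path, invisibly.
#' @export
write_pr_curve_csv <- function(curve, path) {
  stopifnot(inherits(curve, "pr_curve"))
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}
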