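#' ICP configuration
#'
#' Controls the iterative-closest-point refinement. Two stage layouts are
#' offered. `three_stage` is the classical multiscale schedule: (1) ICP at
#' `voxel_size` / `distance_threshold` for `base_iterations`; (2) restart from
#' the stage-1 result with the voxel size halved; (3) restart at the original
#' voxel size with the threshold tightened (halved) to sharpen convergence.
#' `single` runs one stage for `base_iterations * iteration_multiplier`
#' iterations — for thin plant structures the deep single-stage run is the
#' variant that keeps registration from collapsing, with the multiplier
#' defaulting to 10.
#'
#' Defaults (`voxel_size` twice the evaluation threshold, 30 base iterations)
#' are engineering choices, configurable per run. Set `voxel_size` below the
#' sampling resolution of the clouds to make the voxel downsampling lossless
#' when exact transform recovery matters.
#'
#' @param voxel_size voxel edge (meters) for grid downsampling before
#'   correspondence search.
#' @param distance_threshold maximum correspondence distance (meters).
#' @param base_iterations iterations per stage.
#' @param iteration_multiplier multiplier applied in the `single` layout.
#' @param stages `"single"` or `"three_stage"`.
#' @param convergence_tolerance relative change in fitness and inlier RMSE
#'   below which iteration stops early.
#' @return object of class `icp_config`.
#' @export
icp_config <- function(voxel_size = 0.01, distance_threshold = 0.02,
                       base_iterations = 30L, iteration_multiplier = 10L,
                       stages = c("single", "three_stage"),
                       convergence_tolerance = 1e-7) {
  stages <- match.arg(stages)
  if (!is.finite(voxel_size) || voxel_size <= 0) abort_input("voxel_size must be > 0")
  if (!is.finite(distance_threshold) || distance_threshold <= 0)
    abort_input("distance_threshold must be > 0")
  base_iterations <- as.integer(base_iterations)
  iteration_multiplier <- as.integer(iteration_multiplier)
  if (base_iterations < 1L) abort_input("base_iterations must be >= 1")
  if (iteration_multiplier < 1L) abort_input("iteration_multiplier must be >= 1")
  if (!is.finite(convergence_tolerance) || convergence_tolerance < 0)
    abort_input("convergence_tolerance must be >= 0")
  structure(list(voxel_size = voxel_size,
                 distance_threshold = distance_threshold,
                 base_iterations = base_iterations,
                 iteration_multiplier = iteration_multiplier,
                 stages = stages,
                 convergence_tolerance = convergence_tolerance),
            class = "icp_config")
}

#' Refine an alignment with iterative closest point
#'
#' Point-to-point ICP between voxel-downsampled clouds, starting from
#' `initial`. Refinement is rigid: the scale estimated during initialization
#' is frozen and only rotation/translation are updated. Each iteration finds
#' nearest neighbors of the transformed source in the target, keeps pairs
#' closer than the distance threshold, and solves the least-squares rigid
#' update (Kabsch). Iteration stops early when both the fitness (matched
#' fraction) and the inlier RMSE change by less than the configured relative
#' tolerance. The returned transform is the evaluated iterate with the lowest
#' inlier RMSE (ties to the latest), so refinement never reports a worse
#' alignment than the initial transform. Fully deterministic.
#'
#' @param source,target [point_cloud()]s with at least 10 points each.
#' @param initial a [similarity_transform()] (identity allowed).
#' @param config an [icp_config()].
#' @return object of class `registration_result`: `transform`,
#'   `inlier_rmse` (meters), `fitness` (fraction of source points matched),
#'   `iterations_run`.
#' @export
icp_refine <- function(source, target, initial = similarity_transform(),
                       config = icp_config()) {
  stopifnot(inherits(source, "point_cloud"), inherits(target, "point_cloud"),
            inherits(initial, "similarity_transform"), inherits(config, "icp_config"))
  if (n_points(source) < 10L || n_points(target) < 10L)
    abort_input("ICP needs at least 10 points in each cloud")

  if (config$stages == "single") {
    st <- icp_stage(source, target, initial,
                    voxel = config$voxel_size,
                    threshold = config$distance_threshold,
                    max_iter = config$base_iterations * config$iteration_multiplier,
                    tol = config$convergence_tolerance)
    res <- st
  } else {
    s1 <- icp_stage(source, target, initial,
                    voxel = config$voxel_size,
                    threshold = config$distance_threshold,
                    max_iter = config$base_iterations,
                    tol = config$convergence_tolerance)
    s2 <- icp_stage(source, target, s1$transform,
                    voxel = config$voxel_size / 2,
                    threshold = config$distance_threshold,
                    max_iter = config$base_iterations,
                    tol = config$convergence_tolerance)
    s3 <- icp_stage(source, target, s2$transform,
                    voxel = config$voxel_size,
                    threshold = config$distance_threshold / 2,
                    max_iter = config$base_iterations,
                    tol = config$convergence_tolerance)
    res <- s3
    res$iterations_run <- s1$iterations_run + s2$iterations_run + s3$iterations_run
  }
  structure(res, class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("<registration_result> fitness %.4f, inlier RMSE %.6g m, %d iterations\n",
              x$fitness, x$inlier_rmse, x$iterations_run))
  invisible(x)
}

# One ICP stage. Evaluates the initial transform first so the best-by-RMSE
# bookkeeping guarantees the result is never worse than the input alignment.
icp_stage <- function(source, target, initial, voxel, threshold, max_iter, tol) {
  src <- voxel_downsample(source$points, voxel)
  tgt <- voxel_downsample(target$points, voxel)

  evaluate <- function(tf) {
    p <- transform_points(src, tf)
    nn <- cpp_nn(p, tgt)
    m <- nn$dist < threshold
    list(p = p, match = m, idx = nn$index,
         fitness = mean(m),
         rmse = if (any(m)) sqrt(mean(nn$dist[m]^2)) else Inf)
  }

  tf <- initial
  ev <- evaluate(tf)
  if (!any(ev$match))
    abort_stage("ICP found no correspondences within threshold %g at start", threshold,
                data = list(initial = initial))
  best <- list(transform = tf, fitness = ev$fitness, rmse = ev$rmse)
  iterations <- 0L
  for (it in seq_len(max_iter)) {
    p_m <- ev$p[ev$match, , drop = FALSE]
    q_m <- tgt[ev$idx[ev$match], , drop = FALSE]
    rigid <- kabsch_rigid(p_m, q_m)
    tf <- compose_transforms(rigid, tf)
    prev <- ev
    ev <- evaluate(tf)
    iterations <- it
    if (!any(ev$match)) { tf <- best$transform; break }
    if (ev$rmse <= best$rmse) {
      best <- list(transform = tf, fitness = ev$fitness, rmse = ev$rmse)
    }
    rel_f <- abs(ev$fitness - prev$fitness) / max(prev$fitness, .Machine$double.eps)
    rel_r <- abs(ev$rmse - prev$rmse) / max(prev$rmse, .Machine$double.eps)
    if (rel_f < tol && rel_r < tol) break
  }
  list(transform = best$transform, fitness = best$fitness,
       inlier_rmse = best$rmse, iterations_run = iterations)
}

# Least-squares rigid motion (rotation + translation, unit scale) mapping p
# onto q; Kabsch with the usual reflection guard.
kabsch_rigid <- function(p, q) {
  mu_p <- colMeans(p)
  mu_q <- colMeans(q)
  h <- crossprod(sweep(q, 2, mu_q), sweep(p, 2, mu_p))
  dec <- svd(h)
  d_sign <- sign(det(dec$u) * det(dec$v))
  if (d_sign == 0) d_sign <- 1
  R <- dec$u %*% diag(c(1, 1, d_sign)) %*% t(dec$v)
  similarity_transform(scale = 1, rotation = R,
                       translation = mu_q - as.vector(R %*% mu_p))
}
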