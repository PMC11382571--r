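#' Parameters of the synthetic plant surface cloud
#'
#' Describes a simplified plant — a cylindrical stem with drooping parabolic
#' leaf ribbons — sampled uniformly by area, standing in for a
#' terrestrial-laser-scan ground truth. Defaults emulate a late-vegetative
#' corn plant scanned at roughly 7 mm resolution: a 1.2 m stem, 8 leaves of
#' 0.5 m, and an areal density of 2e4 points per square meter (mean point
#' spacing ~ 1/sqrt(density) = 7 mm).
#'
#' @param stem_height stem height (meters).
#' @param stem_radius stem radius (meters).
#' @param leaf_count number of leaves.
#' @param leaf_length leaf length along the midrib (meters).
#' @param leaf_droop quadratic droop coefficient (1/meters); the leaf tip
#'   drops by `leaf_droop * leaf_length^2` relative to its straight path.
#' @param sampling_density points per square meter of surface.
#' @param seed integer seed; the generator is a pure function of parameters
#'   and seed.
#' @return object of class `plant_params`.
#' @export
plant_params <- function(stem_height = 1.2, stem_radius = 0.02,
                         leaf_count = 8L, leaf_length = 0.5,
                         leaf_droop = 0.5, sampling_density = 2e4,
                         seed = 1L) {
  leaf_count <- as.integer(leaf_count)
  if (any(!is.finite(c(stem_height, stem_radius, leaf_length, leaf_droop,
                       sampling_density))) ||
      stem_height <= 0 || stem_radius <= 0 || leaf_length <= 0 ||
      leaf_droop < 0 || sampling_density <= 0)
    abort_input("physical plant parameters must be positive")
  if (leaf_count < 0L) abort_input("leaf_count must be >= 0")
  structure(list(stem_height = stem_height, stem_radius = stem_radius,
                 leaf_count = leaf_count, leaf_length = leaf_length,
                 leaf_droop = leaf_droop, sampling_density = sampling_density,
                 seed = as.integer(seed)),
            class = "plant_params")
}

# Leaf centerline in local (radial distance rho, height z) coordinates:
# rho(s) = s cos(beta), z(s) = s sin(beta) - droop s^2, s in [0, leaf_length],
# with launch elevation beta = 35 degrees. Arc speed for uniform-by-area
# sampling along s.
leaf_beta <- 35 * pi / 180

leaf_arc_speed <- function(s, droop) {
  sqrt(cos(leaf_beta)^2 + (sin(leaf_beta) - 2 * droop * s)^2)
}

leaf_arc_length <- function(len, droop, n = 512L) {
  s <- seq(0, len, length.out = n)
  sum((leaf_arc_speed(s[-1], droop) + leaf_arc_speed(s[-n], droop)) / 2) * (len / (n - 1))
}

#' Generate a synthetic plant point cloud
#'
#' Samples the stem cylinder and each leaf ribbon with Poisson(area x
#' density) points placed uniformly by surface area (leaf arclength sampled
#' by inverse transform of the arc speed). Leaves attach at evenly spaced
#' heights between 40% and 95% of the stem, at golden-angle azimuths. Two
#' deterministic anchor points close the stem at z = 0 and z = stem_height,
#' so the z-extent of the cloud is at least the stem height and at most
#' stem height + leaf length. Deterministic per seed.
#'
#' @param params a [plant_params()].
#' @return a [point_cloud()]. The generator's surface area (m^2) is attached
#'   as attribute `surface_area`.
#' @export
generate_plant_cloud <- function(params = plant_params()) {
  stopifnot(inherits(params, "plant_params"))
  withr::with_seed(params$seed, {
    h <- params$stem_height
    r <- params$stem_radius
    stem_area <- 2 * pi * r * h
    leaf_w <- params$leaf_length / 8
    arc <- leaf_arc_length(params$leaf_length, params$leaf_droop)
    leaf_area <- leaf_w * arc
    total_area <- stem_area + params$leaf_count * leaf_area

    n_stem <- stats::rpois(1, params$sampling_density * stem_area)
    theta <- stats::runif(n_stem, 0, 2 * pi)
    z <- stats::runif(n_stem, 0, h)
    stem <- cbind(r * cos(theta), r * sin(theta), z)
    # anchors guaranteeing the construction bound on the z-extent
    stem <- rbind(stem, c(r, 0, 0), c(r, 0, h))

    leaves <- vector("list", params$leaf_count)
    if (params$leaf_count > 0L) {
      attach_z <- seq(0.4 * h, 0.95 * h, length.out = params$leaf_count)
      azimuth <- (seq_len(params$leaf_count) - 1) * 2.399963  # golden angle
      # inverse-cdf table for arclength-uniform sampling of s
      sg <- seq(0, params$leaf_length, length.out = 512L)
      speed <- leaf_arc_speed(sg, params$leaf_droop)
      cdf <- cumsum(c(0, (speed[-1] + speed[-length(speed)]) / 2 * diff(sg)))
      cdf <- cdf / cdf[length(cdf)]
      for (k in seq_len(params$leaf_count)) {
        n_k <- stats::rpois(1, params$sampling_density * leaf_area)
        if (n_k == 0L) next
        u <- stats::runif(n_k)
        s <- stats::approx(cdf, sg, xout = u, rule = 2)$y
        t_ <- stats::runif(n_k, -leaf_w / 2, leaf_w / 2)
        rho <- r + s * cos(leaf_beta)
        zz <- attach_z[k] + s * sin(leaf_beta) - params$leaf_droop * s^2
        ca <- cos(azimuth[k]); sa <- sin(azimuth[k])
        # ribbon spans the horizontal direction perpendicular to the midrib
        leaves[[k]] <- cbind(rho * ca - t_ * sa, rho * sa + t_ * ca, zz)
      }
    }
    pts <- do.call(rbind, c(list(stem), leaves[!vapply(leaves, is.null, logical(1))]))
    out <- point_cloud(pts)
    attr(out, "surface_area") <- total_area
    out
  })
}

#' Degradation parameters for a synthetic reconstruction
#'
#' Emulates a point cloud exported from a trained radiance field: coordinate
#' jitter, random dropout, a sprinkle of gross outliers, and an unknown
#' similarity transform taking it out of the ground-truth frame. Applied in
#' that order: transform, jitter, dropout, outlier injection.
#'
#' @param jitter_sigma isotropic Gaussian coordinate noise sd (meters).
#' @param dropout_fraction per-point independent removal probability in
#'   `[0, 1)`.
#' @param outlier_fraction outliers injected as a fraction of the retained
#'   count, `>= 0`.
#' @param outlier_scale half-width (meters) by which the cloud's bounding box
#'   is inflated when placing outliers.
#' @param transform optional [similarity_transform()] applied first.
#' @param seed integer seed.
#' @return object of class `degrade_params`.
#' @export
degrade_params <- function(jitter_sigma = 0.002, dropout_fraction = 0.2,
                           outlier_fraction = 0.01, outlier_scale = 0.25,
                           transform = NULL, seed = 1L) {
  if (!is.finite(jitter_sigma) || jitter_sigma < 0)
    abort_input("jitter_sigma must be >= 0")
  if (!is.finite(dropout_fraction) || dropout_fraction < 0 || dropout_fraction >= 1)
    abort_input("dropout_fraction must lie in [0, 1)")
  if (!is.finite(outlier_fraction) || outlier_fraction < 0)
    abort_input("outlier_fraction must be >= 0")
  if (!is.finite(outlier_scale) || outlier_scale < 0)
    abort_input("outlier_scale must be >= 0")
  if (!is.null(transform)) stopifnot(inherits(transform, "similarity_transform"))
  structure(list(jitter_sigma = jitter_sigma, dropout_fraction = dropout_fraction,
                 outlier_fraction = outlier_fraction, outlier_scale = outlier_scale,
                 transform = transform, seed = as.integer(seed)),
            class = "degrade_params")
}

#' Degrade a cloud into a synthetic reconstruction
#'
#' @param cloud the source [point_cloud()] (e.g. a [generate_plant_cloud()]
#'   output).
#' @param params a [degrade_params()].
#' @return the degraded `point_cloud`. Injected outliers receive the mean
#'   color when the source carries color.
#' @export
degrade_cloud <- function(cloud, params = degrade_params()) {
  stopifnot(inherits(cloud, "point_cloud"), inherits(params, "degrade_params"))
  withr::with_seed(params$seed, {
    pts <- cloud$points
    cols <- cloud$colors
    if (!is.null(params$transform))
      pts <- transform_points(pts, params$transform)
    if (params$jitter_sigma > 0)
      pts <- pts + matrix(stats::rnorm(length(pts), sd = params$jitter_sigma),
                          nrow(pts), 3)
    if (params$dropout_fraction > 0) {
      keep <- stats::runif(nrow(pts)) >= params$dropout_fraction
      if (!any(keep)) abort_stage("dropout removed every point")
      pts <- pts[keep, , drop = FALSE]
      if (!is.null(cols)) cols <- cols[keep, , drop = FALSE]
    }
    if (params$outlier_fraction > 0) {
      n_out <- round(params$outlier_fraction * nrow(pts))
      if (n_out > 0) {
        lo <- apply(pts, 2, min) - params$outlier_scale
        hi <- apply(pts, 2, max) + params$outlier_scale
        out_pts <- cbind(stats::runif(n_out, lo[1], hi[1]),
                         stats::runif(n_out, lo[2], hi[2]),
                         stats::runif(n_out, lo[3], hi[3]))
        pts <- rbind(pts, out_pts)
        if (!is.null(cols))
          cols <- rbind(cols, matrix(as.integer(round(colMeans(cols))),
                                     n_out, 3, byrow = TRUE))
      }
    }
    point_cloud(pts, cols)
  })
}

#' Generate a synthetic training curve with an engineered plateau
#'
#' Exponential decay from `start_value` toward `floor_value` whose amplitude
#' falls to 1e-3 of itself at `plateau_iteration` (so the curve is flat on
#' the scale of typical plateau thresholds from there on), plus optional
#' seeded Gaussian noise, sampled at the given checkpoint iterations. With
#' zero noise the series is strictly decreasing.
#'
#' @param plateau_iteration iteration by which the decay has flattened; must
#'   lie within the checkpoint span.
#' @param start_value,floor_value curve endpoints, `start_value > floor_value
#'   >= 0`.
#' @param noise_sigma sd of additive Gaussian noise (0 for none).
#' @param checkpoints strictly increasing iteration vector.
#' @param seed integer seed.
#' @return a [metric_series()].
#' @export
generate_training_curve <- function(plateau_iteration, start_value = 0.6,
                                    floor_value = 0.1, noise_sigma = 0,
                                    checkpoints = c(1000, 2000, 4000, 8000,
                                                    16000, 32000, 60000),
                                    seed = 1L) {
  checkpoints <- as.numeric(checkpoints)
  if (is.unsorted(checkpoints, strictly = TRUE))
    abort_input("checkpoints must be strictly increasing")
  if (!is.finite(start_value) || !is.finite(floor_value) ||
      start_value <= floor_value || floor_value < 0)
    abort_input("need start_value > floor_value >= 0")
  if (plateau_iteration <= checkpoints[1] ||
      plateau_iteration > checkpoints[length(checkpoints)])
    abort_input("plateau_iteration must lie within the checkpoint span")
  if (!is.finite(noise_sigma) || noise_sigma < 0)
    abort_input("noise_sigma must be >= 0")
  k <- log(1000) / (plateau_iteration - checkpoints[1])
  vals <- floor_value + (start_value - floor_value) *
    exp(-k * (checkpoints - checkpoints[1]))
  if (noise_sigma > 0)
    vals <- withr::with_seed(seed, vals + stats::rnorm(length(vals), sd = noise_sigma))
  metric_series(checkpoints, vals)
}

#' Generate a deterministic image pair (reference, degraded)
#'
#' The base image is a fixed sinusoidal texture with integer intensities in
#' `[0, 250]`; the second image is a degraded copy. Stands in for a
#' (validation, rendered) pair.
#'
#' @param size `c(rows, cols)`, each `>= 8`.
#' @param degradation one of `"none"`, `"gaussian_noise"` (sd `amount`,
#'   clipped to range), `"blur"` (box blur of radius `amount`),
#'   `"intensity_shift"` (adds `amount`; exact for `amount <= 5`, clipped
#'   above).
#' @param amount degradation strength (ignored for `"none"`).
#' @param seed integer seed (used by the noise degradation).
#' @return list of two [as_raster()] objects: `reference`, `degraded`.
#' @export
generate_image_pair <- function(size = c(64, 64),
                                degradation = c("none", "gaussian_noise",
                                                "blur", "intensity_shift"),
                                amount = 0, seed = 1L) {
  degradation <- match.arg(degradation)
  size <- as.integer(size)
  if (length(size) != 2L || any(size < 8L)) abort_input("size must be >= 8 x 8")
  i <- matrix(seq_len(size[1]), size[1], size[2])
  j <- matrix(seq_len(size[2]), size[1], size[2], byrow = TRUE)
  base <- 125 + 60 * sin(2 * pi * 3 * i / size[1]) * cos(2 * pi * 2 * j / size[2]) +
    40 * sin(2 * pi * (i + j) / 17)
  base <- round(pmin(pmax(base, 0), 250))
  deg <- switch(degradation,
    none = base,
    gaussian_noise = withr::with_seed(seed, {
      pmin(pmax(base + matrix(stats::rnorm(length(base), sd = amount),
                              size[1], size[2]), 0), 255)
    }),
    blur = box_blur(base, as.integer(amount)),
    intensity_shift = pmin(pmax(base + amount, 0), 255))
  list(reference = as_raster(base), degraded = as_raster(deg))
}

# Separable box blur with edge replication.
box_blur <- function(img, radius) {
  if (radius < 1L) return(img)
  w <- 2L * radius + 1L
  pad_rows <- rbind(img[rep(1L, radius), , drop = FALSE], img,
                    img[rep(nrow(img), radius), , drop = FALSE])
  sm <- apply(pad_rows, 2, function(col) stats::filter(col, rep(1 / w, w)))
  sm <- sm[(radius + 1L):(radius + nrow(img)), , drop = FALSE]
  pad_cols <- cbind(sm[, rep(1L, radius), drop = FALSE], sm,
                    sm[, rep(ncol(sm), radius), drop = FALSE])
  sm2 <- t(apply(pad_cols, 1, function(row) stats::filter(row, rep(1 / w, w))))
  sm2[, (radius + 1L):(radius + ncol(img)), drop = FALSE]
}
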