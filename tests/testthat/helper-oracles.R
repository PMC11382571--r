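# Independent brute-force oracles and small constructors shared by the tests.
# The oracles avoid colSums/crossprod so every arithmetic step runs in plain
# double precision, matching the compiled kd-tree bit for bit.

brute_nn_dist <- function(query, reference) {
  q <- if (inherits(query, "point_cloud")) query$points else as.matrix(query)
  r <- if (inherits(reference, "point_cloud")) reference$points else as.matrix(reference)
  apply(q, 1, function(p) {
    dx <- r[, 1] - p[1]
    dy <- r[, 2] - p[2]
    dz <- r[, 3] - p[3]
    min(sqrt(dx * dx + dy * dy + dz * dz))
  })
}

brute_precision <- function(recon, gt, d) 100 * mean(brute_nn_dist(recon, gt) < d)
brute_recall <- function(recon, gt, d) 100 * mean(brute_nn_dist(gt, recon) < d)

# Mean distance to the k nearest neighbours of every point, O(N^2).
brute_knn_mean_dist <- function(points, k) {
  n <- nrow(points)
  vapply(seq_len(n), function(i) {
    dx <- points[, 1] - points[i, 1]
    dy <- points[, 2] - points[i, 2]
    dz <- points[, 3] - points[i, 3]
    d <- sqrt(dx * dx + dy * dy + dz * dz)[-i]
    mean(sort(d)[seq_len(k)])
  }, numeric(1))
}

# First index i (1-based) whose C consecutive absolute diffs are all < theta.
brute_first_window <- function(values, theta, consistency) {
  d <- abs(diff(values))
  for (i in seq_len(length(d) - consistency + 1L)) {
    if (all(d[i:(i + consistency - 1L)] < theta)) return(i)
  }
  NA_integer_
}

rot_z <- function(angle) {
  rbind(c(cos(angle), -sin(angle), 0),
        c(sin(angle), cos(angle), 0),
        c(0, 0, 1))
}

random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  q <- q %*% diag(sign(diag(qr.R(qr_))))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

random_similarity <- function(scale_range = c(0.8, 1.25), shift = 0.3) {
  similarity_transform(scale = stats::runif(1, scale_range[1], scale_range[2]),
                       rotation = random_rotation(),
                       translation = stats::runif(3, -shift, shift))
}

random_cloud <- function(n, spread = 1) {
  point_cloud(matrix(stats::runif(3 * n, 0, spread), n, 3))
}

test_plant <- function(density = 3000, seed = 1) {
  generate_plant_cloud(plant_params(sampling_density = density, seed = seed))
}

# One-layer backbone returning fixed 1x1xC features per image identity,
# for hand-checkable perceptual-distance cases.
toy_backbone <- function(feature_map, weights = NULL) {
  feature_backbone(function(raster) {
    key <- format(sum(raster$pixels))
    list(array(feature_map[[key]], dim = c(1, 1, length(feature_map[[key]]))))
  }, channel_weights = weights)
}

rotation_angle <- function(r_est, r_true) {
  rel <- r_est %*% t(r_true)
  acos(min(1, max(-1, (sum(diag(rel)) - 1) / 2)))
}
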