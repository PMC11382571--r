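test_that("similarity transforms compose, invert and validate", {
  expect_error(similarity_transform(scale = -1), "positive")
  expect_error(similarity_transform(rotation = diag(3) * 1.001), "orthonormal")
  refl <- diag(c(-1, 1, 1))
  expect_error(similarity_transform(rotation = refl), "proper")

  withr::with_seed(21, {
    for (i in 1:10) {
      a <- random_similarity()
      b <- random_similarity()
      p <- matrix(rnorm(30), 10, 3)
      # composition applies b first
      expect_equal(apply_transform(apply_transform(p, b), a),
                   apply_transform(p, compose_transforms(a, b)), tolerance = 1e-12)
      # inverse law
      expect_equal(apply_transform(apply_transform(p, a), invert_transform(a)),
                   p, tolerance = 1e-9)
      # closure: composed rotation stays orthonormal within the class tolerance
      ab <- compose_transforms(a, b)
      expect_lt(max(abs(crossprod(ab$rotation) - diag(3))), 1e-9)
    }
  })
})

test_that("apply_transform maps points as scale * R * p + t", {
  pc <- point_cloud(rbind(c(1, 0, 0)), colors = rbind(c(10L, 20L, 30L)))
  tf <- similarity_transform(rotation = rot_z(pi / 2))
  got <- apply_transform(pc, tf)
  expect_equal(got$points, rbind(c(0, 1, 0)), tolerance = 1e-15)
  expect_identical(got$colors, pc$colors)
  expect_equal(apply_transform(pc, similarity_transform())$points, pc$points)
})

test_that("correspondence initialization recovers exact similarity transforms", {
  src <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0.3, 0.2, 1.4))
  expect_equal(estimate_initial_transform(src, src)$scale, 1, tolerance = 1e-12)
  expect_equal(estimate_initial_transform(src, src)$translation, c(0, 0, 0),
               tolerance = 1e-12)

  truth <- similarity_transform(scale = 2, rotation = rot_z(pi / 2),
                                translation = c(1, 0, 0))
  tgt <- apply_transform(src, truth)
  est <- estimate_initial_transform(src, tgt)
  expect_equal(est$scale, 2, tolerance = 1e-9)
  expect_equal(est$rotation, truth$rotation, tolerance = 1e-9)
  expect_equal(est$translation, truth$translation, tolerance = 1e-9)

  # random similarities over generic correspondence sets
  withr::with_seed(31, {
    for (i in 1:10) {
      s <- matrix(rnorm(15), 5, 3)
      tf <- random_similarity()
      est2 <- estimate_initial_transform(s, apply_transform(s, tf))
      expect_equal(est2$scale, tf$scale, tolerance = 1e-9)
      expect_lt(max(abs(est2$rotation - tf$rotation)), 1e-9)
      expect_lt(max(abs(est2$translation - tf$translation)), 1e-9)
    }
  })
})

test_that("degenerate correspondence geometry is rejected", {
  line <- rbind(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2))
  expect_error(estimate_initial_transform(line, line), "collinear",
               class = "plantrecon_degenerate_error")
  expect_error(estimate_initial_transform(line[1:2, ], line[1:2, ]), "3 correspondence")
})

test_that("ICP of a cloud onto itself stays at identity", {
  pc <- test_plant(density = 2000, seed = 2)
  cfg <- icp_config(voxel_size = 1e-4, distance_threshold = 0.05,
                    base_iterations = 10, iteration_multiplier = 2)
  res <- icp_refine(pc, pc, similarity_transform(), cfg)
  expect_lt(max(abs(res$transform$rotation - diag(3))), 1e-9)
  expect_lt(max(abs(res$transform$translation)), 1e-9)
  expect_equal(res$fitness, 1)
  expect_lt(res$inlier_rmse, 1e-12)
})

test_that("both stage layouts recover a known rigid motion to 1e-6", {
  pc <- test_plant(density = 2500, seed = 4)
  known <- similarity_transform(rotation = rot_z(5 * pi / 180),
                                translation = c(0.05, -0.02, 0.01))
  src <- apply_transform(pc, known)
  truth <- invert_transform(known)
  for (stages in c("single", "three_stage")) {
    cfg <- icp_config(voxel_size = 1e-4, distance_threshold = 0.2,
                      base_iterations = 30, iteration_multiplier = 10,
                      stages = stages)
    res <- icp_refine(src, pc, similarity_transform(), cfg)
    expect_lt(max(abs(res$transform$translation - truth$translation)), 1e-6)
    expect_lt(rotation_angle(res$transform$rotation, truth$rotation), 1e-6)
  }
})

test_that("ICP under Gaussian jitter stays within the statistical bound", {
  errs <- vapply(1:5, function(seed) {
    pc <- test_plant(density = 2500, seed = seed)
    known <- similarity_transform(rotation = rot_z(5 * pi / 180),
                                  translation = c(0.05, -0.02, 0.01))
    src <- degrade_cloud(apply_transform(pc, known),
                         degrade_params(jitter_sigma = 0.001, dropout_fraction = 0,
                                        outlier_fraction = 0, seed = seed))
    cfg <- icp_config(voxel_size = 1e-4, distance_threshold = 0.2,
                      base_iterations = 30, iteration_multiplier = 10)
    res <- icp_refine(src, pc, similarity_transform(), cfg)
    truth <- invert_transform(known)
    max(abs(res$transform$translation - truth$translation))
  }, numeric(1))
  expect_lt(max(errs), 0.005)
})

test_that("refinement never reports a worse inlier RMSE than its start", {
  pc <- test_plant(density = 2000, seed = 6)
  off <- similarity_transform(rotation = rot_z(2 * pi / 180),
                              translation = c(0.01, 0.01, -0.005))
  src <- apply_transform(pc, off)
  cfg <- icp_config(voxel_size = 1e-4, distance_threshold = 0.1,
                    base_iterations = 5, iteration_multiplier = 1)
  res <- icp_refine(src, pc, similarity_transform(), cfg)
  # RMSE of the identity start on the same downsampled clouds and threshold
  nn0 <- nn_distances(voxel_downsample(src, 1e-4), voxel_downsample(pc, 1e-4))
  rmse0 <- sqrt(mean(nn0[nn0 < 0.1]^2))
  expect_lte(res$inlier_rmse, rmse0)
})

test_that("ICP is deterministic and fails cleanly without correspondences", {
  pc <- test_plant(density = 1500, seed = 8)
  known <- similarity_transform(rotation = rot_z(0.05), translation = c(0.02, 0, 0))
  src <- apply_transform(pc, known)
  cfg <- icp_config(voxel_size = 1e-4, distance_threshold = 0.1,
                    base_iterations = 10, iteration_multiplier = 2)
  r1 <- icp_refine(src, pc, similarity_transform(), cfg)
  r2 <- icp_refine(src, pc, similarity_transform(), cfg)
  expect_identical(r1$transform, r2$transform)
  expect_identical(r1$inlier_rmse, r2$inlier_rmse)

  far <- apply_transform(pc, similarity_transform(translation = c(50, 0, 0)))
  err <- tryCatch(icp_refine(far, pc, similarity_transform(), cfg),
                  error = function(e) e)
  expect_s3_class(err, "plantrecon_stage_error")
  expect_match(conditionMessage(err), "no correspondences")
  expect_s3_class(err$data$initial, "similarity_transform")
})
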