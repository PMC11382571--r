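test_that("point_cloud validates its invariants", {
  expect_s3_class(point_cloud(diag(3)), "point_cloud")
  expect_error(point_cloud(matrix(numeric(0), 0, 3)), "at least one")
  expect_error(point_cloud(rbind(c(0, 0, Inf))), "finite")
  expect_error(point_cloud(diag(3), colors = rbind(c(0, 0, 300), c(0, 0, 0), c(1, 1, 1))),
               "\\[0, 255\\]")
  expect_error(point_cloud(diag(3), colors = rbind(c(0, 0, 0))), "matching")
})

test_that("ASCII PLY with colors loads and XYZ text loads", {
  ply <- tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0", "element vertex 3",
               "property float x", "property float y", "property float z",
               "property uchar red", "property uchar green", "property uchar blue",
               "end_header",
               "0 0 0 255 0 0", "1 0 0 0 255 0", "0 1 0.5 0 0 255"), ply)
  pc <- load_cloud(ply)
  expect_equal(n_points(pc), 3)
  expect_equal(pc$colors, rbind(c(255L, 0L, 0L), c(0L, 255L, 0L), c(0L, 0L, 255L)))
  expect_equal(pc$points[3, 3], 0.5)

  xyz <- tempfile(fileext = ".xyz")
  writeLines(c("0 0 0", "1 0 0"), xyz)
  pc2 <- load_cloud(xyz)
  expect_equal(n_points(pc2), 2)
  expect_null(pc2$colors)
})

test_that("write/load round-trips preserve coordinates within dialect precision", {
  withr::with_seed(42, {
    pc <- point_cloud(matrix(runif(3000, -2, 2), 1000, 3),
                      colors = matrix(sample(0:255, 3000, replace = TRUE), 1000, 3))
  })
  # binary PLY stores float32: relative error bounded by 2^-23
  f <- tempfile(fileext = ".ply")
  write_cloud(pc, f)
  back <- load_cloud(f)
  expect_lt(max(abs(back$points - pc$points)), 2 * 2^-23)
  expect_identical(back$colors, pc$colors)
  # ASCII PLY, PCD and XYZ print full double precision
  for (fmt in c("pcd", "xyz")) {
    f2 <- tempfile(fileext = paste0(".", fmt))
    write_cloud(pc, f2)
    expect_equal(load_cloud(f2)$points, pc$points)
    expect_identical(load_cloud(f2)$colors, pc$colors)
  }
  f3 <- tempfile(fileext = ".ply")
  write_cloud(pc, f3, binary = FALSE)
  expect_equal(load_cloud(f3)$points, pc$points)
})

test_that("binary PLY headers carry the vertex count and color properties", {
  pc <- point_cloud(diag(3))
  f <- tempfile(fileext = ".ply")
  write_cloud(pc, f)
  hdr <- readLines(f, n = 3, warn = FALSE)
  expect_equal(hdr[3], "element vertex 3")
})

test_that("malformed cloud files fail with the offending location", {
  expect_error(load_cloud(tempfile(fileext = ".ply")), "not found")
  empty <- tempfile(fileext = ".xyz")
  writeLines(character(0), empty)
  expect_error(load_cloud(empty), "zero points")
  bad <- tempfile(fileext = ".xyz")
  writeLines(c("0 0 0", "1 oops 0"), bad)
  expect_error(load_cloud(bad), "line 2")
  short <- tempfile(fileext = ".xyz")
  writeLines(c("0 0 0", "1 1"), short)
  expect_error(load_cloud(short), "line 2")
  odd <- tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0", "element vertex 1",
               "property float x", "property float y", "property float z",
               "property float nx", "end_header", "0 0 0 0"), odd)
  expect_error(load_cloud(odd), "unsupported")
})

test_that("crop keeps exactly the closed-box members, in order", {
  pc <- point_cloud(rbind(c(0.5, 0.5, 0.5), c(2, 2, 2)))
  box <- bounding_volume(c(0, 0, 0), c(1, 1, 1))
  expect_equal(crop_to_bounds(pc, box)$points, rbind(c(0.5, 0.5, 0.5)))

  withr::with_seed(7, {
    cloud <- random_cloud(400, spread = 2)
  })
  box2 <- bounding_volume(c(0.3, 0.2, 0.5), c(1.5, 1.9, 1.1))
  got <- crop_to_bounds(cloud, box2)
  inside <- apply(cloud$points, 1, function(p)
    all(p >= box2$min_corner & p <= box2$max_corner))
  expect_equal(got$points, cloud$points[inside, , drop = FALSE])
  # idempotent, and a whole-cloud box is the identity
  expect_equal(crop_to_bounds(got, box2)$points, got$points)
  big <- bounding_volume(c(-1, -1, -1), c(3, 3, 3))
  expect_equal(crop_to_bounds(cloud, big)$points, cloud$points)
  # boundary points are kept (closed box)
  edge <- point_cloud(rbind(c(0, 0, 0), c(1, 1, 1), c(1.0000001, 1, 1)))
  unit <- bounding_volume(c(0, 0, 0), c(1, 1, 1))
  expect_equal(n_points(crop_to_bounds(edge, unit)), 2)
  # a box that misses everything is a misplaced-crop error
  expect_error(crop_to_bounds(pc, bounding_volume(c(5, 5, 5), c(6, 6, 6))), "empty")
})

test_that("duplicate removal keeps first occurrences and honors epsilon", {
  two <- point_cloud(rbind(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(n_points(remove_duplicates(two, epsilon = 0)), 1)

  near <- point_cloud(rbind(c(0, 0, 0), c(0.001, 0, 0)))
  expect_equal(n_points(remove_duplicates(near, epsilon = 0.002)), 1)
  expect_equal(remove_duplicates(near, epsilon = 0.002)$points, rbind(c(0, 0, 0)))

  withr::with_seed(11, {
    cloud <- random_cloud(200)
  })
  dmin <- min(dist(cloud$points))
  expect_equal(remove_duplicates(cloud, epsilon = dmin * 0.99)$points, cloud$points)

  # property: no two retained points closer than epsilon, earliest kept
  withr::with_seed(12, {
    coarse <- point_cloud(matrix(round(runif(600, 0, 1), 1), 200, 3))
  })
  eps <- 0.15
  kept <- remove_duplicates(coarse, epsilon = eps)
  expect_gte(min(dist(kept$points)), eps)
  expect_equal(kept$points[1, ], coarse$points[1, ])
})

test_that("statistical outlier removal matches the brute-force statistic", {
  withr::with_seed(3, {
    dense <- matrix(runif(3000), 1000, 3)
  })
  cloud <- point_cloud(rbind(dense, c(100, 100, 100)))
  out <- remove_statistical_outliers(cloud, k_neighbors = 8, std_ratio = 3)
  expect_equal(n_points(out), 1000)
  expect_equal(attr(out, "n_removed"), 1)
  expect_true(max(out$points) < 100)

  # exact agreement with an O(N^2) recomputation of the same statistic
  md <- brute_knn_mean_dist(cloud$points, 8)
  keep <- md <= mean(md) + 3 * sd(md)
  expect_equal(out$points, cloud$points[keep, , drop = FALSE])

  # a uniform grid has no outliers at ratio 3 by construction
  g <- as.matrix(expand.grid(x = seq(0, 1, length.out = 6),
                             y = seq(0, 1, length.out = 6),
                             z = seq(0, 1, length.out = 6)))
  grid_cloud <- point_cloud(g)
  cleaned <- remove_statistical_outliers(grid_cloud, k_neighbors = 6, std_ratio = 3)
  expect_equal(n_points(cleaned), n_points(grid_cloud))
  expect_equal(attr(cleaned, "n_removed"), 0)
  expect_error(remove_statistical_outliers(point_cloud(diag(3)), k_neighbors = 5),
               "too small")
})

test_that("voxel downsampling returns first-occurrence-ordered cell centroids", {
  pts <- rbind(c(0.1, 0.1, 0.1), c(0.9, 0.9, 0.9), c(0.2, 0.1, 0.1))
  got <- voxel_downsample(pts, 0.5)
  expect_equal(got, rbind(c(0.15, 0.1, 0.1), c(0.9, 0.9, 0.9)))
  # voxel below the minimum spacing is lossless
  withr::with_seed(5, {
    cloud <- random_cloud(100)
  })
  expect_equal(voxel_downsample(cloud, 1e-9), cloud$points)
})
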