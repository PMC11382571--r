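test_that("metric series validate ordering and finiteness", {
  expect_s3_class(metric_series(c(0, 10), c(1, 0.5)), "metric_series")
  expect_error(metric_series(c(10, 0), c(1, 2)), "strictly increasing")
  expect_error(metric_series(c(0, 0), c(1, 2)), "strictly increasing")
  expect_error(metric_series(c(-1, 2), c(1, 2)), "non-negative")
  expect_error(metric_series(c(1, 2), c(1, NA)), "finite")
})

test_that("interpolation is linear, hits checkpoints, and holds the tail", {
  s <- metric_series(c(0, 10), c(1, 0))
  cfg <- plateau_config(granularity = 11, total_iterations = 10)
  g <- interpolate_series(s, cfg)
  expect_equal(g$iterations, 0:10)
  expect_equal(g$values[6], 0.5)          # midpoint
  expect_equal(g$values[1], 1)
  expect_equal(g$values[11], 0)

  # hold rule beyond the last checkpoint
  cfg2 <- plateau_config(granularity = 21, total_iterations = 20)
  g2 <- interpolate_series(s, cfg2)
  expect_true(all(g2$values[11:21] == 0))

  # geometric checkpoint spacing with values 1/iteration, probed at 3 points
  its <- c(1000, 2000, 4000, 8000, 16000, 32000)
  gs <- metric_series(its, 1 / its)
  cfg3 <- plateau_config(granularity = 32, total_iterations = 32000)
  g3 <- interpolate_series(gs, cfg3)
  probe <- function(x) {
    i <- findInterval(x, its)
    w <- (x - its[i]) / (its[i + 1] - its[i])
    (1 - w) / its[i] + w / its[i + 1]
  }
  for (x in c(3000, 12000, 21000)) {
    j <- which.min(abs(g3$iterations - x))
    expect_equal(g3$values[j], probe(g3$iterations[j]), tolerance = 1e-12)
  }
  # interpolation preserves monotonicity of a monotone source
  expect_true(all(diff(g3$values) <= 0))
  expect_error(interpolate_series(metric_series(5, 1), cfg), "at least 2")
})

test_that("plateau detection finds the first qualifying window", {
  theta <- 0.005
  cfg <- plateau_config(theta = theta, consistency = 6)

  const <- metric_series(0:19, rep(0.3, 20))
  res <- detect_plateau(const, cfg)
  expect_true(res$found)
  expect_equal(res$plateau_index, 1)
  expect_equal(res$recommended_iteration, const$iterations[1 + 6])

  linear <- metric_series(0:19, 1 - (0:19) * 2 * theta)
  expect_false(detect_plateau(linear, cfg)$found)

  # diffs [10t, 8t, 4t, 2t, t/2 x 8]: first window of 6 sub-theta diffs
  # starts at the 5th difference
  diffs <- c(10, 8, 4, 2, rep(0.5, 8)) * theta
  vals <- 1 - cumsum(c(0, diffs))
  s <- metric_series(seq_along(vals) - 1, vals)
  res2 <- detect_plateau(s, cfg)
  expect_true(res2$found)
  expect_equal(res2$plateau_index, 5)
  expect_equal(res2$recommended_iteration, s$iterations[5 + 6])

  expect_error(detect_plateau(metric_series(0:5, rep(1, 6)), cfg), "consistency")
})

test_that("plateau detection agrees with a brute-force window scan", {
  withr::with_seed(301, {
    for (i in 1:50) {
      n <- sample(10:120, 1)
      vals <- cumsum(rnorm(n, sd = 0.01))
      theta <- runif(1, 0.001, 0.02)
      cc <- sample(2:8, 1)
      cfg <- plateau_config(theta = theta, consistency = cc)
      if (n <= cc) next
      s <- metric_series(seq_len(n), vals)
      got <- detect_plateau(s, cfg)
      want <- brute_first_window(vals, theta, cc)
      if (is.na(want)) {
        expect_false(got$found)
      } else {
        expect_true(got$found)
        expect_equal(got$plateau_index, want)
      }
      # invariance under constant shift and negation
      expect_equal(detect_plateau(metric_series(seq_len(n), vals + 5), cfg)$plateau_index,
                   got$plateau_index)
      expect_equal(detect_plateau(metric_series(seq_len(n), -vals), cfg)$plateau_index,
                   got$plateau_index)
    }
  })
})

test_that("smaller theta never recommends stopping earlier", {
  curve <- generate_training_curve(20000, noise_sigma = 0, seed = 1)
  cfg_of <- function(theta) plateau_config(theta = theta, granularity = 500)
  recs <- vapply(c(0.02, 0.01, 0.005, 0.002, 0.001), function(th)
    recommend_stop(curve, cfg_of(th))$iteration, numeric(1))
  expect_true(all(diff(recs) >= 0))
})

test_that("stop recommendation lands on the engineered plateau", {
  cfg <- plateau_config()     # theta 0.005, C 6, 1000 points, 60000 iterations
  curve <- generate_training_curve(20000, noise_sigma = 0, seed = 1)
  dec <- recommend_stop(curve, cfg)
  step <- diff(dec$interpolated$iterations[1:2])
  # brute scan of the interpolated series gives the first confirmable index
  want <- brute_first_window(dec$interpolated$values, cfg$theta, cfg$consistency)
  expect_false(is.na(want))
  confirm <- dec$interpolated$iterations[want + cfg$consistency]
  expect_lte(abs(dec$iteration - confirm), step)

  # constant series: confirmation near the start of the grid
  const <- metric_series(c(0, 60000), c(0.2, 0.2))
  dec2 <- recommend_stop(const, cfg)
  expect_lte(dec2$iteration, const$iterations[1] + (cfg$consistency + 1) * 60000 / 999)

  # relentlessly steep series: no plateau, recommend the full budget
  steep <- metric_series(seq(0, 60000, length.out = 50),
                         seq(10, 0, length.out = 50))
  dec3 <- recommend_stop(steep, cfg)
  expect_false(dec3$result$found)
  expect_equal(dec3$iteration, 60000)
})

test_that("Pearson correlation matches hand computations and guards variance", {
  expect_equal(pearson_correlation(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(pearson_correlation(c(1, 2, 3), c(-1, -2, -3)), -1)
  expect_equal(pearson_correlation(c(1, 2, 3), c(1, 3, 2)), 0.5)
  expect_error(pearson_correlation(c(1, 1, 1), c(1, 2, 3)), "zero-variance")
  expect_error(pearson_correlation(c(1, 2), c(1, 2)), "at least 3")
})

test_that("correlation reports capture the perceptual-geometric relation", {
  withr::with_seed(302, {
    f1 <- runif(8, 20, 90)
    tab <- data.frame(run = paste0("r", 1:8),
                      psnr = rnorm(8, 20, 3),
                      ssim = runif(8, 0.3, 0.9),
                      lpips = 1 - f1 / 100,
                      f1 = f1)
  })
  m <- correlation_report(tab)
  expect_equal(m["lpips", "f1"], -1)     # exact affine relation
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(1, 4))
  expect_equal(m["psnr", "ssim"], pearson_correlation(tab$psnr, tab$ssim))
  tab$ssim <- 0.5
  expect_error(correlation_report(tab), "zero-variance")
})

test_that("series build from rendered checkpoints, sorted, no duplicates", {
  p <- generate_image_pair(c(16, 16), "intensity_shift", amount = 5)
  key_a <- format(sum(p$reference$pixels))
  key_b <- format(sum(p$degraded$pixels))
  bk <- toy_backbone(setNames(list(c(1, 0), c(0, 1)), c(key_a, key_b)),
                     weights = list(c(0.5, 0.5)))
  validation <- list(p$reference)
  ckpts <- list(list(iteration = 2000, images = list(p$reference)),
                list(iteration = 1000, images = list(p$degraded)))
  s <- build_series(ckpts, validation, bk)
  expect_equal(s$iterations, c(1000, 2000))     # unsorted input comes out sorted
  expect_equal(s$values, c(0.5, 0), tolerance = 1e-8)
  expect_error(build_series(list(ckpts[[1]], ckpts[[1]]), validation, bk), "duplicate")
  expect_error(build_series(list(ckpts[[1]]), validation, bk), "at least 2")
})

test_that("series CSV round-trips and malformed rows name their line", {
  s <- generate_training_curve(15000, noise_sigma = 0.002, seed = 4)
  f <- tempfile(fileext = ".csv")
  write_metric_series(s, f)
  back <- read_metric_series(f)
  expect_equal(back$iterations, s$iterations)
  expect_equal(back$values, s$values, tolerance = 1e-12)

  bad <- tempfile(fileext = ".csv")
  writeLines(c("iteration,value", "0,1", "10,oops"), bad)
  expect_error(read_metric_series(bad), "line 3")
  bad2 <- tempfile(fileext = ".csv")
  writeLines(c("iteration,value", "0,1,9"), bad2)
  expect_error(read_metric_series(bad2), "line 2")
  bad3 <- tempfile(fileext = ".csv")
  writeLines(c("a,b", "0,1"), bad3)
  expect_error(read_metric_series(bad3), "header")
})
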