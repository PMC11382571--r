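#' Checkpoint-indexed metric series
#'
#' Stores a metric (typically per-checkpoint average perceptual distance)
#' against training iteration. Iterations must be strictly increasing and
#' non-negative; they need not be integers after interpolation onto a uniform
#' grid.
#'
#' @param iterations strictly increasing non-negative numeric vector.
#' @param values parallel numeric vector.
#' @return object of class `metric_series`.
#' @export
metric_series <- function(iterations, values) {
  iterations <- as.numeric(iterations)
  values <- as.numeric(values)
  if (length(iterations) != length(values))
    abort_input("iterations and values must have equal length")
  if (length(iterations) < 1L) abort_input("series must be non-empty")
  if (anyNA(iterations) || anyNA(values) || !all(is.finite(values)))
    abort_input("series entries must be finite")
  if (any(iterations < 0)) abort_input("iterations must be non-negative")
  if (is.unsorted(iterations, strictly = TRUE))
    abort_input("iterations must be strictly increasing")
  structure(list(iterations = iterations, values = values),
            class = "metric_series")
}

#' @export
print.metric_series <- function(x, ...) {
  cat(sprintf("<metric_series> %d points, iterations [%g, %g], values [%g, %g]\n",
              length(x$iterations), min(x$iterations), max(x$iterations),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Plateau-detection configuration
#'
#' Defaults follow the reference early-stopping setup: change threshold
#' `theta = 0.005`, consistency length `C = 6` consecutive steps,
#' interpolation granularity 1,000 grid points, spanning 60,000 training
#' iterations.
#'
#' @param theta threshold on the absolute successive change, `> 0`.
#' @param consistency number of consecutive sub-threshold steps required.
#' @param granularity number of uniform interpolation points, `>= 2`.
#' @param total_iterations end of the interpolation grid.
#' @return object of class `plateau_config`.
#' @export
plateau_config <- function(theta = 0.005, consistency = 6L,
                           granularity = 1000L, total_iterations = 60000) {
  if (!is.finite(theta) || theta <= 0) abort_input("theta must be > 0")
  consistency <- as.integer(consistency)
  granularity <- as.integer(granularity)
  if (consistency < 1L) abort_input("consistency must be >= 1")
  if (granularity < 2L) abort_input("granularity must be >= 2")
  if (!is.finite(total_iterations) || total_iterations <= 0)
    abort_input("total_iterations must be > 0")
  structure(list(theta = theta, consistency = consistency,
                 granularity = granularity, total_iterations = total_iterations),
            class = "plateau_config")
}

#' Interpolate a checkpoint series onto a uniform grid
#'
#' Checkpoints are typically saved at exponentially spaced iterations;
#' plateau detection needs a uniform grid, so the series is piecewise-linearly
#' interpolated onto `granularity` points from the first checkpoint iteration
#' to `total_iterations`. Beyond the last checkpoint the last value is held
#' constant — extrapolating a slope would fabricate phantom plateaus (or hide
#' real ones).
#'
#' @param series a [metric_series()] with at least 2 points.
#' @param config a [plateau_config()].
#' @return the interpolated `metric_series`.
#' @export
interpolate_series <- function(series, config = plateau_config()) {
  stopifnot(inherits(series, "metric_series"), inherits(config, "plateau_config"))
  if (length(series$iterations) < 2L)
    abort_input("interpolation needs at least 2 checkpoints")
  if (config$total_iterations <= series$iterations[1])
    abort_input("total_iterations must exceed the first checkpoint iteration")
  grid <- seq(series$iterations[1], config$total_iterations,
              length.out = config$granularity)
  vals <- stats::approx(series$iterations, series$values, xout = grid,
                        method = "linear", rule = 2)$y
  metric_series(grid, vals)
}

#' Detect a plateau in a metric series
#'
#' Finds the smallest index `i` (1-based) such that the absolute successive
#' differences `|value[j+1] - value[j]|` stay below `theta` for `C`
#' consecutive steps `j = i, ..., i + C - 1`. The recommended stop iteration
#' is the grid iteration at index `i + C` — the first moment an online
#' monitor, seeing values one by one, can confirm the plateau. The criterion
#' depends only on absolute differences, so shifting or negating the series
#' leaves the result unchanged.
#'
#' @param series a [metric_series()] longer than `consistency`.
#' @param config a [plateau_config()] (`granularity`/`total_iterations` are
#'   not used here; apply [interpolate_series()] first for checkpoint data).
#' @return object of class `plateau_result`: `found`, `plateau_index`
#'   (1-based start of the qualifying window, `NA` when not found),
#'   `recommended_iteration` (`NA` when not found).
#' @export
detect_plateau <- function(series, config = plateau_config()) {
  stopifnot(inherits(series, "metric_series"), inherits(config, "plateau_config"))
  v <- series$values
  cc <- config$consistency
  if (length(v) <= cc)
    abort_input("series length (%d) must exceed consistency (%d)", length(v), cc)
  ok <- abs(diff(v)) < config$theta
  # window of C consecutive TRUEs starting at diff index i
  run <- cumsum(ok)
  wins <- run[seq(cc, length(ok))] - c(0, run[seq_len(length(ok) - cc)])
  hit <- which(wins == cc)
  if (length(hit) == 0L) {
    return(structure(list(found = FALSE, plateau_index = NA_integer_,
                          recommended_iteration = NA_real_),
                     class = "plateau_result"))
  }
  i <- hit[1]
  structure(list(found = TRUE, plateau_index = i,
                 recommended_iteration = series$iterations[i + cc]),
            class = "plateau_result")
}

#' @export
print.plateau_result <- function(x, ...) {
  if (x$found)
    cat(sprintf("<plateau_result> plateau from index %d, stop at iteration %g\n",
                x$plateau_index, x$recommended_iteration))
  else cat("<plateau_result> no plateau found\n")
  invisible(x)
}

#' Recommend a stop iteration for a training run
#'
#' Interpolates the checkpoint series onto the uniform grid, detects the
#' plateau, and returns the training iteration at which stopping is
#' confirmed; when no plateau exists the full `total_iterations` is
#' recommended.
#'
#' @param series a raw checkpoint [metric_series()].
#' @param config a [plateau_config()].
#' @return list with `iteration` (recommended stop), `result`
#'   (the [detect_plateau()] output) and `interpolated` (the grid series).
#' @export
recommend_stop <- function(series, config = plateau_config()) {
  interp <- interpolate_series(series, config)
  res <- detect_plateau(interp, config)
  list(iteration = if (res$found) res$recommended_iteration else config$total_iterations,
       result = res,
       interpolated = interp)
}

#' Build a metric series from rendered checkpoints
#'
#' Computes the mean perceptual distance of each checkpoint's rendered image
#' set against the fixed validation set, yielding one series entry per
#' checkpoint, sorted by iteration.
#'
#' @param checkpoints list of `list(iteration =, images = list of rasters)`;
#'   at least 2, iterations distinct; each image list pairs one-to-one with
#'   `validation`.
#' @param validation list of `raster_image`s.
#' @param backbone a [feature_backbone()].
#' @return a [metric_series()] of mean perceptual distances.
#' @export
build_series <- function(checkpoints, validation, backbone = conv_backbone()) {
  if (!is.list(checkpoints) || length(checkpoints) < 2L)
    abort_input("need at least 2 checkpoints")
  its <- vapply(checkpoints, function(ck) {
    if (is.null(ck$iteration) || is.null(ck$images))
      abort_input("each checkpoint needs 'iteration' and 'images'")
    as.numeric(ck$iteration)
  }, numeric(1))
  if (anyDuplicated(its)) abort_input("duplicate checkpoint iterations")
  vals <- vapply(checkpoints, function(ck) {
    if (length(ck$images) != length(validation))
      abort_input("checkpoint image set does not pair with validation set")
    average_image_metrics(ck$images, validation, backbone)$lpips
  }, numeric(1))
  ord <- order(its)
  metric_series(its[ord], vals[ord])
}

#' Pearson correlation coefficient
#'
#' Sample (ddof = 1) Pearson correlation; errors on zero-variance input
#' rather than returning NaN.
#'
#' @param a,b numeric vectors of equal length `>= 3`.
#' @return correlation in \[-1, 1\].
#' @export
pearson_correlation <- function(a, b) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) != length(b)) abort_input("inputs must have equal length")
  if (length(a) < 3L) abort_input("need at least 3 observations")
  if (anyNA(a) || anyNA(b)) abort_input("inputs must not contain NA")
  if (stats::var(a) == 0 || stats::var(b) == 0)
    abort_input("correlation undefined for zero-variance input")
  stats::cor(a, b)
}

#' Pairwise correlation matrix of run metrics
#'
#' Symmetric matrix of pairwise Pearson coefficients across the numeric
#' columns of a per-run metric table (e.g. psnr, ssim, lpips, f1) — the
#' analysis that justifies using the perceptual distance as a surrogate for
#' the geometric F-score during training.
#'
#' @param metric_table data frame with `>= 3` rows; all numeric columns are
#'   correlated pairwise.
#' @return symmetric numeric matrix with unit diagonal.
#' @export
correlation_report <- function(metric_table) {
  metric_table <- as.data.frame(metric_table)
  num <- vapply(metric_table, is.numeric, logical(1))
  tab <- metric_table[num]
  if (ncol(tab) < 2L) abort_input("need at least 2 numeric columns")
  if (nrow(tab) < 3L) abort_input("need at least 3 rows")
  k <- ncol(tab)
  m <- diag(1, k)
  dimnames(m) <- list(names(tab), names(tab))
  for (i in seq_len(k - 1L))
    for (j in seq(i + 1L, k)) {
      r <- pearson_correlation(tab[[i]], tab[[j]])
      m[i, j] <- r
      m[j, i] <- r
    }
  m
}

#' Read / write a metric series as CSV
#'
#' Columns `iteration,value`. The reader validates numeric content and names
#' the offending line on failure.
#' @param path CSV path.
#' @return a [metric_series()] for the reader; the path, invisibly, for the
#'   writer.
#' @export
read_metric_series <- function(path) {
  if (!file.exists(path)) abort_input("series file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) abort_input("%s: expected a header and data rows", path)
  header <- tolower(gsub("[\"[:space:]]", "", lines[1]))
  if (header != "iteration,value")
    abort_input("%s: header must be 'iteration,value'", path)
  sp <- strsplit(lines[-1], ",", fixed = TRUE)
  lens <- lengths(sp)
  bad <- which(lens != 2L)
  if (length(bad) > 0L)
    abort_input("%s: line %d has %d fields, expected 2", path, bad[1] + 1L, lens[bad[1]])
  vals <- suppressWarnings(as.numeric(unlist(sp)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1]
    abort_input("%s: non-numeric value on line %d", path, ceiling(bad / 2) + 1L)
  }
  m <- matrix(vals, ncol = 2L, byrow = TRUE)
  ord <- order(m[, 1])
  metric_series(m[ord, 1], m[ord, 2])
}

#' @rdname read_metric_series
#' @param series a `metric_series` to serialize.
#' @export
write_metric_series <- function(series, path) {
  stopifnot(inherits(series, "metric_series"))
  utils::write.csv(data.frame(iteration = series$iterations,
                              value = series$values),
                   path, row.names = FALSE)
  invisible(path)
}
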