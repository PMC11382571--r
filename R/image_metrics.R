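#' Construct a raster image
#'
#' A grayscale matrix or an m x n x 3 color array of intensities in
#' `[0, max_value]`, with the bit-depth ceiling (`MAX_I`) carried alongside
#' for PSNR.
#'
#' @param pixels numeric matrix (m x n) or array (m x n x 3).
#' @param max_value maximum representable intensity (255 for 8-bit,
#'   65535 for 16-bit).
#' @return object of class `raster_image`.
#' @export
as_raster <- function(pixels, max_value = 255) {
  if (is.matrix(pixels)) {
    dims_ok <- all(dim(pixels) >= 1L)
  } else if (is.array(pixels) && length(dim(pixels)) == 3L && dim(pixels)[3] == 3L) {
    dims_ok <- all(dim(pixels)[1:2] >= 1L)
  } else {
    abort_input("pixels must be an m x n matrix or m x n x 3 array")
  }
  if (!dims_ok) abort_input("raster dimensions must be >= 1")
  if (!is.finite(max_value) || max_value <= 0) abort_input("max_value must be > 0")
  storage.mode(pixels) <- "double"
  if (anyNA(pixels) || any(pixels < 0) || any(pixels > max_value))
    abort_input("intensities must lie in [0, max_value]")
  structure(list(pixels = pixels, max_value = max_value), class = "raster_image")
}

#' Read a raster from a PNG file
#'
#' Values are rescaled from the PNG's normalized 0..1 range to
#' `[0, max_value]`. Gray+alpha / RGBA inputs drop the alpha channel.
#'
#' @param path PNG file path.
#' @param max_value intensity ceiling of the stored image (255 for 8-bit PNG,
#'   65535 for 16-bit).
#' @return a [as_raster()] object.
#' @export
read_raster <- function(path, max_value = 255) {
  if (!file.exists(path)) abort_input("image not found: %s", path)
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) {
    if (dim(px)[3] == 2L) px <- px[, , 1]                # gray + alpha
    else if (dim(px)[3] == 4L) px <- px[, , 1:3]          # drop alpha
    else if (dim(px)[3] != 3L) abort_input("%s: unsupported channel count", path)
  }
  as_raster(px * max_value, max_value = max_value)
}

#' Write a raster to a PNG file
#' @param raster a `raster_image`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_raster <- function(raster, path) {
  stopifnot(inherits(raster, "raster_image"))
  png::writePNG(raster$pixels / raster$max_value, path)
  invisible(path)
}

raster_pixels <- function(x) {
  if (inherits(x, "raster_image")) x$pixels else x
}

check_same_shape <- function(x, y) {
  px <- raster_pixels(x)
  py <- raster_pixels(y)
  if (!identical(dim(px), dim(py)))
    abort_input("images must have identical dimensions")
  list(x = px, y = py)
}

#' Mean squared error between two images
#'
#' Mean over all pixels (and channels, for color) of the squared intensity
#' difference.
#' @param reference,test `raster_image`s (or bare arrays) of equal dimensions.
#' @return non-negative scalar.
#' @export
mse <- function(reference, test) {
  p <- check_same_shape(reference, test)
  mean((p$x - p$y)^2)
}

#' Peak signal-to-noise ratio
#'
#' `PSNR = 10 log10(MAX_I^2 / MSE)` in decibels. Identical images (MSE = 0)
#' return `Inf` as a documented sentinel rather than an error; serializers
#' write it as null with a flag.
#'
#' @inheritParams mse
#' @param max_value intensity ceiling MAX_I; defaults to the reference's.
#' @return decibels (possibly `Inf`).
#' @export
psnr <- function(reference, test, max_value = NULL) {
  if (is.null(max_value))
    max_value <- if (inherits(reference, "raster_image")) reference$max_value else 255
  m <- mse(reference, test)
  if (m == 0) return(Inf)
  10 * log10(max_value^2 / m)
}

#' Structural similarity index
#'
#' `SSIM(x,y) = (2 mu_x mu_y + C1)(2 sigma_xy + C2) /
#'  ((mu_x^2 + mu_y^2 + C1)(sigma_x^2 + sigma_y^2 + C2))` with
#' `C1 = (k1 MAX_I)^2`, `C2 = (k2 MAX_I)^2`. `mode = "global"` (default)
#' applies the formula once over the whole image, which is how the index is
#' written; `mode = "windowed"` averages it over sliding 11 x 11 uniform
#' windows. Color images are converted to grayscale by channel mean.
#' Variances and covariance use the population (ddof = 0) form.
#'
#' @inheritParams mse
#' @param k1,k2 stabilizer constants (community defaults 0.01 and 0.03).
#' @param mode `"global"` or `"windowed"`.
#' @param max_value intensity ceiling; defaults to the reference's.
#' @return scalar in \[-1, 1\].
#' @export
ssim <- function(reference, test, k1 = 0.01, k2 = 0.03,
                 mode = c("global", "windowed"), max_value = NULL) {
  mode <- match.arg(mode)
  if (!is.finite(k1) || !is.finite(k2) || k1 <= 0 || k2 <= 0)
    abort_input("k1 and k2 must be > 0")
  if (is.null(max_value))
    max_value <- if (inherits(reference, "raster_image")) reference$max_value else 255
  p <- check_same_shape(reference, test)
  x <- to_gray(p$x)
  y <- to_gray(p$y)
  c1 <- (k1 * max_value)^2
  c2 <- (k2 * max_value)^2
  if (mode == "global") {
    return(ssim_formula(mean(x), mean(y),
                        mean(x^2) - mean(x)^2, mean(y^2) - mean(y)^2,
                        mean(x * y) - mean(x) * mean(y), c1, c2))
  }
  w <- 11L
  if (nrow(x) < w || ncol(x) < w)
    abort_input("windowed SSIM needs images of at least 11 x 11 pixels")
  mu_x <- window_mean(x, w)
  mu_y <- window_mean(y, w)
  sxx <- window_mean(x * x, w) - mu_x^2
  syy <- window_mean(y * y, w) - mu_y^2
  sxy <- window_mean(x * y, w) - mu_x * mu_y
  mean(ssim_formula(mu_x, mu_y, sxx, syy, sxy, c1, c2))
}

ssim_formula <- function(mu_x, mu_y, var_x, var_y, cov_xy, c1, c2) {
  ((2 * mu_x * mu_y + c1) * (2 * cov_xy + c2)) /
    ((mu_x^2 + mu_y^2 + c1) * (var_x + var_y + c2))
}

to_gray <- function(px) {
  if (length(dim(px)) == 3L) (px[, , 1] + px[, , 2] + px[, , 3]) / 3 else px
}

# Mean over all w x w windows (valid positions) via integral images.
window_mean <- function(m, w) {
  cs <- apply(apply(m, 2, cumsum), 1, cumsum)       # transposed integral image
  cs <- t(cs)
  pad <- matrix(0, nrow(m) + 1L, ncol(m) + 1L)
  pad[-1, -1] <- cs
  nr <- nrow(m) - w + 1L
  nc <- ncol(m) - w + 1L
  i <- seq_len(nr)
  j <- seq_len(nc)
  (pad[i + w, j + w, drop = FALSE] - pad[i, j + w, drop = FALSE] -
     pad[i + w, j, drop = FALSE] + pad[i, j, drop = FALSE]) / (w * w)
}

#' Define a feature backbone for the perceptual metric
#'
#' The perceptual distance consumes per-layer feature stacks
#' `H_l x W_l x C_l`; a backbone is any deterministic mapping from a raster
#' to such a list, together with per-layer channel weights `w_l`.
#'
#' @param extract function taking a `raster_image` and returning a list of
#'   3-d arrays (`H_l x W_l x C_l`), one per layer.
#' @param channel_weights optional list of non-negative numeric vectors, one
#'   per layer, of length `C_l`; `NULL` means the default `1/C_l` per channel
#'   (the cosine-distance setting).
#' @return object of class `feature_backbone`.
#' @export
feature_backbone <- function(extract, channel_weights = NULL) {
  if (!is.function(extract)) abort_input("extract must be a function")
  if (!is.null(channel_weights)) {
    if (!is.list(channel_weights) ||
        !all(vapply(channel_weights, function(w) is.numeric(w) && all(w >= 0), logical(1))))
      abort_input("channel_weights must be a list of non-negative numeric vectors")
  }
  structure(list(extract = extract, channel_weights = channel_weights),
            class = "feature_backbone")
}

#' Deterministic multi-scale convolution backbone
#'
#' A fixed-seed convolution bank standing in for a trained perceptual
#' network: layer `l` downsamples the grayscale image by block-averaging at
#' factor `2^(l-1)` and convolves it (valid mode) with `channels` fixed 3 x 3
#' kernels drawn once from the seed, followed by a tanh nonlinearity. The
#' kernels are frozen inside the returned object, so extraction is fully
#' deterministic — no downloads, no trained weights.
#'
#' @param layers number of scales L.
#' @param channels feature channels per layer C_l.
#' @param seed integer seed fixing the kernel bank.
#' @return a [feature_backbone()].
#' @export
conv_backbone <- function(layers = 3L, channels = 8L, seed = 1234L) {
  layers <- as.integer(layers)
  channels <- as.integer(channels)
  if (layers < 1L || channels < 1L) abort_input("layers and channels must be >= 1")
  kernels <- withr::with_seed(seed, {
    lapply(seq_len(layers), function(l)
      lapply(seq_len(channels), function(c)
        matrix(stats::rnorm(9), 3, 3)))
  })
  extract <- function(raster) {
    stopifnot(inherits(raster, "raster_image"))
    g <- to_gray(raster$pixels) / raster$max_value
    lapply(seq_len(layers), function(l) {
      img <- block_mean(g, 2L^(l - 1L))
      if (nrow(img) < 3L || ncol(img) < 3L)
        abort_input("image too small for backbone layer %d", l)
      feats <- lapply(kernels[[l]], function(k) tanh(conv2_valid(img, k)))
      array(unlist(feats), dim = c(dim(feats[[1]]), channels))
    })
  }
  feature_backbone(extract)
}

conv2_valid <- function(img, kern) {
  kr <- nrow(kern)
  kc <- ncol(kern)
  nr <- nrow(img) - kr + 1L
  nc <- ncol(img) - kc + 1L
  out <- matrix(0, nr, nc)
  for (i in seq_len(kr))
    for (j in seq_len(kc))
      out <- out + kern[i, j] * img[i:(i + nr - 1L), j:(j + nc - 1L)]
  out
}

block_mean <- function(img, f) {
  if (f == 1L) return(img)
  nr <- (nrow(img) %/% f) * f
  nc <- (ncol(img) %/% f) * f
  if (nr < f || nc < f) abort_input("image too small to downsample by %d", f)
  img <- img[seq_len(nr), seq_len(nc), drop = FALSE]
  # average f x f blocks
  m <- rowsum(img, rep(seq_len(nr %/% f), each = f)) / f
  t(rowsum(t(m), rep(seq_len(nc %/% f), each = f)) / f)
}

#' Perceptual feature distance between two images
#'
#' Layer features are unit-normalized along the channel dimension at every
#' spatial location (with an epsilon of 1e-10 guarding zero-norm vectors),
#' differenced, weighted channel-wise by `w_l`, squared-l2-summed over
#' channels, averaged over the layer's spatial grid, and summed over layers:
#' `d(x, x0) = sum_l 1/(H_l W_l) sum_{h,w} || w_l * (yhat^l_hw - yhat0^l_hw) ||_2^2`.
#' With the default `w_l = 1/C_l` the per-location summand measures a cosine
#' distance: the feature magnitude is normalized away and only directional
#' disagreement contributes. Zero for identical inputs, symmetric, and
#' invariant to any positive rescaling of the raw features of both inputs.
#'
#' @param x,x0 `raster_image`s of equal dimensions.
#' @param backbone a [feature_backbone()]; defaults to [conv_backbone()].
#' @return non-negative scalar.
#' @export
lpips <- function(x, x0, backbone = conv_backbone()) {
  stopifnot(inherits(backbone, "feature_backbone"))
  check_same_shape(x, x0)
  fx <- backbone$extract(x)
  f0 <- backbone$extract(x0)
  if (length(fx) != length(f0))
    abort_stage("backbone returned differing layer counts")
  total <- 0
  for (l in seq_along(fx)) {
    a <- unit_normalize_channels(fx[[l]])
    b <- unit_normalize_channels(f0[[l]])
    if (!identical(dim(a), dim(b)))
      abort_stage("backbone layer %d shapes differ between inputs", l)
    cl <- dim(a)[3]
    w <- if (is.null(backbone$channel_weights)) rep(1 / cl, cl)
         else backbone$channel_weights[[l]]
    if (length(w) != cl)
      abort_input("channel_weights for layer %d must have length %d", l, cl)
    diff <- a - b
    sq <- sweep(diff, 3, w, `*`)^2
    total <- total + mean(apply(sq, c(1, 2), sum))
  }
  total
}

unit_normalize_channels <- function(feat) {
  norms <- sqrt(apply(feat^2, c(1, 2), sum))
  sweep(feat, c(1, 2), norms + 1e-10, `/`)
}

#' Average image metrics over paired lists
#'
#' Arithmetic mean of PSNR, SSIM and the perceptual distance over
#' corresponding pairs — the per-checkpoint statistic the early-stopping
#' monitor consumes. Infinite PSNR values (identical pairs) are excluded from
#' the PSNR mean; their count is reported.
#'
#' @param rendered,validation equal-length lists of `raster_image`s.
#' @param backbone a [feature_backbone()] for the perceptual term.
#' @return list with `psnr`, `ssim`, `lpips` means, `n_pairs`, and
#'   `n_psnr_infinite` (pairs dropped from the PSNR mean; the PSNR mean is
#'   `NA` when every pair was identical).
#' @export
average_image_metrics <- function(rendered, validation, backbone = conv_backbone()) {
  if (!is.list(rendered) || !is.list(validation))
    abort_input("rendered and validation must be lists of rasters")
  if (length(rendered) != length(validation))
    abort_input("rendered and validation lists must have equal length")
  if (length(rendered) < 1L) abort_input("need at least one image pair")
  ps <- mapply(function(a, b) psnr(b, a), rendered, validation)
  ss <- mapply(function(a, b) ssim(b, a), rendered, validation)
  lp <- mapply(function(a, b) lpips(a, b, backbone), rendered, validation)
  inf_n <- sum(is.infinite(ps))
  list(psnr = if (inf_n == length(ps)) NA_real_ else mean(ps[is.finite(ps)]),
       ssim = mean(ss),
       lpips = mean(lp),
       n_pairs = length(ps),
       n_psnr_infinite = inf_n)
}
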