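# Preprocessing stage: ROI crop, bilinear resize, Gaussian smoothing with
# optional blending against the original, and per-image min-max normalisation
# to [-1, 1]. The smoothing kernel B_R(x,y) = sum_{u,v} R(u,v) K(x-u, y-v)
# is realised with a truncated, renormalised Gaussian (radius ceil(3*sigma))
# and zero padding at the borders.

#' Crop the retinal region of interest
#'
#' Returns the tight bounding box of pixels strictly brighter than
#' `threshold * max(image)`; camera borders in fundus photographs are black,
#' so this discards them. If no pixel qualifies the input is returned
#' unchanged.
#'
#' @param image A [gray_image].
#' @param threshold Relative threshold in (0, 1); default 0.05.
#' @return A cropped [gray_image].
#' @export
crop_roi <- function(image, threshold = 0.05) {
  stopifnot(is_gray_image(image))
  px <- image$pixels
  mask <- px > threshold * max(px)
  if (!any(mask)) return(image)
  rows <- range(which(apply(mask, 1, any)))
  cols <- range(which(apply(mask, 2, any)))
  gray_image(px[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE],
             image$dynamic_range)
}

# Separable bilinear interpolation of a matrix to (ht, wt), pixel-centre
# aligned: source coordinate of output index i is (i + 0.5) * H/Ht - 0.5,
# clamped to the raster. Resizing to the own size is the identity.
.resize_bilinear_mat <- function(px, ht, wt) {
  H <- nrow(px); W <- ncol(px)
  rs <- pmin(pmax((seq_len(ht) - 0.5) * H / ht - 0.5, 0), H - 1)
  cs <- pmin(pmax((seq_len(wt) - 0.5) * W / wt - 0.5, 0), W - 1)
  r0 <- pmin(floor(rs), H - 1); fr <- rs - r0; r1 <- pmin(r0 + 1, H - 1)
  c0 <- pmin(floor(cs), W - 1); fc <- cs - c0; c1 <- pmin(c0 + 1, W - 1)
  rows <- px[r0 + 1, , drop = FALSE] * (1 - fr) + px[r1 + 1, , drop = FALSE] * fr
  rows[, c0 + 1, drop = FALSE] * rep(1 - fc, each = ht) +
    rows[, c1 + 1, drop = FALSE] * rep(fc, each = ht)
}

#' Resize an image
#'
#' Bilinear resampling by default (the preprocessing stage's method); bicubic
#' (Catmull-Rom) is available for the super-resolution baselines.
#'
#' @param image A [gray_image].
#' @param target Integer vector `(height, width)`.
#' @param method `"bilinear"` (default) or `"bicubic"`.
#' @return A [gray_image] of the target size; the dynamic range is preserved.
#' @export
resize_image <- function(image, target, method = c("bilinear", "bicubic")) {
  stopifnot(is_gray_image(image))
  method <- match.arg(method)
  target <- as.integer(target)
  if (length(target) != 2L || any(target < 1L))
    stop("resize_image: target must be positive (height, width)")
  px <- if (method == "bilinear")
    .resize_bilinear_mat(image$pixels, target[1], target[2])
  else .resize_bicubic_mat(image$pixels, target[1], target[2])
  gray_image(px, image$dynamic_range)
}

#' Truncated Gaussian smoothing kernel
#'
#' Weights are proportional to `exp(-(u^2 + v^2) / (2 sigma^2))` on the grid
#' `u, v = -r..r` with `r = ceiling(3 sigma)`, then renormalised so the kernel
#' sums to exactly one (brightness preserving).
#'
#' @param sigma Positive standard deviation, in pixels.
#' @return A `gaussian_kernel`: list with `weights` ((2r+1) x (2r+1) matrix),
#'   `sigma`, `radius`.
#' @export
gaussian_kernel <- function(sigma) {
  if (!is.finite(sigma) || sigma <= 0) stop("gaussian_kernel: sigma must be > 0")
  r <- ceiling(3 * sigma)
  u <- -r:r
  w <- exp(-outer(u^2, u^2, "+") / (2 * sigma^2))
  structure(list(weights = w / sum(w), sigma = sigma, radius = r),
            class = "gaussian_kernel")
}

#' Gaussian blur by 2-D convolution
#'
#' Zero padding at the borders; output dimensions equal input dimensions.
#' Interior pixels (further than the kernel radius from any border) of a
#' constant image are unchanged because the kernel sums to one.
#'
#' @param image A [gray_image].
#' @param kernel A [gaussian_kernel] (or any odd-sided weight matrix wrapped
#'   in one).
#' @return The blurred [gray_image].
#' @export
gaussian_blur <- function(image, kernel) {
  stopifnot(is_gray_image(image), inherits(kernel, "gaussian_kernel"))
  px <- image$pixels
  w <- kernel$weights
  r <- kernel$radius
  x <- array(px, c(1L, nrow(px), ncol(px), 1L))
  cols <- .im2col(x, nrow(w), ncol(w), 1L, 1L, r, r)
  # the Gaussian is symmetric under (u,v) -> (-u,-v), so correlation with the
  # kernel equals the convolution of the smoothing equation
  out <- matrix(as.numeric(crossprod(cols, as.numeric(w))), nrow(px), ncol(px))
  gray_image(out, image$dynamic_range)
}

#' Blend a smoothed image with its original
#'
#' Pixelwise `alpha * R + beta * B_R + gamma`. `(1, 0, 0)` returns the
#' original, `(0, 1, 0)` the blurred image; a Graham-style sharpening preset
#' is `(4, -4, mid)`.
#'
#' @param original,blurred [gray_image]s of identical size.
#' @param params List or numeric vector with `alpha`, `beta`, `gamma`.
#' @return The blended [gray_image].
#' @export
blend_images <- function(original, blurred, params) {
  stopifnot(is_gray_image(original), is_gray_image(blurred))
  if (original$height != blurred$height || original$width != blurred$width)
    stop("blend_images: image dimensions differ")
  p <- unlist(params)[1:3]
  if (!all(is.finite(p))) stop("blend_images: blending coefficients must be finite")
  px <- p[1] * original$pixels + p[2] * blurred$pixels + p[3]
  rng <- range(c(original$dynamic_range, px))
  gray_image(px, c(min(rng[1], original$dynamic_range[1]),
                   max(rng[2], original$dynamic_range[2])))
}

#' Min-max normalisation to [-1, 1]
#'
#' Affine map `(R - min(R)) / (max(R) - min(R)) * 2 - 1`; the per-image
#' minimum maps to -1 and the maximum to +1.
#'
#' @param image A [gray_image] with `max > min` (a constant image is a
#'   degenerate input and raises an error).
#' @return A [gray_image] with `dynamic_range = c(-1, 1)`.
#' @export
normalize_minmax <- function(image) {
  stopifnot(is_gray_image(image))
  px <- image$pixels
  lo <- min(px); hi <- max(px)
  if (hi <= lo) stop("normalize_minmax: constant image (max == min) is degenerate")
  gray_image((px - lo) / (hi - lo) * 2 - 1, c(-1, 1))
}

#' Default preprocessing configuration
#'
#' @param target Output size, default `c(224, 224)`.
#' @param sigma Gaussian sigma in pixels; `NULL` (default) means
#'   `target_width / 30`.
#' @param blend Blending coefficients `(alpha, beta, gamma)`; the default
#'   `(0, 1, 0)` is pure smoothing.
#' @param crop_threshold Relative ROI threshold, default 0.05.
#' @param blur Logical; disable to bypass the smoothing/blending stage.
#' @export
preprocess_config <- function(target = c(224, 224), sigma = NULL,
                              blend = c(alpha = 0, beta = 1, gamma = 0),
                              crop_threshold = 0.05, blur = TRUE) {
  list(target = as.integer(target), sigma = sigma, blend = blend,
       crop_threshold = crop_threshold, blur = blur)
}

#' Full preprocessing pipeline
#'
#' Composition crop -> resize -> blur + blend -> normalise. Output is always
#' `target`-sized with pixels in `[-1, 1]`.
#'
#' @param image A [gray_image] (grayscale conversion happens at read time).
#' @param config A [preprocess_config] list.
#' @return The preprocessed [gray_image].
#' @export
preprocess_pipeline <- function(image, config = preprocess_config()) {
  out <- crop_roi(image, config$crop_threshold)
  out <- resize_image(out, config$target)
  if (isTRUE(config$blur)) {
    sigma <- if (is.null(config$sigma)) config$target[2] / 30 else config$sigma
    blurred <- gaussian_blur(out, gaussian_kernel(sigma))
    out <- blend_images(out, blurred, config$blend)
  }
  normalize_minmax(out)
}
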