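# Super-resolution networks. The hybrid local-global model stacks HLG blocks
# (deformable-convolution local path, inter-pixel non-local attention, and a
# 2x2-patch transformer) on top of a point-wise/3x3/point-wise preliminary
# feature extractor, aggregates all block outputs with 1x1 compress-concat-
# fuse feature reuse, and reconstructs through a 1x1 reduction + pixel
# shuffle added to a bicubic upsample of the input. The reconstruction 1x1
# convolution is zero-initialised, so an untrained network is exactly bicubic
# interpolation. The SRCNN baseline follows its printed three-stage layout:
# two 3x3/64 convolutions, a 4x4 stride-2 transposed convolution, and a
# final 3x3 convolution back to one channel. Both minimise the mean squared
# error between predicted and target high-resolution images.

# Catmull-Rom (Keys, a = -0.5) bicubic resampling, pixel-centre aligned,
# edge-replicated; separable.
.cubic_w <- function(t, a = -0.5) {
  at <- abs(t)
  ifelse(at <= 1, (a + 2) * at^3 - (a + 3) * at^2 + 1,
         ifelse(at < 2, a * at^3 - 5 * a * at^2 + 8 * a * at - 4 * a, 0))
}

.resize_bicubic_mat <- function(px, ht, wt) {
  H <- nrow(px); W <- ncol(px)
  interp_axis <- function(m, src_n, dst_n, along_rows) {
    s <- (seq_len(dst_n) - 0.5) * src_n / dst_n - 0.5
    i0 <- floor(s)
    out <- 0
    for (k in -1:2) {
      idx <- pmin(pmax(i0 + k, 0), src_n - 1) + 1
      w <- .cubic_w(s - (i0 + k))
      out <- out + if (along_rows) m[idx, , drop = FALSE] * w
      else m[, idx, drop = FALSE] * rep(w, each = nrow(m))
    }
    out
  }
  interp_axis(interp_axis(px, H, ht, TRUE), W, wt, FALSE)
}

bicubic_resize <- function(px, ht, wt) .resize_bicubic_mat(px, ht, wt)

# map a gray_image into the [-1, 1] working range using its declared
# dynamic range (not the per-image extrema, so LR/HR pairs stay consistent)
img_to_unit <- function(image) {
  r <- image$dynamic_range
  (image$pixels - r[1]) / (r[2] - r[1]) * 2 - 1
}

unit_to_img <- function(px, dynamic_range = c(0, 255)) {
  r <- dynamic_range
  gray_image(pmin(pmax((px + 1) / 2, 0), 1) * (r[2] - r[1]) + r[1], r)
}

# --- parameter initialisation -------------------------------------------------

#' Configuration for the hybrid local-global SR network
#'
#' @param channels Base channel width C (default 32).
#' @param n_blocks Number of stacked HLG blocks (default 4).
#' @param scale Upsampling factor (default 2).
#' @param patch_side Patch size of the patch-transformer path (default 2).
#' @param deform_refine Apply a deformable refinement after the transformer
#'   path (default TRUE).
#' @param embed Non-local embedding channels (default `channels / 2`).
#' @export
hlg_config <- function(channels = 32L, n_blocks = 4L, scale = 2L,
                       patch_side = 2L, deform_refine = TRUE,
                       embed = max(1L, channels %/% 2L)) {
  list(channels = as.integer(channels), n_blocks = as.integer(n_blocks),
       scale = as.integer(scale), patch_side = as.integer(patch_side),
       deform_refine = isTRUE(deform_refine), embed = as.integer(embed))
}

#' Initialise hybrid local-global SR parameters
#' @param config A [hlg_config] list.
#' @return A parameter tree (class `hlg_params`). Draws from the current RNG
#'   stream; seed via the caller (e.g. [train_sr]).
#' @export
hlg_init <- function(config = hlg_config()) {
  C <- config$channels; C2 <- 2L * C
  d_tok <- C * config$patch_side^2
  block_init <- function() {
    b <- list(
      dconv = dconv_params_init(C, C),
      alm_pw = list(W = he_conv(C, 1L, C), b = rep(0, C)),
      nl = nonlocal_params_init(C, config$embed),
      tf = transformer_params_init(d_tok),
      fuse = list(W = he_conv(4L * C, 1L, C), b = rep(0, C)))
    if (config$deform_refine) b$refine <- dconv_params_init(C, C)
    b
  }
  structure(list(
    config = config,
    prelim = list(pw1 = list(W = he_conv(1L, 1L, C2), b = rep(0, C2)),
                  conv3 = list(W = he_conv(C2, 3L, C2), b = rep(0, C2)),
                  pw2 = list(W = he_conv(C2, 1L, C), b = rep(0, C))),
    blocks = replicate(config$n_blocks, block_init(), simplify = FALSE),
    reuse = list(
      comp = replicate(config$n_blocks,
                       list(W = he_conv(C, 1L, C %/% 2L), b = rep(0, C %/% 2L)),
                       simplify = FALSE),
      fuse = list(W = he_conv(config$n_blocks * (C %/% 2L), 1L, C),
                  b = rep(0, C))),
    recon = list(W = matrix(0, C, config$scale^2), b = rep(0, config$scale^2))),
    class = "hlg_params")
}

# --- public operation surface --------------------------------------------------

#' Preliminary feature modelling
#'
#' Point-wise channel expansion (1 -> 2C), a 3x3 convolution in the expanded
#' space, and a point-wise merge back to C channels; ReLU after the first two
#' stages. Spatial dimensions are preserved.
#'
#' @param image A [gray_image] (normalised) or a `(1, H, W)` array.
#' @param params An `hlg_params` tree (its `prelim` branch is used).
#' @return `(C, H, W)` feature array.
#' @export
preliminary_features <- function(image, params) {
  x <- if (is_gray_image(image)) {
    array(image$pixels, c(1L, image$height, image$width))
  } else image
  x <- as_fm4(x)
  p <- params$prelim
  a1 <- relu_fwd(conv2d_fwd(x, p$pw1$W, p$pw1$b, 1L))
  a2 <- relu_fwd(conv2d_fwd(a1, p$conv3$W, p$conv3$b, 3L))
  fm_drop(conv2d_fwd(a2, p$pw2$W, p$pw2$b, 1L))
}

# single-image/batch block forward used by both the public op and training
hlg_block_fwd <- function(x, bp, config, training = FALSE) {
  x <- as_fm4(x)
  d <- dim(x)
  C <- d[1]
  dc <- dconv_fwd(x, bp$dconv, training)
  da <- relu_fwd(dc$out)
  alm <- conv2d_fwd(da, bp$alm_pw$W, bp$alm_pw$b, 1L)
  nl <- nl_fwd(x, bp$nl, residual = TRUE, training = training)
  psgm0 <- x * 0
  tf_caches <- vector("list", d[4])
  for (n in seq_len(d[4])) {
    sq <- patchify(array(x[, , , n], d[1:3]), config$patch_side)
    tr <- tf_fwd(t(sq$tokens), bp$tf, training = training)
    sq$tokens <- t(tr$out)
    psgm0[, , , n] <- unpatchify(sq)
    tf_caches[[n]] <- tr$caches
  }
  if (config$deform_refine) {
    rf <- dconv_fwd(psgm0, bp$refine, training)
    psgm <- rf$out
  } else {
    rf <- NULL
    psgm <- psgm0
  }
  cat4 <- array(0, c(4L * C, d[2], d[3], d[4]))
  cat4[1:C, , , ] <- alm
  cat4[(C + 1L):(2L * C), , , ] <- nl$out
  cat4[(2L * C + 1L):(3L * C), , , ] <- psgm
  cat4[(3L * C + 1L):(4L * C), , , ] <- x
  fused <- conv2d_fwd(cat4, bp$fuse$W, bp$fuse$b, 1L)
  cache <- if (training) list(x = x, dc = dc, da_in = dc$out, da = da, alm_in = da,
                              nl = nl, psgm0 = psgm0, tf_caches = tf_caches,
                              rf = rf, cat4 = cat4) else NULL
  list(alm = alm, ipgm = nl$out, psgm = psgm, fused = fused, cache = cache)
}

hlg_block_bwd <- function(dfused, dres_extra, bp, config, cache) {
  # dres_extra: gradient arriving directly at the block output via the
  # residual skip (out = fused + x), already included by the caller in dfused
  # handling; here dfused is the gradient at `fused` only.
  d <- dim(cache$x)
  C <- d[1]
  g <- zero_like(bp)
  cb <- conv2d_bwd(dfused, cache$cat4, bp$fuse$W, 1L)
  g$fuse$W <- cb$dW; g$fuse$b <- cb$db
  dcat <- cb$dx
  dalm <- dcat[1:C, , , , drop = FALSE]
  dnl <- dcat[(C + 1L):(2L * C), , , , drop = FALSE]
  dpsgm <- dcat[(2L * C + 1L):(3L * C), , , , drop = FALSE]
  dx <- array(dcat[(3L * C + 1L):(4L * C), , , , drop = FALSE], d)
  # ALM path
  ab <- conv2d_bwd(dalm, cache$da, bp$alm_pw$W, 1L)
  g$alm_pw$W <- ab$dW; g$alm_pw$b <- ab$db
  dda <- relu_bwd(ab$dx, cache$da_in)
  db1 <- dconv_bwd(dda, cache$x, bp$dconv, cache$dc$cache)
  g$dconv <- db1$grads
  dx <- dx + db1$dx
  # IPGM path
  nb <- nl_bwd(dnl, cache$x, bp$nl, cache$nl$caches, residual = TRUE)
  g$nl <- nb$grads
  dx <- dx + nb$dx
  # PSGM path
  if (config$deform_refine) {
    rb <- dconv_bwd(array(dpsgm, d), cache$psgm0, bp$refine, cache$rf$cache)
    g$refine <- rb$grads
    dpsgm0 <- rb$dx
  } else {
    dpsgm0 <- array(dpsgm, d)
  }
  tf_g <- NULL
  for (n in seq_len(d[4])) {
    sq <- patchify(array(dpsgm0[, , , n], d[1:3]), config$patch_side)
    tb <- tf_bwd(t(sq$tokens), bp$tf, cache$tf_caches[[n]])
    tf_g <- if (is.null(tf_g)) tb$grads else tree_add(tf_g, tb$grads)
    sq$tokens <- t(tb$dx)
    dx[, , , n] <- dx[, , , n] + unpatchify(sq)
  }
  g$tf$layers <- tf_g$layers
  list(dx = dx, grads = g)
}

#' One hybrid local-global block
#'
#' Runs the adaptive local path (deformable convolution + point-wise fuse),
#' the inter-pixel global path (non-local attention with residual), and the
#' patch-scope global path (2x2 patch transformer with optional deformable
#' refinement), then concatenates the three outputs with the input and fuses
#' them with a point-wise convolution back to the base channel count.
#'
#' @param features `(C, H, W)` array, `H`/`W` divisible by the patch side.
#' @param params One element of `hlg_params$blocks`.
#' @param config An [hlg_config]; defaults to a config matching `features`.
#' @return List of class `hlg_block_output` with `alm`, `ipgm`, `psgm`,
#'   `fused` feature maps (all `(C, H, W)`).
#' @export
hlg_block <- function(features, params, config = NULL) {
  x <- as_fm4(features)
  if (is.null(config))
    config <- hlg_config(channels = dim(x)[1],
                         deform_refine = !is.null(params$refine))
  r <- hlg_block_fwd(x, params, config, training = FALSE)
  structure(list(alm = fm_drop(r$alm), ipgm = fm_drop(r$ipgm),
                 psgm = fm_drop(r$psgm), fused = fm_drop(r$fused)),
            class = "hlg_block_output")
}

#' Feature reuse: compress, concatenate and fuse HLG block outputs
#'
#' Each block output is channel-compressed by a 1x1 convolution (to C/2 by
#' default), all compressed maps are concatenated, and a final 1x1
#' convolution fuses them back to the base channel count, giving the
#' aggregated map M for reconstruction.
#'
#' @param block_outputs List of `(C, H, W)` arrays (the per-block fused
#'   outputs after their residual skips).
#' @param params The `reuse` branch of an `hlg_params` tree.
#' @return `(C, H, W)` aggregated feature array.
#' @export
feature_reuse <- function(block_outputs, params) {
  if (!length(block_outputs)) stop("feature_reuse: need at least one block output")
  d0 <- dim(as_fm4(block_outputs[[1]]))
  comp <- lapply(seq_along(block_outputs), function(i) {
    x <- as_fm4(block_outputs[[i]])
    if (!all(dim(x) == d0)) stop("feature_reuse: block outputs must share dims")
    conv2d_fwd(x, params$comp[[i]]$W, params$comp[[i]]$b, 1L)
  })
  cc <- sum(vapply(comp, function(z) dim(z)[1], integer(1)))
  cat4 <- array(0, c(cc, d0[2], d0[3], d0[4]))
  at <- 0L
  for (z in comp) {
    cz <- dim(z)[1]
    cat4[(at + 1L):(at + cz), , , ] <- z
    at <- at + cz
  }
  fm_drop(conv2d_fwd(cat4, params$fuse$W, params$fuse$b, 1L))
}

#' Reconstruction stage
#'
#' A 1x1 convolution reduces the aggregated features to `scale^2` channels,
#' pixel shuffle rearranges them into a single `scale`-times-larger channel,
#' and the result is added to a bicubic upsample of the input image. With
#' the reduction convolution zeroed the output is exactly the bicubic
#' interpolation.
#'
#' @param m `(C, H, W)` aggregated feature array.
#' @param input_image A [gray_image] (in the working `[-1,1]` range) or an
#'   `H x W` matrix.
#' @param params The `recon` branch of an `hlg_params` tree.
#' @param scale Upsampling factor (default 2).
#' @return A [gray_image] with `dynamic_range` `(-1, 1)`, size
#'   `(scale*H, scale*W)`.
#' @export
reconstruct_sr <- function(m, input_image, params, scale = 2L) {
  m <- as_fm4(m)
  d <- dim(m)
  if (ncol(params$W) != scale^2)
    stop("reconstruct_sr: reduction must emit scale^2 channels")
  z <- conv2d_fwd(m, params$W, params$b, 1L)
  up <- pixel_shuffle(z, scale)
  px <- if (is_gray_image(input_image)) input_image$pixels else as.matrix(input_image)
  bic <- .resize_bicubic_mat(px, d[2] * scale, d[3] * scale)
  out <- array(up, c(d[2] * scale, d[3] * scale)) + bic
  gray_image(out, c(-1, 1))
}

# --- end-to-end forward/backward ---------------------------------------------

# x: (1, H, W, N) in [-1, 1]
hlg_fwd <- function(x, params, training = FALSE) {
  cfg <- params$config
  x <- as_fm4(x)
  d <- dim(x)
  p <- params$prelim
  p1 <- conv2d_fwd(x, p$pw1$W, p$pw1$b, 1L); a1 <- relu_fwd(p1)
  c3 <- conv2d_fwd(a1, p$conv3$W, p$conv3$b, 3L); a2 <- relu_fwd(c3)
  f0 <- conv2d_fwd(a2, p$pw2$W, p$pw2$b, 1L)
  cur <- f0
  blocks <- vector("list", cfg$n_blocks)
  outs <- vector("list", cfg$n_blocks)
  for (i in seq_len(cfg$n_blocks)) {
    r <- hlg_block_fwd(cur, params$blocks[[i]], cfg, training)
    blocks[[i]] <- r
    outs[[i]] <- r$fused + cur           # residual skip inside the stack
    cur <- outs[[i]]
  }
  C <- cfg$channels
  comp <- vector("list", cfg$n_blocks)
  cat4 <- array(0, c(cfg$n_blocks * (C %/% 2L), d[2], d[3], d[4]))
  for (i in seq_len(cfg$n_blocks)) {
    comp[[i]] <- conv2d_fwd(outs[[i]], params$reuse$comp[[i]]$W,
                            params$reuse$comp[[i]]$b, 1L)
    cat4[((i - 1L) * (C %/% 2L) + 1L):(i * (C %/% 2L)), , , ] <- comp[[i]]
  }
  M <- conv2d_fwd(cat4, params$reuse$fuse$W, params$reuse$fuse$b, 1L)
  z <- conv2d_fwd(M, params$recon$W, params$recon$b, 1L)
  up <- pixel_shuffle(z, cfg$scale)
  bic <- up * 0
  for (n in seq_len(d[4]))
    bic[1, , , n] <- .resize_bicubic_mat(array(x[1, , , n], d[2:3]),
                                         d[2] * cfg$scale, d[3] * cfg$scale)
  out <- up + bic
  cache <- if (training) list(x = x, p1 = p1, a1 = a1, c3 = c3, a2 = a2,
                              f0 = f0, blocks = blocks, outs = outs,
                              cat4 = cat4, M = M, z_dim = dim(z)) else NULL
  list(out = out, cache = cache)
}

hlg_bwd <- function(dout, params, cache) {
  cfg <- params$config
  g <- zero_like(params)
  g$config <- params$config
  dup <- pixel_shuffle_bwd(dout, cache$z_dim, cfg$scale)
  rb <- conv2d_bwd(dup, cache$M, params$recon$W, 1L)
  g$recon$W <- rb$dW; g$recon$b <- rb$db
  fb <- conv2d_bwd(rb$dx, cache$cat4, params$reuse$fuse$W, 1L)
  g$reuse$fuse$W <- fb$dW; g$reuse$fuse$b <- fb$db
  C <- cfg$channels
  half <- C %/% 2L
  dcur <- NULL
  for (i in rev(seq_len(cfg$n_blocks))) {
    dcomp <- fb$dx[((i - 1L) * half + 1L):(i * half), , , , drop = FALSE]
    cbk <- conv2d_bwd(dcomp, cache$outs[[i]], params$reuse$comp[[i]]$W, 1L)
    g$reuse$comp[[i]]$W <- cbk$dW; g$reuse$comp[[i]]$b <- cbk$db
    dout_i <- cbk$dx
    if (!is.null(dcur)) dout_i <- dout_i + dcur
    bb <- hlg_block_bwd(dout_i, NULL, params$blocks[[i]], cfg,
                        cache$blocks[[i]]$cache)
    g$blocks[[i]] <- bb$grads
    dcur <- bb$dx + dout_i               # residual: out_i = fused + cur
  }
  p <- params$prelim
  b2 <- conv2d_bwd(dcur, cache$a2, p$pw2$W, 1L)
  g$prelim$pw2$W <- b2$dW; g$prelim$pw2$b <- b2$db
  dc3 <- relu_bwd(b2$dx, cache$c3)
  b1 <- conv2d_bwd(dc3, cache$a1, p$conv3$W, 3L)
  g$prelim$conv3$W <- b1$dW; g$prelim$conv3$b <- b1$db
  dp1 <- relu_bwd(b1$dx, cache$p1)
  b0 <- conv2d_bwd(dp1, cache$x, p$pw1$W, 1L)
  g$prelim$pw1$W <- b0$dW; g$prelim$pw1$b <- b0$db
  g
}

# --- SRCNN baseline -----------------------------------------------------------

#' Initialise the SRCNN-style baseline
#'
#' Feature extraction: two 3x3/64 convolutions (stride 1, pad 1, ReLU);
#' upsampling: one 4x4 stride-2 pad-1 transposed convolution with 64 filters;
#' reconstruction: a 3x3 convolution from 64 channels down to 1. The final
#' convolution is zero-initialised so training starts from a flat residual.
#' @param filters Filter count per stage (default 64).
#' @export
srcnn_init <- function(filters = 64L) {
  f <- as.integer(filters)
  structure(list(
    conv1 = list(W = he_conv(1L, 3L, f), b = rep(0, f)),
    conv2 = list(W = he_conv(f, 3L, f), b = rep(0, f)),
    tconv = list(W = matrix(rnorm(f * 16L * f, sd = sqrt(2 / (f * 4L))),
                            f * 16L, f), b = rep(0, f)),
    conv3 = list(W = matrix(0, f * 9L, 1L), b = rep(0, 1))),
    class = "srcnn_params")
}

srcnn_fwd_internal <- function(x, params, training = FALSE) {
  x <- as_fm4(x)
  c1 <- conv2d_fwd(x, params$conv1$W, params$conv1$b, 3L); a1 <- relu_fwd(c1)
  c2 <- conv2d_fwd(a1, params$conv2$W, params$conv2$b, 3L); a2 <- relu_fwd(c2)
  u <- tconv2d_fwd(a2, params$tconv$W, params$tconv$b, 4L, 2L, 1L)
  au <- relu_fwd(u)
  out <- conv2d_fwd(au, params$conv3$W, params$conv3$b, 3L)
  d <- dim(x)
  for (n in seq_len(d[4]))
    out[1, , , n] <- out[1, , , n] +
      .resize_bicubic_mat(array(x[1, , , n], d[2:3]), 2L * d[2], 2L * d[3])
  cache <- if (training) list(x = x, c1 = c1, a1 = a1, c2 = c2, a2 = a2,
                              u = u, au = au) else NULL
  list(out = out, cache = cache)
}

srcnn_bwd <- function(dout, params, cache) {
  g <- zero_like(params)
  b3 <- conv2d_bwd(dout, cache$au, params$conv3$W, 3L)
  g$conv3$W <- b3$dW; g$conv3$b <- b3$db
  du <- relu_bwd(b3$dx, cache$u)
  bt <- tconv2d_bwd(du, cache$a2, params$tconv$W, 4L, 2L, 1L)
  g$tconv$W <- bt$dW; g$tconv$b <- bt$db
  dc2 <- relu_bwd(bt$dx, cache$c2)
  b2 <- conv2d_bwd(dc2, cache$a1, params$conv2$W, 3L)
  g$conv2$W <- b2$dW; g$conv2$b <- b2$db
  dc1 <- relu_bwd(b2$dx, cache$c1)
  b1 <- conv2d_bwd(dc1, cache$x, params$conv1$W, 3L)
  g$conv1$W <- b1$dW; g$conv1$b <- b1$db
  g
}

#' SRCNN-style forward pass
#'
#' @param image A [gray_image] in the `[-1,1]` working range, or a
#'   `(1, H, W)` array.
#' @param params An `srcnn_params` tree from [srcnn_init].
#' @param stages Return the intermediate stage shapes as an attribute
#'   (default FALSE).
#' @return A [gray_image] (or array) of size `2H x 2W`.
#' @export
srcnn_forward <- function(image, params, stages = FALSE) {
  x <- if (is_gray_image(image)) array(image$pixels, c(1L, image$height, image$width))
  else image
  r <- srcnn_fwd_internal(as_fm4(x), params, training = stages)
  out <- fm_drop(r$out)
  res <- if (is_gray_image(image)) gray_image(array(out, dim(out)[2:3]), c(-1, 1))
  else out
  if (stages) {
    attr(res, "stage_dims") <- list(features = dim(r$cache$a2)[1:3],
                                    upsampled = dim(r$cache$au)[1:3],
                                    output = dim(r$out)[1:3])
  }
  res
}

# --- loss and training --------------------------------------------------------

#' Mean squared error between image batches
#'
#' Mean over the batch of mean squared pixel differences (for equally sized
#' images this is the grand mean over all pixels of all images).
#'
#' @param pred,target A [gray_image], a numeric array, or a list of either.
#' @return Non-negative scalar.
#' @export
mse_loss <- function(pred, target) {
  to_list <- function(z) {
    if (is_gray_image(z)) list(z$pixels)
    else if (is.list(z)) lapply(z, function(q) if (is_gray_image(q)) q$pixels else q)
    else list(z)
  }
  p <- to_list(pred); t <- to_list(target)
  if (length(p) != length(t)) stop("mse_loss: batch sizes differ")
  per <- vapply(seq_along(p), function(i) {
    if (!identical(dim(as.array(p[[i]])), dim(as.array(t[[i]]))))
      stop("mse_loss: shape mismatch")
    mean((p[[i]] - t[[i]])^2)
  }, numeric(1))
  mean(per)
}

#' Train a super-resolution model
#'
#' Minimises the MSE between predicted and target high-resolution images with
#' Adam. Deterministic for a fixed seed (single-threaded execution assumed).
#'
#' @param model `"hlg"` or `"srcnn"`.
#' @param pairs List of `list(lr = , hr = )` [gray_image] pairs with
#'   `dim(hr) = scale * dim(lr)`.
#' @param config List: `epochs` (default 5), `batch` (8), `lr` (1e-3),
#'   `crop` (LR crop side for patch sampling, `NULL` = whole image), plus an
#'   optional `hlg` ([hlg_config]) or `filters` (SRCNN) entry.
#' @param seed Integer seed for initialisation, shuffling and crops.
#' @return An `sr_train_state`: `params`, `model`, `loss_history` (one entry
#'   per epoch), `epoch`, `seed`, `config`.
#' @export
train_sr <- function(model = c("hlg", "srcnn"), pairs, config = list(), seed = 1L) {
  model <- match.arg(model)
  if (!length(pairs)) stop("train_sr: need at least one LR/HR pair")
  cfg <- utils::modifyList(list(epochs = 5L, batch = 8L, lr = 1e-3, crop = NULL),
                           config)
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  scale <- round(pairs[[1]]$hr$height / pairs[[1]]$lr$height)
  params <- if (model == "hlg") {
    hcfg <- if (is.null(cfg$hlg)) hlg_config(scale = scale) else cfg$hlg
    hlg_init(hcfg)
  } else srcnn_init(if (is.null(cfg$filters)) 64L else cfg$filters)
  lr_mats <- lapply(pairs, function(p) img_to_unit(p$lr))
  hr_mats <- lapply(pairs, function(p) img_to_unit(p$hr))
  hs <- nrow(lr_mats[[1]]); ws <- ncol(lr_mats[[1]])
  opt <- adam_init(params)
  loss_history <- numeric(0)
  n <- length(pairs)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample(n)
    ep_loss <- 0; nb <- 0L
    i0 <- 1L
    while (i0 <= n) {
      idx <- ord[i0:min(i0 + cfg$batch - 1L, n)]
      B <- length(idx)
      if (is.null(cfg$crop)) {
        ch <- hs; cw <- ws
        xb <- array(0, c(1L, ch, cw, B)); yb <- array(0, c(1L, ch * scale, cw * scale, B))
        for (j in seq_len(B)) {
          xb[1, , , j] <- lr_mats[[idx[j]]]
          yb[1, , , j] <- hr_mats[[idx[j]]]
        }
      } else {
        ch <- cw <- cfg$crop
        xb <- array(0, c(1L, ch, cw, B)); yb <- array(0, c(1L, ch * scale, cw * scale, B))
        for (j in seq_len(B)) {
          r0 <- sample.int(hs - ch + 1L, 1L); c0 <- sample.int(ws - cw + 1L, 1L)
          xb[1, , , j] <- lr_mats[[idx[j]]][r0:(r0 + ch - 1L), c0:(c0 + cw - 1L)]
          yb[1, , , j] <- hr_mats[[idx[j]]][((r0 - 1L) * scale + 1L):((r0 + ch - 1L) * scale),
                                            ((c0 - 1L) * scale + 1L):((c0 + cw - 1L) * scale)]
        }
      }
      fw <- if (model == "hlg") hlg_fwd(xb, params, training = TRUE)
      else srcnn_fwd_internal(xb, params, training = TRUE)
      diff <- fw$out - yb
      loss <- mean(diff^2)
      if (!is.finite(loss))
        stop(sprintf("train_sr: non-finite loss at epoch %d (diverged)", ep))
      dout <- 2 * diff / length(diff)
      grads <- if (model == "hlg") hlg_bwd(dout, params, fw$cache)
      else srcnn_bwd(dout, params, fw$cache)
      st <- adam_step(params, grads, opt, lr = cfg$lr)
      params <- st$params
      class(params) <- if (model == "hlg") "hlg_params" else "srcnn_params"
      opt <- st$state
      ep_loss <- ep_loss + loss; nb <- nb + 1L
      i0 <- i0 + cfg$batch
    }
    loss_history <- c(loss_history, ep_loss / nb)
  }
  structure(list(params = params, model = model, loss_history = loss_history,
                 epoch = cfg$epochs, seed = as.integer(seed), config = cfg),
            class = "sr_train_state")
}

#' Enhance (super-resolve) an image with a trained model
#'
#' @param state An `sr_train_state` from [train_sr] (or a bare parameter tree
#'   plus `model`).
#' @param image A [gray_image] in any dynamic range; it is mapped to the
#'   `[-1,1]` working range, enhanced, and mapped back.
#' @param model Override the model kind when passing bare parameters.
#' @return The enhanced [gray_image] in the input's dynamic range.
#' @export
sr_enhance <- function(state, image, model = NULL) {
  params <- if (inherits(state, "sr_train_state")) state$params else state
  model <- if (inherits(state, "sr_train_state")) state$model
  else if (!is.null(model)) model
  else if (inherits(params, "hlg_params")) "hlg" else "srcnn"
  x <- array(img_to_unit(image), c(1L, image$height, image$width, 1L))
  out <- if (model == "hlg") hlg_fwd(x, params, training = FALSE)$out
  else srcnn_fwd_internal(x, params, training = FALSE)$out
  unit_to_img(array(out, dim(out)[2:3]), image$dynamic_range)
}
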