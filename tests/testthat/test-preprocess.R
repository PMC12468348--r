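# ROI crop, bilinear resize, Gaussian smoothing/blending, normalisation.

test_that("crop_roi returns the tight bounding box of bright pixels", {
  black <- gray_image(matrix(0, 20, 20))
  expect_identical(crop_roi(black)$pixels, black$pixels)

  # bright disc inside a black frame; oracle: brute-force thresholded bbox
  px <- matrix(0, 50, 50)
  for (i in 1:50) for (j in 1:50)
    if ((i - 25)^2 + (j - 25)^2 <= 25) px[i, j] <- 200
  img <- gray_image(px)
  cropped <- crop_roi(img, 0.05)
  mask <- px > 0.05 * max(px)
  rows <- range(which(apply(mask, 1, any)))
  cols <- range(which(apply(mask, 2, any)))
  expect_identical(cropped$pixels,
                   px[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE])
  expect_true(all(dim(cropped$pixels) >= 10) && all(dim(cropped$pixels) <= 12))

  # no black border: unchanged dims
  full <- rand_image(9, 11, c(100, 255), seed = 3)
  expect_equal(dim(crop_roi(full)$pixels), c(9L, 11L))
})

test_that("bilinear resize matches a brute-force evaluation", {
  img <- rand_image(13, 9, seed = 5)
  same <- resize_image(img, c(13, 9))
  expect_equal(same$pixels, img$pixels, tolerance = 1e-9)

  const <- gray_image(matrix(7, 5, 5))
  up <- resize_image(const, c(12, 8))
  expect_true(all(abs(up$pixels - 7) < 1e-12))

  src <- gray_image(matrix(c(0, 2, 2, 4), 2, 2))
  out <- resize_image(src, c(4, 4))
  # brute-force bilinear at pixel-centre-aligned coordinates, edge clamped
  oracle <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) {
    r <- min(max((i - 0.5) * 2 / 4 - 0.5, 0), 1)
    c <- min(max((j - 0.5) * 2 / 4 - 0.5, 0), 1)
    r0 <- floor(r); c0 <- floor(c)
    r1 <- min(r0 + 1, 1); c1 <- min(c0 + 1, 1)
    fr <- r - r0; fc <- c - c0
    oracle[i, j] <- (1 - fr) * (1 - fc) * src$pixels[r0 + 1, c0 + 1] +
      (1 - fr) * fc * src$pixels[r0 + 1, c1 + 1] +
      fr * (1 - fc) * src$pixels[r1 + 1, c0 + 1] +
      fr * fc * src$pixels[r1 + 1, c1 + 1]
  }
  expect_equal(out$pixels, oracle, tolerance = 1e-12)
  expect_true(all(out$pixels >= 0 & out$pixels <= 4))
  expect_error(resize_image(img, c(0, 5)), "positive")
})

test_that("gaussian_kernel is normalised with the stated shape", {
  for (s in c(0.3, 1, 2.7)) {
    k <- gaussian_kernel(s)
    expect_equal(sum(k$weights), 1, tolerance = 1e-12)
    expect_equal(k$radius, ceiling(3 * s))
    expect_identical(k$weights, k$weights[rev(seq_len(nrow(k$weights))),
                                          rev(seq_len(ncol(k$weights)))])
    expect_equal(which.max(k$weights),
                 (length(k$weights) + 1L) %/% 2L)  # centre is the max
  }
  k1 <- gaussian_kernel(1)
  ctr <- k1$radius + 1L
  expect_equal(k1$weights[ctr, ctr] / k1$weights[ctr + 1L, ctr], exp(0.5),
               tolerance = 1e-12)
  k03 <- gaussian_kernel(0.3)
  expect_gt(k03$weights[2, 2], 0.9)
  expect_error(gaussian_kernel(0), "> 0")
})

test_that("gaussian_blur matches the quadruple-loop convolution oracle", {
  img <- gray_image(matrix(runif(49, 0, 255), 7, 7))
  k <- gaussian_kernel(0.5)
  out <- gaussian_blur(img, k)
  r <- k$radius
  oracle <- matrix(0, 7, 7)
  for (x in 1:7) for (y in 1:7) {
    acc <- 0
    for (u in -r:r) for (v in -r:r) {
      xu <- x - u; yv <- y - v
      if (xu >= 1 && xu <= 7 && yv >= 1 && yv <= 7)
        acc <- acc + img$pixels[xu, yv] * k$weights[u + r + 1, v + r + 1]
    }
    oracle[x, y] <- acc
  }
  expect_equal(out$pixels, oracle, tolerance = 1e-10)

  # constant interior is preserved; delta reproduces the kernel
  const <- gray_image(matrix(42, 11, 11))
  bc <- gaussian_blur(const, gaussian_kernel(1))
  rr <- gaussian_kernel(1)$radius
  inner <- bc$pixels[(rr + 1):(11 - rr), (rr + 1):(11 - rr)]
  expect_true(all(abs(inner - 42) < 1e-10))

  delta <- matrix(0, 9, 9); delta[5, 5] <- 1
  bd <- gaussian_blur(gray_image(delta, c(0, 1)), gaussian_kernel(0.5))
  k05 <- gaussian_kernel(0.5)
  expect_equal(bd$pixels[(5 - k05$radius):(5 + k05$radius),
                         (5 - k05$radius):(5 + k05$radius)],
               k05$weights, tolerance = 1e-12)
})

test_that("blur invariants: linear in intensity, extrema bounded", {
  img <- rand_image(12, 12, seed = 9)
  k <- gaussian_kernel(0.8)
  b1 <- gaussian_blur(img, k)
  b3 <- gaussian_blur(gray_image(img$pixels * 3, c(0, 765)), k)
  expect_equal(b3$pixels, 3 * b1$pixels, tolerance = 1e-9)
  expect_lte(max(b1$pixels), max(img$pixels) + 1e-9)
  expect_gte(min(b1$pixels), 0 - 1e-9)   # zero padding can only pull toward 0
})

test_that("blend follows alpha*R + beta*B + gamma", {
  img <- rand_image(8, 8, seed = 2)
  blur <- gaussian_blur(img, gaussian_kernel(1))
  expect_equal(blend_images(img, blur, c(1, 0, 0))$pixels, img$pixels)
  expect_equal(blend_images(img, blur, c(0, 1, 0))$pixels, blur$pixels)
  const <- gray_image(matrix(3, 9, 9))
  sharp <- blend_images(const, gaussian_blur(const, gaussian_kernel(0.5)),
                        c(4, -4, 0.5))
  inner <- sharp$pixels[3:7, 3:7]
  expect_true(all(abs(inner - 0.5) < 1e-10))
  expect_error(blend_images(img, rand_image(4, 4), c(1, 1, 0)), "dimensions")
})

test_that("normalize_minmax maps extremes to [-1, 1] and is idempotent", {
  img <- gray_image(matrix(0:255, 16, 16))
  nm <- normalize_minmax(img)
  expect_equal(min(nm$pixels), -1)
  expect_equal(max(nm$pixels), 1)
  expect_equal(nm$dynamic_range, c(-1, 1))
  two <- normalize_minmax(gray_image(matrix(c(10, 20), 1, 2)))
  expect_equal(as.numeric(two$pixels), c(-1, 1))
  expect_error(normalize_minmax(gray_image(matrix(5, 3, 3))), "degenerate")
  again <- normalize_minmax(nm)
  expect_equal(again$pixels, nm$pixels, tolerance = 1e-12)
})

test_that("full pipeline yields target-size rasters in [-1, 1]", {
  rec <- generate_fundus(2, phantom_params(image_side = 112L), seed = 5)
  cfg <- preprocess_config(target = c(56, 56))
  out <- preprocess_pipeline(rec$image, cfg)
  expect_equal(dim(out$pixels), c(56L, 56L))
  expect_true(all(out$pixels >= -1 & out$pixels <= 1))
  # determinism
  out2 <- preprocess_pipeline(rec$image, cfg)
  expect_identical(out$pixels, out2$pixels)
  # blur disabled equals crop . resize . normalize
  cfg2 <- preprocess_config(target = c(56, 56), blur = FALSE)
  manual <- normalize_minmax(resize_image(crop_roi(rec$image, 0.05), c(56, 56)))
  expect_equal(preprocess_pipeline(rec$image, cfg2)$pixels, manual$pixels)
})
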