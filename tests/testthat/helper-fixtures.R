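# Shared fixtures: small random rasters, tiny network configs, and a central
# finite-difference gradient checker used by several suites.

rand_image <- function(h, w, range = c(0, 255), seed = 1) {
  old <- retinasr:::local_seed(seed)
  on.exit(retinasr:::restore_seed(old))
  gray_image(matrix(sample(seq(range[1], range[2]), h * w, replace = TRUE), h, w),
             range)
}

rand_fm <- function(C, H, W, N = NULL, seed = 1, sd = 1) {
  old <- retinasr:::local_seed(seed)
  on.exit(retinasr:::restore_seed(old))
  if (is.null(N)) array(rnorm(C * H * W, sd = sd), c(C, H, W))
  else array(rnorm(C * H * W * N, sd = sd), c(C, H, W, N))
}

# central-difference gradient of scalar-valued f at selected indices
num_grad_at <- function(f, p, idx, eps = 1e-5) {
  vapply(idx, function(i) {
    p1 <- p; p1[i] <- p1[i] + eps
    p2 <- p; p2[i] <- p2[i] - eps
    (f(p1) - f(p2)) / (2 * eps)
  }, numeric(1))
}

max_rel_err <- function(a, b) {
  max(abs(a - b) / pmax(1e-6, abs(a) + abs(b)))
}

tiny_unet_config <- function(side = 16L) {
  unet_config(input_side = side, encoder_filters = c(2L, 3L, 4L, 5L))
}
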