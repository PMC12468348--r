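# Assembly of the SR networks: preliminary features, HLG block, feature
# reuse, reconstruction, the SRCNN baseline, MSE loss and training.

ns <- asNamespace("retinasr")

make_hlg <- function(C = 4L, blocks = 2L, seed = 1) {
  old <- retinasr:::local_seed(seed)
  on.exit(retinasr:::restore_seed(old))
  hlg_init(hlg_config(channels = C, n_blocks = blocks, embed = 2L))
}

test_that("preliminary_features preserves space and hits the channel target", {
  hp <- make_hlg(C = 8L)
  x <- rand_fm(1, 8, 8, seed = 2, sd = 0.5)
  f <- preliminary_features(x, hp)
  expect_equal(dim(f), c(8L, 8L, 8L))
  # constructed-weights oracle: expansion duplicates the channel, the 3x3 is
  # a centred delta, and the merge averages -> output equals the input,
  # broadcast over channels
  C <- 4L; C2 <- 8L
  hp2 <- make_hlg(C = C)
  hp2$prelim$pw1$W <- matrix(1, 1, C2); hp2$prelim$pw1$b <- rep(0, C2)
  delta <- matrix(0, C2 * 9, C2)
  for (c in 1:C2) delta[c + C2 * 4, c] <- 1   # centre tap (k = 4)
  hp2$prelim$conv3$W <- delta; hp2$prelim$conv3$b <- rep(0, C2)
  hp2$prelim$pw2$W <- matrix(1 / C2, C2, C); hp2$prelim$pw2$b <- rep(0, C)
  xp <- rand_fm(1, 6, 6, seed = 3, sd = 0.5)
  xp[] <- abs(xp)                              # keep ReLUs transparent
  f2 <- preliminary_features(xp, hp2)
  for (c in 1:C) expect_equal(f2[c, , ], xp[1, , ], tolerance = 1e-12)
})

test_that("hlg_block keeps shapes and supports branch ablation", {
  hp <- make_hlg()
  cfg <- hlg_config(channels = 4L, n_blocks = 2L, embed = 2L)
  x <- rand_fm(4, 6, 6, seed = 4, sd = 0.5)
  out <- hlg_block(x, hp$blocks[[1]], cfg)
  expect_s3_class(out, "hlg_block_output")
  for (nm in c("alm", "ipgm", "psgm", "fused"))
    expect_equal(dim(out[[nm]]), c(4L, 6L, 6L))
  # ablation: zero the IPGM and PSGM contributions in the fusion weights and
  # compare against an ALM+input-only assembly
  bp <- hp$blocks[[1]]
  bp$fuse$W[5:12, ] <- 0                       # rows of ipgm+psgm slices
  ab <- hlg_block(x, bp, cfg)
  cat0 <- array(0, c(16, 6, 6))
  cat0[1:4, , ] <- ab$alm
  cat0[13:16, , ] <- x
  manual <- ns$fm_drop(ns$conv2d_fwd(ns$as_fm4(cat0), bp$fuse$W, bp$fuse$b, 1L))
  expect_equal(ab$fused, manual, tolerance = 1e-10)
})

test_that("feature_reuse compresses, concatenates and fuses", {
  hp <- make_hlg(C = 4L, blocks = 1L)
  # identity 1x1 convs collapse the formula to the single block output
  hp$reuse$comp[[1]]$W <- diag(4)[, 1:2]       # C -> C/2 slice
  m0 <- rand_fm(4, 5, 5, seed = 5)
  # full identity variant: one block, identity compress and fuse
  hp_id <- hp
  hp_id$reuse$comp[[1]]$W <- diag(4); hp_id$reuse$comp[[1]]$b <- rep(0, 4)
  hp_id$reuse$fuse$W <- diag(4); hp_id$reuse$fuse$b <- rep(0, 4)
  expect_equal(feature_reuse(list(m0), hp_id$reuse), m0, tolerance = 1e-12)
  # k blocks at C/2 each concatenate to k*C/2 channels before fusion
  hp2 <- make_hlg(C = 4L, blocks = 3L)
  outs <- lapply(1:3, function(i) rand_fm(4, 5, 5, seed = 10 + i))
  M <- feature_reuse(outs, hp2$reuse)
  expect_equal(dim(M), c(4L, 5L, 5L))
  # per-pixel linear-algebra oracle
  px <- c(2, 3)
  comp <- lapply(1:3, function(i)
    t(hp2$reuse$comp[[i]]$W) %*% outs[[i]][, px[1], px[2]] + hp2$reuse$comp[[i]]$b)
  oracle <- t(hp2$reuse$fuse$W) %*% do.call(c, comp) + hp2$reuse$fuse$b
  expect_equal(M[, px[1], px[2]], as.numeric(oracle), tolerance = 1e-9)
  expect_error(feature_reuse(list(), hp2$reuse), "at least one")
})

test_that("reconstruction with a zeroed branch is exactly bicubic", {
  hp <- make_hlg()                              # recon conv is zero-initialised
  m <- rand_fm(4, 8, 8, seed = 6)
  input <- matrix(runif(64, -1, 1), 8, 8)
  out <- reconstruct_sr(m, input, hp$recon, scale = 2)
  expect_equal(dim(out$pixels), c(16L, 16L))
  bic <- ns$.resize_bicubic_mat(input, 16, 16)
  expect_lt(max(abs(out$pixels - bic)), 1e-6)
  expect_equal(length(out$pixels), 4L * length(input))
})

test_that("end-to-end network output doubles the input and stays finite", {
  hp <- make_hlg()
  for (trial in 1:5) {
    x <- array(runif(8 * 8, -1, 1), c(1, 8, 8, 1))
    out <- ns$hlg_fwd(x, hp, training = FALSE)$out
    expect_equal(dim(out), c(1L, 16L, 16L, 1L))
    expect_true(all(is.finite(out)))
  }
})

test_that("srcnn reproduces the printed stage dimensions", {
  old <- retinasr:::local_seed(3)
  on.exit(retinasr:::restore_seed(old))
  sp <- srcnn_init(filters = 64L)
  img <- gray_image(matrix(runif(224 * 224, -1, 1), 224, 224), c(-1, 1))
  out <- srcnn_forward(img, sp, stages = TRUE)
  dims <- attr(out, "stage_dims")
  expect_equal(dims$features, c(64L, 224L, 224L))
  expect_equal(dims$upsampled, c(64L, 448L, 448L))
  expect_equal(dims$output, c(1L, 448L, 448L))
  expect_equal(dim(out$pixels), c(448L, 448L))
})

test_that("mse_loss matches the explicit double-sum oracle", {
  a <- gray_image(matrix(1:4, 2, 2), c(0, 255))
  expect_equal(mse_loss(a, a), 0)
  b <- gray_image(matrix(1:4 + 1, 2, 2), c(0, 255))
  expect_equal(mse_loss(a, b), 1)
  set.seed(9)
  preds <- lapply(1:3, function(i) matrix(rnorm(12), 3, 4))
  tgts <- lapply(1:3, function(i) matrix(rnorm(12), 3, 4))
  oracle <- mean(vapply(1:3, function(k) {
    s <- 0
    for (i in 1:3) for (j in 1:4) s <- s + (preds[[k]][i, j] - tgts[[k]][i, j])^2
    s / 12
  }, numeric(1)))
  expect_equal(mse_loss(preds, tgts), oracle, tolerance = 1e-12)
  expect_error(mse_loss(list(matrix(0, 2, 2)), list(matrix(0, 3, 3))), "shape")
})

test_that("gradients of the full SR network agree with finite differences", {
  old <- retinasr:::local_seed(5)
  on.exit(retinasr:::restore_seed(old))
  hp <- make_hlg(C = 4L, blocks = 1L, seed = 5)
  hp$recon$W <- matrix(rnorm(length(hp$recon$W), sd = 0.3), nrow(hp$recon$W))
  # perturb the deformable predictors off integer sampling positions, where
  # the bilinear kernel has kinks and central differences are invalid
  hp$blocks[[1]]$dconv$Wp <- matrix(rnorm(length(hp$blocks[[1]]$dconv$Wp), sd = 0.05),
                                    nrow(hp$blocks[[1]]$dconv$Wp))
  hp$blocks[[1]]$refine$Wp <- matrix(rnorm(length(hp$blocks[[1]]$refine$Wp), sd = 0.05),
                                     nrow(hp$blocks[[1]]$refine$Wp))
  x <- array(rnorm(36, sd = 0.3), c(1, 6, 6, 1))
  fw <- ns$hlg_fwd(x, hp, training = TRUE)
  dout <- array(rnorm(length(fw$out), sd = 0.5), dim(fw$out))
  g <- ns$hlg_bwd(dout, hp, fw$cache)
  spots <- list(
    list("prelim", "conv3", "W"), list("blocks", 1L, "fuse", "W"),
    list("blocks", 1L, "nl", "theta"), list("blocks", 1L, "dconv", "W"),
    list("recon", "W"))
  set_leaf <- function(tree, path, value) {
    if (length(path) == 1L) { tree[[path[[1]]]] <- value; return(tree) }
    tree[[path[[1]]]] <- set_leaf(tree[[path[[1]]]], path[-1], value)
    tree
  }
  for (sp in spots) {
    getp <- function(tree) Reduce(function(t, k) t[[k]], sp, tree)
    leaf <- getp(hp)
    pv <- as.numeric(leaf)
    gv <- as.numeric(getp(g))
    idx <- sample(length(pv), min(5, length(pv)))
    f <- function(v) {
      h2 <- set_leaf(hp, sp, array(v, dim(as.array(leaf))))
      sum(ns$hlg_fwd(x, h2, training = FALSE)$out * dout)
    }
    ng <- num_grad_at(f, pv, idx)
    expect_lt(max_rel_err(ng, gv[idx]), 1e-4)
  }
})

test_that("train_sr descends, is seed-deterministic, and records history", {
  rec <- generate_fundus(2, phantom_params(image_side = 48L), seed = 3)
  pair <- make_sr_pairs(list(rec), 2L)
  cfg <- list(epochs = 4L, batch = 1L, lr = 1e-3,
              hlg = hlg_config(channels = 4L, n_blocks = 1L, embed = 2L))
  st1 <- train_sr("hlg", pair, cfg, seed = 9)
  expect_length(st1$loss_history, 4L)
  expect_lt(st1$loss_history[4], st1$loss_history[1])
  st2 <- train_sr("hlg", pair, cfg, seed = 9)
  expect_identical(st1$loss_history, st2$loss_history)
  # srcnn path trains too
  sc <- train_sr("srcnn", pair, list(epochs = 3L, batch = 1L, lr = 1e-3,
                                     filters = 8L), seed = 9)
  expect_lt(sc$loss_history[3], sc$loss_history[1] + 1e-12)
  enh <- sr_enhance(st1, pair[[1]]$lr)
  expect_equal(dim(enh$pixels), c(48L, 48L))
})
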