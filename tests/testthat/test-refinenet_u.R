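# RefineNet-U classifier: activations, shape ladder, head, loss, training,
# and the plain-CNN baseline.

ns <- asNamespace("retinasr")

test_that("relu and leaky_relu follow their piecewise definitions", {
  expect_equal(relu(-3), 0)
  expect_equal(relu(2), 2)
  expect_equal(leaky_relu(-2, 0.01), -0.02)
  x <- seq(0, 5, by = 0.5)
  expect_equal(leaky_relu(x, 0.3), relu(x))
  expect_error(leaky_relu(1, 1.5), "slope")
})

test_that("config enforces encoder/decoder symmetry and input divisibility", {
  cfg <- tiny_unet_config()
  expect_identical(cfg$decoder_filters, rev(cfg$encoder_filters))
  expect_error(unet_config(input_side = 100), "divisible by 16")
})

test_that("encoder/bridge/decoder reproduce the spatial shape ladder", {
  old <- retinasr:::local_seed(2)
  on.exit(retinasr:::restore_seed(old))
  side <- 48L
  cfg <- unet_config(input_side = side, encoder_filters = c(2L, 3L, 4L, 5L))
  um <- unet_init(cfg)
  x <- rand_fm(1, side, side, seed = 2, sd = 0.5)
  enc <- encoder_forward(x, um)
  expect_equal(enc$shapes$conv1, c(2L, 48L, 48L))
  expect_equal(enc$shapes$pool1, c(2L, 24L, 24L))
  expect_equal(enc$shapes$pool4, c(5L, 3L, 3L))
  br <- bridge_forward(enc$pooled, um)
  expect_equal(dim(br)[1:3], c(10L, 3L, 3L))       # bridge = 2x last filters
  dec <- decoder_forward(br, enc$skips, um)
  expect_equal(dim(dec)[1:3], c(2L, 48L, 48L))     # side restored, 1st filters
  # 112-side bottleneck arithmetic: 112 / 2^4 = 7
  cfg2 <- unet_config(input_side = 112L, encoder_filters = c(2L, 2L, 2L, 2L))
  um2 <- unet_init(cfg2)
  enc2 <- encoder_forward(rand_fm(1, 112, 112, seed = 3, sd = 0.5), um2)
  expect_equal(enc2$shapes$pool4[2:3], c(7L, 7L))
  # concat doubles the upsampled channels at every decoder level
  expect_equal(dim(ns$unet_fwd(ns$as_fm4(x), um, FALSE)$cache$dec[[1]]$cat4)[1],
               2L * cfg$decoder_filters[1])
})

test_that("classify_head yields a softmax over five grades", {
  old <- retinasr:::local_seed(4)
  on.exit(retinasr:::restore_seed(old))
  cfg <- tiny_unet_config()
  um <- unet_init(cfg)
  dec <- rand_fm(cfg$decoder_filters[4], 16, 16, seed = 4)
  out <- classify_head(dec, um)
  expect_s3_class(out, "classifier_output")
  expect_length(out$probs, 5L)
  expect_equal(sum(out$probs), 1, tolerance = 1e-9)
  expect_equal(out$predicted, which.max(out$probs) - 1L)
  # zero weights -> zero logits -> uniform probabilities
  um0 <- um
  um0$params$head$W1[] <- 0; um0$params$head$b1[] <- 0
  um0$params$head$W2[] <- 0; um0$params$head$b2[] <- 0
  expect_equal(classify_head(dec, um0)$probs, rep(0.2, 5), tolerance = 1e-12)
  # softmax shift invariance
  um_s <- um0
  um_s$params$head$b2 <- rep(3.7, 5)
  expect_equal(classify_head(dec, um_s)$probs, rep(0.2, 5), tolerance = 1e-12)
  # dropout inactive at inference: repeated passes identical
  expect_identical(classify_head(dec, um)$probs, classify_head(dec, um)$probs)
})

test_that("cross_entropy matches the summation oracle and guards labels", {
  onehot <- diag(5)
  perfect <- diag(5)
  expect_equal(cross_entropy(perfect, onehot), 0, tolerance = 1e-9)
  unif <- matrix(0.2, 4, 5)
  labs <- diag(5)[1:4, ]
  expect_equal(cross_entropy(unif, labs), log(5), tolerance = 1e-12)
  set.seed(5)
  p <- matrix(rexp(15), 3, 5); p <- p / rowSums(p)
  y <- diag(5)[sample(1:5, 3, TRUE), ]
  oracle <- -mean(vapply(1:3, function(i) sum(y[i, ] * log(p[i, ])), numeric(1)))
  expect_equal(cross_entropy(p, y), oracle, tolerance = 1e-10)
  expect_error(cross_entropy(p, y * 0.5), "one-hot")
})

test_that("predict_grade breaks ties low and survives monotone transforms", {
  expect_equal(predict_grade(c(0.1, 0.6, 0.1, 0.1, 0.1)), 1L)
  expect_equal(predict_grade(rep(0.2, 5)), 0L)
  set.seed(6)
  for (i in 1:20) {
    p <- runif(5); p <- p / sum(p)
    mono <- sample(list(function(z) z^3, function(z) exp(z),
                        function(z) log(z + 1), function(z) 2 * z + 1), 1)[[1]]
    expect_equal(predict_grade(p), predict_grade(mono(p)))
  }
})

test_that("analytic gradients of the classifier match finite differences", {
  old <- retinasr:::local_seed(7)
  on.exit(retinasr:::restore_seed(old))
  um <- unet_init(tiny_unet_config())
  x <- rand_fm(1, 16, 16, 3, seed = 7)
  y <- c(1L, 3L, 5L)
  fw <- ns$unet_fwd(x, um, training = FALSE)
  ce <- ns$softmax_ce_fwd(fw$logits, y)
  g <- ns$unet_bwd(ns$softmax_ce_bwd(ce$probs, y), um, fw$cache)
  set_leaf <- function(tree, path, value) {
    if (length(path) == 1L) { tree[[path[[1]]]] <- value; return(tree) }
    tree[[path[[1]]]] <- set_leaf(tree[[path[[1]]]], path[-1], value)
    tree
  }
  loss_with <- function(path, v) {
    m2 <- um
    leaf <- Reduce(function(t, k) t[[k]], path, um$params)
    m2$params <- set_leaf(m2$params, path, array(v, dim(as.array(leaf))))
    ns$softmax_ce_fwd(ns$unet_fwd(x, m2, training = FALSE)$logits, y)$loss
  }
  checked <- 0L
  for (path in list(list("enc", 1L, "W1"), list("bridge", "W2"),
                    list("dec", 2L, "Wu"), list("dec", 4L, "W2"),
                    list("head", "W1"))) {
    pv <- as.numeric(Reduce(function(t, k) t[[k]], path, um$params))
    gv <- as.numeric(Reduce(function(t, k) t[[k]], path, g))
    idx <- sample(length(pv), 4)
    ng <- num_grad_at(function(v) loss_with(path, v), pv, idx)
    expect_lt(max_rel_err(ng, gv[idx]), 1e-3)
    checked <- checked + length(idx)
  }
  expect_gte(checked, 20L)
})

test_that("training overfits a toy 2-grade set and is deterministic", {
  old <- retinasr:::local_seed(8)
  on.exit(retinasr:::restore_seed(old))
  side <- 16L
  n <- 20L
  x <- array(0, c(1, side, side, n))
  y <- rep(c(0L, 3L), each = n / 2)
  for (i in seq_len(n)) {
    base <- matrix(rnorm(side^2, sd = 0.1), side, side)
    if (y[i] == 3L) base[6:11, 6:11] <- base[6:11, 6:11] + 1.5
    x[1, , , i] <- base
  }
  ds <- list(x = x, y = y)
  cfg <- tiny_unet_config()
  clf <- train_classifier("refinenet_u", ds, cfg, seed = 1,
                          opts = list(epochs = 20L, batch = 10L, lr = 1e-3))
  expect_equal(tail(clf$history$accuracy, 1), 1.0)
  clf2 <- train_classifier("refinenet_u", ds, cfg, seed = 1,
                           opts = list(epochs = 3L, batch = 10L, lr = 1e-3))
  clf3 <- train_classifier("refinenet_u", ds, cfg, seed = 1,
                           opts = list(epochs = 3L, batch = 10L, lr = 1e-3))
  expect_identical(clf2$history, clf3$history)
  expect_error(train_classifier("refinenet_u", list(x = x, y = rep(0L, n)), cfg, 1),
               "two classes")
})

test_that("baseline CNN emits softmax over 5 classes with fewer parameters", {
  old <- retinasr:::local_seed(9)
  on.exit(retinasr:::restore_seed(old))
  side <- 48L
  cm <- cnn_init(cnn_config(input_side = side))
  out <- baseline_cnn_forward(rand_fm(1, side, side, seed = 9, sd = 0.5), cm)
  expect_length(out$probs, 5L)
  expect_equal(sum(out$probs), 1, tolerance = 1e-9)
  um <- unet_init(unet_config(input_side = side,
                              encoder_filters = c(16L, 32L, 64L, 128L)))
  expect_lt(ns$n_params(cm$params), ns$n_params(um$params))
})
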