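# RefineNet-U: a U-Net style encoder/bridge/decoder whose decoder output is
# flattened into a dropout/dense/softmax head for five-grade severity
# classification, plus a loosely structured plain-CNN baseline. Every
# convolution is followed by batch normalisation and ReLU; the encoder ends
# with dropout 0.5 and the head applies dropout 0.3 before its dense layers.
# The head's first dense layer uses LeakyReLU (slope 0.01) by default.

#' Rectified linear unit
#' @param x Numeric input (any shape).
#' @export
relu <- function(x) pmax(x, 0)

#' Leaky rectified linear unit
#' @param x Numeric.
#' @param a Negative-side slope in (0, 1), default 0.01.
#' @export
leaky_relu <- function(x, a = 0.01) {
  if (a <= 0 || a >= 1) stop("leaky_relu: slope must be in (0, 1)")
  ifelse(x >= 0, x, a * x)
}

#' RefineNet-U configuration
#'
#' @param input_side Input image side; must be divisible by 16 (four 2x
#'   poolings). Default 448.
#' @param encoder_filters Encoder filter counts per level, default
#'   `c(64, 128, 256, 512)`; the decoder mirrors them in reverse.
#' @param bridge_filters Bridge width, default `2 * last encoder filter`.
#' @param dense_units Head layer sizes, default `c(128, 5)`.
#' @param encoder_dropout Dropout rate after the last encoder block (0.5).
#' @param head_dropout Dropout rate before the dense head (0.3).
#' @param leaky_slope Negative slope of the head activation (0.01).
#' @param head_activation `"leaky"` (default) or `"relu"`.
#' @export
unet_config <- function(input_side = 448L,
                        encoder_filters = c(64L, 128L, 256L, 512L),
                        bridge_filters = 2L * encoder_filters[length(encoder_filters)],
                        dense_units = c(128L, 5L),
                        encoder_dropout = 0.5, head_dropout = 0.3,
                        leaky_slope = 0.01,
                        head_activation = c("leaky", "relu")) {
  input_side <- as.integer(input_side)
  if (input_side %% 16L != 0L)
    stop("unet_config: input_side must be divisible by 16")
  list(input_side = input_side,
       encoder_filters = as.integer(encoder_filters),
       decoder_filters = rev(as.integer(encoder_filters)),
       bridge_filters = as.integer(bridge_filters),
       dense_units = as.integer(dense_units),
       encoder_dropout = encoder_dropout, head_dropout = head_dropout,
       leaky_slope = leaky_slope,
       head_activation = match.arg(head_activation))
}

#' Initialise RefineNet-U parameters
#' @param config A [unet_config].
#' @param head Build the flatten/dense head (default TRUE). At the full
#'   448-pixel scale the head alone holds ~1.6e9 weights; shape-ladder runs
#'   through [encoder_forward]/[bridge_forward]/[decoder_forward] can skip it.
#' @return List with `params` (trainable tree) and `bn` (running
#'   batch-normalisation statistics), class `unet_model`.
#' @export
unet_init <- function(config = unet_config(), head = TRUE) {
  ef <- config$encoder_filters
  nl <- length(ef)
  bf <- config$bridge_filters
  df <- config$decoder_filters
  conv_block <- function(cin, cout) list(
    W1 = he_conv(cin, 3L, cout), b1 = rep(0, cout), bn1 = bn_init(cout),
    W2 = he_conv(cout, 3L, cout), b2 = rep(0, cout), bn2 = bn_init(cout))
  bn_state <- function(cout) list(
    bn1 = list(mean = rep(0, cout), var = rep(1, cout)),
    bn2 = list(mean = rep(0, cout), var = rep(1, cout)))
  params <- list(enc = list(), bridge = NULL, dec = list(), head = NULL)
  bn <- list(enc = list(), bridge = NULL, dec = list())
  cin <- 1L
  for (l in seq_len(nl)) {
    params$enc[[l]] <- conv_block(cin, ef[l])
    bn$enc[[l]] <- bn_state(ef[l])
    cin <- ef[l]
  }
  params$bridge <- conv_block(cin, bf)
  bn$bridge <- bn_state(bf)
  cin <- bf
  for (l in seq_len(nl)) {
    f <- df[l]
    blk <- conv_block(2L * f, f)
    blk$Wu <- matrix(rnorm(f * 4L * cin, sd = sqrt(2 / (cin * 4L))), f * 4L, cin)
    blk$bu <- rep(0, f)
    blk$bnu <- bn_init(f)
    params$dec[[l]] <- blk
    st <- bn_state(f)
    st$bnu <- list(mean = rep(0, f), var = rep(1, f))
    bn$dec[[l]] <- st
    cin <- f
  }
  if (head) {
    flat <- df[nl] * config$input_side^2         # decoder restores full side
    params$head <- list(
      W1 = he_dense(flat, config$dense_units[1]), b1 = rep(0, config$dense_units[1]),
      W2 = matrix(0, config$dense_units[2], config$dense_units[1]),
      b2 = rep(0, config$dense_units[2]))
  }
  structure(list(params = params, bn = bn, config = config), class = "unet_model")
}

# random element of the dihedral group (4 rotations x optional flip) applied
# per image; square inputs only
.augment_dihedral <- function(xb) {
  d <- dim(xb)
  for (j in seq_len(d[4])) {
    m <- array(xb[1, , , j], d[2:3])
    k <- sample(0:3, 1L)
    if (k > 0) for (r in seq_len(k)) m <- t(m[nrow(m):1, , drop = FALSE])
    if (runif(1) < 0.5) m <- m[, ncol(m):1, drop = FALSE]
    xb[1, , , j] <- m
  }
  xb
}

# conv -> BN -> ReLU helper; returns activation plus caches and updated stats
.cbr_fwd <- function(x, W, b, bnp, bns, k, training) {
  c1 <- conv2d_fwd(x, W, b, k)
  bnr <- bn_fwd(c1, bnp$gamma, bnp$beta, bns$mean, bns$var, training)
  a <- relu_fwd(bnr$out)
  list(out = a, conv = c1, bn = bnr,
       bns = list(mean = bnr$running_mean, var = bnr$running_var))
}

.cbr_bwd <- function(dout, cache, x, W, bnp, k) {
  da <- relu_bwd(dout, cache$bn$out)
  bb <- bn_bwd(da, cache$bn, bnp$gamma)
  cb <- conv2d_bwd(bb$dx, x, W, k)
  list(dx = cb$dx, dW = cb$dW, db = cb$db,
       dbn = list(gamma = bb$dgamma, beta = bb$dbeta))
}

# full forward; x (1, S, S, N). Returns logits (5 x N) and caches.
unet_fwd <- function(x, model, training = FALSE) {
  p <- model$params; bn <- model$bn; cfg <- model$config
  nl <- length(cfg$encoder_filters)
  x <- as_fm4(x)
  cache <- list(x = x, enc = vector("list", nl), dec = vector("list", nl))
  skips <- vector("list", nl)
  cur <- x
  for (l in seq_len(nl)) {
    e <- p$enc[[l]]; s <- bn$enc[[l]]
    r1 <- .cbr_fwd(cur, e$W1, e$b1, e$bn1, s$bn1, 3L, training)
    r2 <- .cbr_fwd(r1$out, e$W2, e$b2, e$bn2, s$bn2, 3L, training)
    pl <- maxpool_fwd_r(r2$out)
    cache$enc[[l]] <- list(in_ = cur, r1 = r1, r2 = r2, pool = pl)
    bn$enc[[l]] <- list(bn1 = r1$bns, bn2 = r2$bns)
    skips[[l]] <- r2$out
    cur <- pl$out
  }
  dr <- dropout_fwd(cur, cfg$encoder_dropout, training)
  cache$enc_drop <- dr
  cur <- dr$out
  rb1 <- .cbr_fwd(cur, p$bridge$W1, p$bridge$b1, p$bridge$bn1, bn$bridge$bn1, 3L, training)
  rb2 <- .cbr_fwd(rb1$out, p$bridge$W2, p$bridge$b2, p$bridge$bn2, bn$bridge$bn2, 3L, training)
  cache$bridge <- list(in_ = cur, r1 = rb1, r2 = rb2)
  bn$bridge <- list(bn1 = rb1$bns, bn2 = rb2$bns)
  cur <- rb2$out
  for (l in seq_len(nl)) {
    dpb <- p$dec[[l]]; s <- bn$dec[[l]]
    up <- tconv2d_fwd(cur, dpb$Wu, dpb$bu, 2L, 2L, 0L)
    bnu <- bn_fwd(up, dpb$bnu$gamma, dpb$bnu$beta, s$bnu$mean, s$bnu$var, training)
    au <- relu_fwd(bnu$out)
    skip <- skips[[nl - l + 1L]]
    dd <- dim(au)
    cat4 <- array(0, c(2L * dd[1], dd[2], dd[3], dd[4]))
    cat4[1:dd[1], , , ] <- au
    cat4[(dd[1] + 1L):(2L * dd[1]), , , ] <- skip
    r1 <- .cbr_fwd(cat4, dpb$W1, dpb$b1, dpb$bn1, s$bn1, 3L, training)
    r2 <- .cbr_fwd(r1$out, dpb$W2, dpb$b2, dpb$bn2, s$bn2, 3L, training)
    cache$dec[[l]] <- list(in_ = cur, up = up, bnu = bnu, au = au,
                           cat4 = cat4, r1 = r1, r2 = r2)
    bn$dec[[l]] <- list(bn1 = r1$bns, bn2 = r2$bns,
                        bnu = list(mean = bnu$running_mean, var = bnu$running_var))
    cur <- r2$out
  }
  dd <- dim(cur)
  flat <- cur; dim(flat) <- c(prod(dd[1:3]), dd[4])
  hd <- dropout_fwd(flat, cfg$head_dropout, training)
  h1 <- dense_fwd(hd$out, p$head$W1, p$head$b1)
  a1 <- if (cfg$head_activation == "leaky") leaky_fwd(h1, cfg$leaky_slope)
  else relu_fwd(h1)
  logits <- dense_fwd(a1, p$head$W2, p$head$b2)
  cache$head <- list(flat = flat, drop = hd, h1 = h1, a1 = a1, dec_dim = dd)
  list(logits = logits, cache = cache, bn = bn)
}

unet_bwd <- function(dlogits, model, cache) {
  p <- model$params; cfg <- model$config
  nl <- length(cfg$encoder_filters)
  # gradients are assembled by assignment (adam_step matches by name);
  # avoiding zero_like here saves a full parameter-sized allocation per step
  g <- list(enc = vector("list", nl), bridge = list(),
            dec = vector("list", nl), head = list())
  hb2 <- dense_bwd(dlogits, cache$head$a1, p$head$W2)
  g$head$W2 <- hb2$dW; g$head$b2 <- hb2$db
  da1 <- if (cfg$head_activation == "leaky")
    leaky_bwd(hb2$dx, cache$head$h1, cfg$leaky_slope)
  else relu_bwd(hb2$dx, cache$head$h1)
  hb1 <- dense_bwd(da1, cache$head$drop$out, p$head$W1)
  g$head$W1 <- hb1$dW; g$head$b1 <- hb1$db
  dflat <- dropout_bwd(hb1$dx, cache$head$drop$mask)
  dcur <- dflat; dim(dcur) <- cache$head$dec_dim
  for (l in rev(seq_len(nl))) {
    cc <- cache$dec[[l]]; dpb <- p$dec[[l]]
    b2 <- .cbr_bwd(dcur, cc$r2, cc$r1$out, dpb$W2, dpb$bn2, 3L)
    g$dec[[l]]$W2 <- b2$dW; g$dec[[l]]$b2 <- b2$db; g$dec[[l]]$bn2 <- b2$dbn
    b1 <- .cbr_bwd(b2$dx, cc$r1, cc$cat4, dpb$W1, dpb$bn1, 3L)
    g$dec[[l]]$W1 <- b1$dW; g$dec[[l]]$b1 <- b1$db; g$dec[[l]]$bn1 <- b1$dbn
    dd <- dim(cc$au)
    dau <- b1$dx[1:dd[1], , , , drop = FALSE]
    dskip <- array(b1$dx[(dd[1] + 1L):(2L * dd[1]), , , , drop = FALSE], dd)
    dbnu_out <- relu_bwd(dau, cc$bnu$out)
    bu <- bn_bwd(dbnu_out, cc$bnu, dpb$bnu$gamma)
    g$dec[[l]]$bnu <- list(gamma = bu$dgamma, beta = bu$dbeta)
    tb <- tconv2d_bwd(bu$dx, cc$in_, dpb$Wu, 2L, 2L, 0L)
    g$dec[[l]]$Wu <- tb$dW; g$dec[[l]]$bu <- tb$db
    dcur <- tb$dx
    # stash the skip gradient for the matching encoder level
    cache$enc[[nl - l + 1L]]$dskip <- dskip
  }
  b2 <- .cbr_bwd(dcur, cache$bridge$r2, cache$bridge$r1$out, p$bridge$W2, p$bridge$bn2, 3L)
  g$bridge$W2 <- b2$dW; g$bridge$b2 <- b2$db; g$bridge$bn2 <- b2$dbn
  b1 <- .cbr_bwd(b2$dx, cache$bridge$r1, cache$bridge$in_, p$bridge$W1, p$bridge$bn1, 3L)
  g$bridge$W1 <- b1$dW; g$bridge$b1 <- b1$db; g$bridge$bn1 <- b1$dbn
  dcur <- dropout_bwd(b1$dx, cache$enc_drop$mask)
  for (l in rev(seq_len(nl))) {
    cc <- cache$enc[[l]]; e <- p$enc[[l]]
    dpool <- maxpool_bwd_r(dcur, cc$pool)
    dr2 <- dpool + cc$dskip
    b2 <- .cbr_bwd(dr2, cc$r2, cc$r1$out, e$W2, e$bn2, 3L)
    g$enc[[l]]$W2 <- b2$dW; g$enc[[l]]$b2 <- b2$db; g$enc[[l]]$bn2 <- b2$dbn
    b1 <- .cbr_bwd(b2$dx, cc$r1, cc$in_, e$W1, e$bn1, 3L)
    g$enc[[l]]$W1 <- b1$dW; g$enc[[l]]$b1 <- b1$db; g$enc[[l]]$bn1 <- b1$dbn
    dcur <- b1$dx
  }
  g
}

# --- public operation surface --------------------------------------------------

#' Encoder forward pass
#'
#' Four blocks of (3x3 conv + BN + ReLU) x2 followed by 2x2 stride-2 max
#' pooling, with dropout after the last block when training. Pre-pool
#' activations are retained as skip connections.
#'
#' @param image A [gray_image] or `(1, S, S)` array with side divisible by 16.
#' @param model A `unet_model` from [unet_init].
#' @param training Apply dropout (default FALSE).
#' @return List with `pooled` (bottleneck input), `skips` (pre-pool maps),
#'   and `shapes` (dims of every stage).
#' @export
encoder_forward <- function(image, model, training = FALSE) {
  x <- if (is_gray_image(image)) array(image$pixels, c(1L, image$height, image$width))
  else image
  x <- as_fm4(x)
  if (dim(x)[2] %% 16L != 0L)
    stop("encoder_forward: input side must be divisible by 16")
  p <- model$params; bn <- model$bn
  nl <- length(model$config$encoder_filters)
  skips <- vector("list", nl)
  shapes <- list()
  cur <- x
  for (l in seq_len(nl)) {
    e <- p$enc[[l]]; s <- bn$enc[[l]]
    r1 <- .cbr_fwd(cur, e$W1, e$b1, e$bn1, s$bn1, 3L, FALSE)
    r2 <- .cbr_fwd(r1$out, e$W2, e$b2, e$bn2, s$bn2, 3L, FALSE)
    skips[[l]] <- r2$out
    shapes[[paste0("conv", l)]] <- dim(r2$out)[1:3]
    pl <- maxpool_fwd_r(r2$out)
    cur <- pl$out
    shapes[[paste0("pool", l)]] <- dim(cur)[1:3]
  }
  if (training) cur <- dropout_fwd(cur, model$config$encoder_dropout, TRUE)$out
  list(pooled = cur, skips = skips, shapes = shapes)
}

#' Bridge forward pass
#'
#' Two 3x3 convolutions (BN + ReLU) at the bridge width; spatial dimensions
#' unchanged.
#' @param pooled Bottleneck feature map from [encoder_forward].
#' @param model A `unet_model`.
#' @return The bridge feature map.
#' @export
bridge_forward <- function(pooled, model) {
  p <- model$params; bn <- model$bn
  r1 <- .cbr_fwd(as_fm4(pooled), p$bridge$W1, p$bridge$b1, p$bridge$bn1, bn$bridge$bn1, 3L, FALSE)
  r2 <- .cbr_fwd(r1$out, p$bridge$W2, p$bridge$b2, p$bridge$bn2, bn$bridge$bn2, 3L, FALSE)
  r2$out
}

#' Decoder forward pass
#'
#' Four blocks of 2x2 stride-2 transposed convolution, concatenation with the
#' matching encoder skip, and two 3x3 conv + BN + ReLU layers; restores the
#' input side.
#' @param bridge Bridge feature map.
#' @param skips Encoder skip list (level 1 first).
#' @param model A `unet_model`.
#' @return The decoder output feature map (last decoder width channels).
#' @export
decoder_forward <- function(bridge, skips, model) {
  p <- model$params; bn <- model$bn
  nl <- length(model$config$encoder_filters)
  cur <- as_fm4(bridge)
  for (l in seq_len(nl)) {
    dpb <- p$dec[[l]]; s <- bn$dec[[l]]
    up <- tconv2d_fwd(cur, dpb$Wu, dpb$bu, 2L, 2L, 0L)
    bnu <- bn_fwd(up, dpb$bnu$gamma, dpb$bnu$beta, s$bnu$mean, s$bnu$var, FALSE)
    au <- relu_fwd(bnu$out)
    skip <- as_fm4(skips[[nl - l + 1L]])
    dd <- dim(au)
    if (!all(dim(skip) == dd))
      stop("decoder_forward: skip dimensions do not match upsampled map")
    cat4 <- array(0, c(2L * dd[1], dd[2], dd[3], dd[4]))
    cat4[1:dd[1], , , ] <- au
    cat4[(dd[1] + 1L):(2L * dd[1]), , , ] <- skip
    r1 <- .cbr_fwd(cat4, dpb$W1, dpb$b1, dpb$bn1, s$bn1, 3L, FALSE)
    r2 <- .cbr_fwd(r1$out, dpb$W2, dpb$b2, dpb$bn2, s$bn2, 3L, FALSE)
    cur <- r2$out
  }
  cur
}

#' Classification head
#'
#' Flatten, dropout (0.3, training only), dense layer with LeakyReLU, dense
#' output layer, softmax over the five grades.
#'
#' @param decoder_out Decoder feature map `(C, S, S)`.
#' @param model A `unet_model` (its `head` parameters are used).
#' @param training Apply dropout.
#' @param seed Optional seed for the dropout mask.
#' @return A `classifier_output`: `logits`, `probs` (length-5, sums to 1),
#'   `predicted` (grade 0-4).
#' @export
classify_head <- function(decoder_out, model, training = FALSE, seed = NULL) {
  cfg <- model$config; p <- model$params
  x <- as_fm4(decoder_out)
  d <- dim(x)
  flat <- x; dim(flat) <- c(prod(d[1:3]), d[4])
  if (!is.null(seed)) { old <- local_seed(seed); on.exit(restore_seed(old), add = TRUE) }
  hd <- dropout_fwd(flat, cfg$head_dropout, training)
  h1 <- dense_fwd(hd$out, p$head$W1, p$head$b1)
  a1 <- if (cfg$head_activation == "leaky") leaky_fwd(h1, cfg$leaky_slope)
  else relu_fwd(h1)
  logits <- dense_fwd(a1, p$head$W2, p$head$b2)
  probs <- softmax_cols(logits)
  structure(list(logits = drop(logits), probs = drop(probs),
                 predicted = unname(apply(probs, 2, which.max)) - 1L),
            class = "classifier_output")
}

#' Predicted grade from classifier output
#'
#' Argmax over the class probabilities; ties break to the lowest class index.
#' @param output A `classifier_output` or a probability vector/matrix.
#' @return Integer grade(s) in 0-4.
#' @export
predict_grade <- function(output) {
  p <- if (inherits(output, "classifier_output")) output$probs else output
  if (is.null(dim(p))) return(which.max(p) - 1L)
  unname(apply(p, 2, which.max)) - 1L
}

#' Categorical cross-entropy
#'
#' `-sum(y * log(yhat))` averaged over the batch, with probabilities floored
#' at `eps` for numerical safety.
#'
#' @param probs Matrix of predicted probabilities, one row per sample.
#' @param labels One-hot matrix of the same shape.
#' @param eps Probability floor (default 1e-12).
#' @return Non-negative scalar.
#' @export
cross_entropy <- function(probs, labels, eps = 1e-12) {
  probs <- as.matrix(probs); labels <- as.matrix(labels)
  if (!identical(dim(probs), dim(labels)))
    stop("cross_entropy: shape mismatch")
  if (any(labels != 0 & labels != 1) || any(abs(rowSums(labels) - 1) > 1e-9))
    stop("cross_entropy: labels must be one-hot")
  -mean(rowSums(labels * log(pmax(probs, eps))))
}

#' Train a five-grade classifier
#'
#' Minimises categorical cross-entropy with Adam; per-epoch training loss and
#' accuracy are recorded. Deterministic for a fixed seed.
#'
#' @param model `"refinenet_u"` or `"baseline_cnn"`.
#' @param dataset List with `x` (`(1, S, S, N)` array in `[-1,1]`) and `y`
#'   (integer grades 0-4); at least two classes must be present.
#' @param config For RefineNet-U a [unet_config]; for the baseline a
#'   [cnn_config]. Training options are given in `opts`.
#' @param seed Integer seed.
#' @param opts List: `epochs` (default 10), `batch` (8), `lr` (1e-4),
#'   `augment` (random dihedral flips/rotations of each training image,
#'   default FALSE; fundus discs have no preferred orientation), `verbose`
#'   (FALSE).
#' @return A `clf_model`: `kind`, `net` (parameters + BN state + config),
#'   `history` (per-epoch `loss`, `accuracy`), `seed`.
#' @export
train_classifier <- function(model = c("refinenet_u", "baseline_cnn"),
                             dataset, config = NULL, seed = 1L, opts = list()) {
  model <- match.arg(model)
  o <- utils::modifyList(list(epochs = 10L, batch = 8L, lr = 1e-4,
                              augment = FALSE, verbose = FALSE),
                         opts)
  y <- as.integer(dataset$y)
  if (length(unique(y)) < 2L)
    stop("train_classifier: dataset must contain at least two classes")
  x <- dataset$x
  n <- dim(x)[4]
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  side <- dim(x)[2]
  if (model == "refinenet_u") {
    if (is.null(config)) config <- unet_config(input_side = side)
    net <- unet_init(config)
  } else {
    if (is.null(config)) config <- cnn_config(input_side = side)
    net <- cnn_init(config)
  }
  opt <- adam_init(net$params)
  history <- data.frame(epoch = integer(0), loss = numeric(0), accuracy = numeric(0))
  for (ep in seq_len(o$epochs)) {
    ord <- sample(n)
    ep_loss <- 0; nb <- 0L; correct <- 0L
    i0 <- 1L
    while (i0 <= n) {
      idx <- ord[i0:min(i0 + o$batch - 1L, n)]
      xb <- x[, , , idx, drop = FALSE]
      if (isTRUE(o$augment)) xb <- .augment_dihedral(xb)
      yb <- y[idx] + 1L
      fw <- if (model == "refinenet_u") unet_fwd(xb, net, training = TRUE)
      else cnn_fwd(xb, net, training = TRUE)
      net$bn <- fw$bn
      ce <- softmax_ce_fwd(fw$logits, yb)
      if (!is.finite(ce$loss))
        stop(sprintf("train_classifier: non-finite loss at epoch %d", ep))
      dlogits <- softmax_ce_bwd(ce$probs, yb)
      grads <- if (model == "refinenet_u") unet_bwd(dlogits, net, fw$cache)
      else cnn_bwd(dlogits, net, fw$cache)
      st <- adam_step(net$params, grads, opt, lr = o$lr)
      net$params <- st$params
      opt <- st$state
      ep_loss <- ep_loss + ce$loss; nb <- nb + 1L
      correct <- correct + sum(apply(ce$probs, 2, which.max) == yb)
      i0 <- i0 + o$batch
    }
    history <- rbind(history, data.frame(epoch = ep, loss = ep_loss / nb,
                                         accuracy = correct / n))
    if (isTRUE(o$verbose))
      message(sprintf("epoch %d: loss %.4f, train accuracy %.3f",
                      ep, ep_loss / nb, correct / n))
  }
  structure(list(kind = model, net = net, history = history,
                 seed = as.integer(seed)),
            class = "clf_model")
}

#' Predict grades for a batch of images
#'
#' @param clf A `clf_model` from [train_classifier].
#' @param x `(1, S, S, N)` array in `[-1,1]`.
#' @param batch Forward batch size (default 16).
#' @return List with `probs` (N x 5 matrix) and `grade` (integer vector).
#' @export
predict_classifier <- function(clf, x, batch = 16L) {
  x <- as_fm4(x)
  n <- dim(x)[4]
  probs <- matrix(0, n, 5L)
  i0 <- 1L
  while (i0 <= n) {
    idx <- i0:min(i0 + batch - 1L, n)
    fw <- if (clf$kind == "refinenet_u")
      unet_fwd(x[, , , idx, drop = FALSE], clf$net, training = FALSE)
    else cnn_fwd(x[, , , idx, drop = FALSE], clf$net, training = FALSE)
    probs[idx, ] <- t(softmax_cols(fw$logits))
    i0 <- i0 + batch
  }
  colnames(probs) <- paste0("p", 0:4)
  list(probs = probs, grade = unname(apply(probs, 1, which.max)) - 1L)
}

# --- plain-CNN baseline -------------------------------------------------------

#' Baseline CNN configuration
#' @param input_side Input side divisible by 8 (three 2x poolings).
#' @param filters Stage filter counts, default `c(16, 32, 64)`.
#' @param dense_units Hidden dense width, default 64.
#' @export
cnn_config <- function(input_side = 448L, filters = c(16L, 32L, 64L),
                       dense_units = 64L) {
  input_side <- as.integer(input_side)
  if (input_side %% 8L != 0L) stop("cnn_config: input_side must be divisible by 8")
  list(input_side = input_side, filters = as.integer(filters),
       dense_units = as.integer(dense_units))
}

#' Initialise the baseline CNN
#' @param config A [cnn_config].
#' @export
cnn_init <- function(config = cnn_config()) {
  f <- config$filters
  params <- list(stages = list(), head = NULL)
  bn <- list(stages = list())
  cin <- 1L
  for (i in seq_along(f)) {
    params$stages[[i]] <- list(W = he_conv(cin, 3L, f[i]), b = rep(0, f[i]),
                               bn = bn_init(f[i]))
    bn$stages[[i]] <- list(mean = rep(0, f[i]), var = rep(1, f[i]))
    cin <- f[i]
  }
  flat <- f[length(f)] * (config$input_side %/% 8L)^2
  params$head <- list(W1 = he_dense(flat, config$dense_units),
                      b1 = rep(0, config$dense_units),
                      W2 = matrix(0, 5L, config$dense_units), b2 = rep(0, 5))
  structure(list(params = params, bn = bn, config = config), class = "cnn_model")
}

cnn_fwd <- function(x, model, training = FALSE) {
  p <- model$params; bn <- model$bn
  x <- as_fm4(x)
  cache <- list(x = x, stages = list())
  cur <- x
  for (i in seq_along(p$stages)) {
    st <- p$stages[[i]]
    c1 <- conv2d_fwd(cur, st$W, st$b, 3L)
    br <- bn_fwd(c1, st$bn$gamma, st$bn$beta, bn$stages[[i]]$mean,
                 bn$stages[[i]]$var, training)
    a <- relu_fwd(br$out)
    pl <- maxpool_fwd_r(a)
    cache$stages[[i]] <- list(in_ = cur, conv = c1, bn = br, act = a, pool = pl)
    bn$stages[[i]] <- list(mean = br$running_mean, var = br$running_var)
    cur <- pl$out
  }
  d <- dim(cur)
  flat <- cur; dim(flat) <- c(prod(d[1:3]), d[4])
  h1 <- dense_fwd(flat, p$head$W1, p$head$b1)
  a1 <- relu_fwd(h1)
  logits <- dense_fwd(a1, p$head$W2, p$head$b2)
  cache$head <- list(flat = flat, h1 = h1, a1 = a1, dim = d)
  list(logits = logits, cache = cache, bn = bn)
}

cnn_bwd <- function(dlogits, model, cache) {
  p <- model$params
  g <- list(stages = vector("list", length(p$stages)), head = list())
  b2 <- dense_bwd(dlogits, cache$head$a1, p$head$W2)
  g$head$W2 <- b2$dW; g$head$b2 <- b2$db
  da1 <- relu_bwd(b2$dx, cache$head$h1)
  b1 <- dense_bwd(da1, cache$head$flat, p$head$W1)
  g$head$W1 <- b1$dW; g$head$b1 <- b1$db
  dcur <- b1$dx; dim(dcur) <- cache$head$dim
  for (i in rev(seq_along(p$stages))) {
    cc <- cache$stages[[i]]; st <- p$stages[[i]]
    dpool <- maxpool_bwd_r(dcur, cc$pool)
    da <- relu_bwd(dpool, cc$bn$out)
    bb <- bn_bwd(da, cc$bn, st$bn$gamma)
    g$stages[[i]]$bn <- list(gamma = bb$dgamma, beta = bb$dbeta)
    cb <- conv2d_bwd(bb$dx, cc$in_, st$W, 3L)
    g$stages[[i]]$W <- cb$dW; g$stages[[i]]$b <- cb$db
    dcur <- cb$dx
  }
  g
}

#' Baseline CNN forward pass
#'
#' Three conv/BN/ReLU/pool stages followed by two dense layers and softmax.
#' @param image A [gray_image] or `(1, S, S)` array, side divisible by 8.
#' @param model A `cnn_model` from [cnn_init].
#' @return A `classifier_output` (`logits`, `probs`, `predicted`).
#' @export
baseline_cnn_forward <- function(image, model) {
  x <- if (is_gray_image(image)) array(image$pixels, c(1L, image$height, image$width))
  else image
  fw <- cnn_fwd(as_fm4(x), model, training = FALSE)
  probs <- softmax_cols(fw$logits)
  structure(list(logits = drop(fw$logits), probs = drop(probs),
                 predicted = unname(apply(probs, 2, which.max)) - 1L),
            class = "classifier_output")
}
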