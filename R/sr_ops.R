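# Numeric primitives of the hybrid local-global super-resolution block:
# 3x3 deformable convolution with learned per-position offsets/modulations,
# point-wise (1x1) convolution, the inter-pixel non-local attention block,
# the 2x2-patch transformer, and pixel shuffle. Public functions operate on
# single (C,H,W) feature maps; the *_fwd / *_bwd internals carry caches for
# training and accept (C,H,W,N) batches.

#' Base offsets of a 3x3 kernel
#'
#' The nine integer taps `(dr, dc)` of a 3x3 sampling grid, ordered so that
#' tap `k = ki + 3*kj` matches the package's im2col row ordering. A
#' deformable convolution with zero offsets and unit modulation therefore
#' shares its weight layout with a standard 3x3 convolution.
#' @return A 9x2 integer matrix.
#' @export
base_offsets_3x3 <- function() {
  cbind(rep(-1:1, times = 3), rep(-1:1, each = 3))
}

#' Deformable 3x3 convolution (single feature map)
#'
#' For every output position `r` computes
#' `sum_k alpha_k * z(r + q_k + delta_k) * gamma_k`, sampling fractional
#' positions bilinearly and reading zeros outside the raster. Spatial
#' dimensions are preserved.
#'
#' @param features `(C, H, W)` numeric array.
#' @param params List with `base_offsets` (9x2 integer matrix), `weights`
#'   (length-9 vector for a single-channel map, or a `(C*9) x C_out` matrix),
#'   `offsets` (`(18, H, W)`; channels `2k-1`/`2k` are the row/column shifts
#'   of tap `k`), `modulations` (`(9, H, W)`, values in `[0, 1]`).
#' @return `(C_out, H, W)` numeric array.
#' @export
deformable_conv <- function(features, params) {
  x <- as_fm4(features)
  d <- dim(x)
  q <- params$base_offsets
  if (is.null(q)) q <- base_offsets_3x3()
  if (nrow(q) != 9L) stop("deformable_conv: exactly 9 base offsets are required")
  W <- params$weights
  if (is.null(dim(W))) {
    if (length(W) != 9L || d[1] != 1L)
      stop("deformable_conv: vector weights require length 9 and a 1-channel map")
    W <- matrix(W, 9L, 1L)
  }
  if (nrow(W) != d[1] * 9L)
    stop("deformable_conv: weights must have C*9 rows")
  off <- params$offsets
  mod <- params$modulations
  if (!all(is.finite(off))) stop("deformable_conv: non-finite offsets")
  if (any(mod < 0 | mod > 1)) stop("deformable_conv: modulations must lie in [0, 1]")
  dim(off) <- c(18L, d[2], d[3], d[4])
  dim(mod) <- c(9L, d[2], d[3], d[4])
  cols <- .deform_im2col(x, off, mod, matrix(as.integer(q), 9L, 2L))
  out <- crossprod(W, cols)
  dim(out) <- c(ncol(W), d[2], d[3], d[4])
  fm_drop(out)
}

#' Predict deformable-convolution offsets and modulations
#'
#' The predictor is a standard 3x3 convolution over the input emitting 18
#' offset channels and 9 modulation channels; modulations pass through a
#' sigmoid. With zero-initialised predictor weights the offsets are all zero
#' and the modulations all 0.5, so training starts from a plain convolution.
#'
#' @param features `(C, H, W)` numeric array.
#' @param predictor_params List with `W` (`(C*9) x 27` matrix) and `b`
#'   (length 27).
#' @return List with `offsets` (`(18, H, W)`) and `modulations` (`(9, H, W)`).
#' @export
learn_offsets <- function(features, predictor_params) {
  x <- as_fm4(features)
  if (ncol(predictor_params$W) != 27L)
    stop("learn_offsets: predictor must emit 27 channels (18 offsets + 9 modulations)")
  pred <- conv2d_fwd(x, predictor_params$W, predictor_params$b, 3L)
  d <- dim(pred)
  list(offsets = fm_drop(pred[1:18, , , , drop = FALSE]),
       modulations = fm_drop(array(sigmoid(pred[19:27, , , , drop = FALSE]),
                                   c(9L, d[2], d[3], d[4]))))
}

#' Point-wise (1x1) convolution
#'
#' A per-pixel linear map across channels; spatial dimensions unchanged.
#'
#' @param features `(C_in, H, W)` numeric array.
#' @param weights `C_out x C_in` matrix.
#' @param bias Optional length-`C_out` bias (default 0).
#' @return `(C_out, H, W)` numeric array.
#' @export
pointwise_conv <- function(features, weights, bias = NULL) {
  x <- as_fm4(features)
  d <- dim(x)
  if (ncol(weights) != d[1])
    stop("pointwise_conv: weight columns must equal input channels")
  xm <- x; dim(xm) <- c(d[1], prod(d[2:4]))
  out <- weights %*% xm
  if (!is.null(bias)) out <- out + bias
  dim(out) <- c(nrow(weights), d[2], d[3], d[4])
  fm_drop(out)
}

# --- non-local (inter-pixel) attention ---------------------------------------

#' Non-local block configuration
#' @param embed_channels Embedding width of the pairwise/unary 1x1 maps;
#'   default `C/2` chosen at parameter creation.
#' @param residual Add the block input to the attention output (default TRUE).
#' @export
nonlocal_config <- function(embed_channels = NULL, residual = TRUE) {
  list(embed_channels = embed_channels, residual = residual)
}

#' Initialise non-local block parameters
#' @param C Input channels.
#' @param embed Embedding channels (default `C/2`, at least 1).
#' @export
nonlocal_params_init <- function(C, embed = max(1L, C %/% 2L)) {
  list(theta = xavier_mat(C, embed), phi = xavier_mat(C, embed),
       g = xavier_mat(C, embed), z = xavier_mat(embed, C))
}

# forward over a batch; per-image attention. When training, the full P x P
# affinity matrix is cached for the backward pass; otherwise queries are
# processed in row chunks to bound memory on large maps.
nl_fwd <- function(x, params, residual = TRUE, training = FALSE,
                   chunk = 2048L) {
  x <- as_fm4(x)
  d <- dim(x)
  P <- d[2] * d[3]
  out <- x * 0
  caches <- if (training) vector("list", d[4]) else NULL
  for (n in seq_len(d[4])) {
    X <- x[, , , n]; dim(X) <- c(d[1], P)
    Th <- crossprod(params$theta, X)   # Ce x P
    Ph <- crossprod(params$phi, X)
    G  <- crossprod(params$g, X)
    if (training) {
      # affinity with queries as columns: S[j, i] = phi(x_j) . theta(x_i)
      A <- .softmax_cols_cpp(crossprod(Ph, Th))
      Y <- G %*% A                     # Ce x P
      caches[[n]] <- list(X = X, Th = Th, Ph = Ph, G = G, A = A, Y = Y)
    } else {
      Y <- matrix(0, nrow(G), P)
      i0 <- 1L
      while (i0 <= P) {
        i1 <- min(i0 + chunk - 1L, P)
        A <- .softmax_cols_cpp(crossprod(Ph, Th[, i0:i1, drop = FALSE]))
        Y[, i0:i1] <- G %*% A
        i0 <- i1 + 1L
      }
    }
    O <- crossprod(params$z, Y)        # C x P
    dim(O) <- c(d[1], d[2], d[3])
    out[, , , n] <- O
  }
  if (residual) out <- out + x
  list(out = out, caches = caches)
}

nl_bwd <- function(dout, x, params, caches, residual = TRUE) {
  x <- as_fm4(x); dout <- as_fm4(dout)
  d <- dim(x)
  P <- d[2] * d[3]
  dx <- x * 0
  g <- list(theta = params$theta * 0, phi = params$phi * 0,
            g = params$g * 0, z = params$z * 0)
  for (n in seq_len(d[4])) {
    cc <- caches[[n]]
    dO <- dout[, , , n]; dim(dO) <- c(d[1], P)
    g$z <- g$z + tcrossprod(cc$Y, dO)
    dY <- params$z %*% dO              # Ce x P
    dG <- tcrossprod(dY, cc$A)         # Ce x P
    dA <- crossprod(cc$G, dY)          # P x P (columns = queries)
    dS <- .softmax_cols_bwd_cpp(cc$A, dA)
    dTh <- cc$Ph %*% dS                # Ce x P
    dPh <- tcrossprod(cc$Th, dS)
    dX <- params$theta %*% dTh + params$phi %*% dPh + params$g %*% dG
    g$theta <- g$theta + tcrossprod(cc$X, dTh)
    g$phi <- g$phi + tcrossprod(cc$X, dPh)
    g$g <- g$g + tcrossprod(cc$X, dG)
    if (residual) dX <- dX + dO
    dim(dX) <- c(d[1], d[2], d[3])
    dx[, , , n] <- dX
  }
  list(dx = dx, grads = g)
}

#' Non-local (inter-pixel attention) block
#'
#' Embedded-Gaussian instantiation: the affinity between pixels i and j is
#' `exp(theta(x_i)' phi(x_j))`, normalised per query by a row softmax, applied
#' to value embeddings `g(x_j)` and projected back to `C` channels; a residual
#' addition of the input follows (toggleable).
#'
#' @param features `(C, H, W)` numeric array.
#' @param config A [nonlocal_config] list.
#' @param params Parameters from [nonlocal_params_init] (matrices `theta`,
#'   `phi`, `g` of dim `C x Ce` and `z` of dim `Ce x C`).
#' @return `(C, H, W)` numeric array.
#' @export
nonlocal_block <- function(features, config = nonlocal_config(), params) {
  res <- nl_fwd(as_fm4(features), params,
                residual = isTRUE(config$residual), training = FALSE)
  fm_drop(res$out)
}

# --- patch sequence and transformer ------------------------------------------

#' Split a feature map into a 2x2 (or p x p) patch sequence
#'
#' Patches are ordered row-major over the patch grid; each token flattens its
#' patch channels-then-rows-then-columns.
#'
#' @param features `(C, H, W)` array with `H`, `W` divisible by `patch_side`.
#' @param patch_side Patch size `p` (default 2, preserving fine detail).
#' @return A `patch_sequence`: list with `tokens` (`n x d` matrix,
#'   `n = (H/p)(W/p)`, `d = C p^2`), `patch_side`, `grid`, `channels`.
#' @export
patchify <- function(features, patch_side = 2L) {
  x <- features
  d <- dim(x)
  if (length(d) != 3L) stop("patchify: features must be (C, H, W)")
  p <- as.integer(patch_side)
  if (d[2] %% p != 0L || d[3] %% p != 0L)
    stop("patchify: H and W must be divisible by patch_side")
  hp <- d[2] %/% p; wp <- d[3] %/% p
  # (C, i, gr, j, gc) -> (C, i, j, gc, gr); token k = gc + wp*gr (row-major)
  y <- aperm(array(x, c(d[1], p, hp, p, wp)), c(1, 2, 4, 5, 3))
  dim(y) <- c(d[1] * p * p, wp * hp)
  structure(list(tokens = t(y), patch_side = p, grid = c(hp, wp),
                 channels = d[1]),
            class = "patch_sequence")
}

#' Reassemble a patch sequence into a feature map
#' @param seq A `patch_sequence` from [patchify].
#' @return The `(C, H, W)` array.
#' @export
unpatchify <- function(seq) {
  stopifnot(inherits(seq, "patch_sequence"))
  p <- seq$patch_side; hp <- seq$grid[1]; wp <- seq$grid[2]; C <- seq$channels
  y <- t(seq$tokens)
  dim(y) <- c(C, p, p, wp, hp)
  x <- aperm(y, c(1, 2, 5, 3, 4))
  dim(x) <- c(C, hp * p, wp * p)
  x
}

#' Initialise patch-transformer parameters
#'
#' Two pre-norm encoder layers, four heads, feed-forward expansion x2, no
#' positional encoding (the attention is content-based and permutation
#' equivariant).
#'
#' @param d Token dimension (`C * p^2`). Must be divisible by `n_heads`.
#' @param n_heads Attention heads (default 4).
#' @param n_layers Encoder layers (default 2).
#' @param ff_mult Feed-forward expansion (default 2).
#' @export
transformer_params_init <- function(d, n_heads = 4L, n_layers = 2L, ff_mult = 2L) {
  if (d %% n_heads != 0L)
    stop("transformer_params_init: token dim must be divisible by the head count")
  dff <- d * ff_mult
  layer <- function() list(
    ln1 = list(g = rep(1, d), b = rep(0, d)),
    Wq = xavier_mat(d, d), bq = rep(0, d),
    Wk = xavier_mat(d, d), bk = rep(0, d),
    Wv = xavier_mat(d, d), bv = rep(0, d),
    Wo = xavier_mat(d, d), bo = rep(0, d),
    ln2 = list(g = rep(1, d), b = rep(0, d)),
    W1 = he_dense(d, dff), b1 = rep(0, dff),
    W2 = matrix(0, d, dff), b2 = rep(0, d))  # zero-init FF output: layer starts near identity
  structure(list(layers = replicate(n_layers, layer(), simplify = FALSE),
                 n_heads = as.integer(n_heads), d = as.integer(d)),
            class = "transformer_params")
}

# layer norm over features (rows) for each token column
ln_fwd <- function(X, g, b, eps = 1e-6) {
  mu <- colMeans(X)
  xc <- sweep(X, 2, mu)
  v <- colMeans(xc * xc)
  invstd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2, invstd, "*")
  list(out = xhat * g + b, xhat = xhat, invstd = invstd)
}

ln_bwd <- function(dout, cache, g) {
  xhat <- cache$xhat
  dgamma <- rowSums(dout * xhat)
  dbeta <- rowSums(dout)
  dxhat <- dout * g
  dx <- sweep(dxhat - matrix(colMeans(dxhat), nrow(dxhat), ncol(dxhat), byrow = TRUE) -
                xhat * matrix(colMeans(dxhat * xhat), nrow(xhat), ncol(xhat), byrow = TRUE),
              2, cache$invstd, "*")
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# multi-head self-attention + FFN, tokens as columns (d x n)
tf_layer_fwd <- function(X, lp, n_heads, training = FALSE) {
  d <- nrow(X); n <- ncol(X); dh <- d %/% n_heads
  l1 <- ln_fwd(X, lp$ln1$g, lp$ln1$b)
  U <- l1$out
  Q <- lp$Wq %*% U + lp$bq; K <- lp$Wk %*% U + lp$bk; V <- lp$Wv %*% U + lp$bv
  O <- matrix(0, d, n)
  As <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    rows <- ((h - 1L) * dh + 1L):(h * dh)
    # S[j, i] = k_j . q_i / sqrt(dh): queries as columns
    S <- crossprod(K[rows, , drop = FALSE], Q[rows, , drop = FALSE]) / sqrt(dh)
    A <- .softmax_cols_cpp(S)
    O[rows, ] <- V[rows, , drop = FALSE] %*% A
    if (training) As[[h]] <- A
  }
  Z <- lp$Wo %*% O + lp$bo
  T2 <- X + Z
  l2 <- ln_fwd(T2, lp$ln2$g, lp$ln2$b)
  Hpre <- lp$W1 %*% l2$out + lp$b1
  Hact <- pmax(Hpre, 0)
  FF <- lp$W2 %*% Hact + lp$b2
  out <- T2 + FF
  cache <- if (training) list(X = X, l1 = l1, U = U, Q = Q, K = K, V = V,
                              As = As, O = O, T2 = T2, l2 = l2,
                              Hpre = Hpre, Hact = Hact) else NULL
  list(out = out, cache = cache)
}

tf_layer_bwd <- function(dout, lp, cache, n_heads) {
  d <- nrow(dout); n <- ncol(dout); dh <- d %/% n_heads
  g <- zero_like(lp)
  # FFN branch
  dFF <- dout
  g$W2 <- dFF %*% t(cache$Hact); g$b2 <- rowSums(dFF)
  dHact <- crossprod(lp$W2, dFF)
  dHpre <- dHact * (cache$Hpre > 0)
  g$W1 <- dHpre %*% t(cache$l2$out); g$b1 <- rowSums(dHpre)
  dU2 <- crossprod(lp$W1, dHpre)
  l2b <- ln_bwd(dU2, cache$l2, lp$ln2$g)
  g$ln2$g <- l2b$dgamma; g$ln2$b <- l2b$dbeta
  dT2 <- dout + l2b$dx
  # attention branch
  dZ <- dT2
  g$Wo <- dZ %*% t(cache$O); g$bo <- rowSums(dZ)
  dO <- crossprod(lp$Wo, dZ)
  dQ <- matrix(0, d, n); dK <- dQ; dV <- dQ
  for (h in seq_len(n_heads)) {
    rows <- ((h - 1L) * dh + 1L):(h * dh)
    A <- cache$As[[h]]
    dOh <- dO[rows, , drop = FALSE]
    Vh <- cache$V[rows, , drop = FALSE]
    dV[rows, ] <- tcrossprod(dOh, A)
    dA <- crossprod(Vh, dOh)
    dS <- .softmax_cols_bwd_cpp(A, dA)
    dQ[rows, ] <- cache$K[rows, , drop = FALSE] %*% dS / sqrt(dh)
    dK[rows, ] <- tcrossprod(cache$Q[rows, , drop = FALSE], dS) / sqrt(dh)
  }
  g$Wq <- dQ %*% t(cache$U); g$bq <- rowSums(dQ)
  g$Wk <- dK %*% t(cache$U); g$bk <- rowSums(dK)
  g$Wv <- dV %*% t(cache$U); g$bv <- rowSums(dV)
  dU <- crossprod(lp$Wq, dQ) + crossprod(lp$Wk, dK) + crossprod(lp$Wv, dV)
  l1b <- ln_bwd(dU, cache$l1, lp$ln1$g)
  g$ln1$g <- l1b$dgamma; g$ln1$b <- l1b$dbeta
  dX <- dT2 + l1b$dx
  list(dx = dX, grads = g)
}

tf_fwd <- function(X, params, training = FALSE) {
  caches <- vector("list", length(params$layers))
  for (i in seq_along(params$layers)) {
    r <- tf_layer_fwd(X, params$layers[[i]], params$n_heads, training)
    X <- r$out
    caches[[i]] <- r$cache
  }
  list(out = X, caches = caches)
}

tf_bwd <- function(dout, params, caches) {
  g <- vector("list", length(params$layers))
  for (i in rev(seq_along(params$layers))) {
    r <- tf_layer_bwd(dout, params$layers[[i]], caches[[i]], params$n_heads)
    dout <- r$dx
    g[[i]] <- r$grads
  }
  list(dx = dout, grads = list(layers = g))
}

#' Apply the patch transformer to a patch sequence
#'
#' Two pre-norm encoder layers with four-head self-attention and a x2
#' feed-forward expansion; token count and dimension are preserved. No
#' positional encoding is added, so permuting input tokens permutes the
#' output tokens identically.
#'
#' @param seq A `patch_sequence` from [patchify].
#' @param params A `transformer_params` object.
#' @return A `patch_sequence` with transformed tokens.
#' @export
patch_transformer <- function(seq, params) {
  stopifnot(inherits(seq, "patch_sequence"), inherits(params, "transformer_params"))
  if (ncol(seq$tokens) %% params$n_heads != 0L)
    stop("patch_transformer: token dim not divisible by head count")
  out <- tf_fwd(t(seq$tokens), params, training = FALSE)$out
  seq$tokens <- t(out)
  seq
}

# --- pixel shuffle -----------------------------------------------------------

.shuffle_index <- function(C, H, W, N, r) {
  co <- C %/% (r * r)
  rh <- H * r; rw <- W * r
  oc <- rep.int(0:(co - 1L), rh * rw * N)
  oh <- rep.int(rep(0:(rh - 1L), each = co), rw * N)
  ow <- rep.int(rep(0:(rw - 1L), each = co * rh), N)
  on <- rep(0:(N - 1L), each = co * rh * rw)
  (oc * r * r + (oh %% r) * r + (ow %% r)) +
    C * ((oh %/% r) + H * ((ow %/% r) + W * on)) + 1
}

#' Sub-pixel rearrangement (pixel shuffle)
#'
#' Rearranges `(C, H, W)` into `(C/r^2, rH, rW)`: output element `(c, h, w)`
#' equals input `(c r^2 + (h mod r) r + (w mod r), floor(h/r), floor(w/r))`.
#'
#' @param features `(C, H, W)` or `(C, H, W, N)` array with `C` divisible by
#'   `r^2`.
#' @param r Integer upscaling factor.
#' @return The upscaled array.
#' @export
pixel_shuffle <- function(features, r) {
  x <- as_fm4(features)
  d <- dim(x)
  r <- as.integer(r)
  if (d[1] %% (r * r) != 0L)
    stop("pixel_shuffle: channels must be divisible by r^2")
  idx <- .shuffle_index(d[1], d[2], d[3], d[4], r)
  out <- x[idx]
  dim(out) <- c(d[1] %/% (r * r), d[2] * r, d[3] * r, d[4])
  if (length(dim(features)) == 3L) fm_drop(out) else out
}

#' Inverse of [pixel_shuffle]
#' @param features `(C, H, W)` or `(C, H, W, N)` array with `H`, `W`
#'   divisible by `r`.
#' @param r Integer factor.
#' @export
pixel_unshuffle <- function(features, r) {
  x <- as_fm4(features)
  d <- dim(x)
  r <- as.integer(r)
  if (d[2] %% r != 0L || d[3] %% r != 0L)
    stop("pixel_unshuffle: H and W must be divisible by r")
  idx <- .shuffle_index(d[1] * r * r, d[2] %/% r, d[3] %/% r, d[4], r)
  out <- numeric(length(x))
  out[idx] <- x
  dim(out) <- c(d[1] * r * r, d[2] %/% r, d[3] %/% r, d[4])
  if (length(dim(features)) == 3L) fm_drop(out) else out
}

# pixel-shuffle backward = inverse permutation of the forward gather
pixel_shuffle_bwd <- function(dout, in_dim, r) {
  idx <- .shuffle_index(in_dim[1], in_dim[2], in_dim[3], in_dim[4], r)
  dx <- numeric(prod(in_dim))
  dx[idx] <- dout
  dim(dx) <- in_dim
  dx
}

# --- deformable convolution module with learned offsets (training path) ------

dconv_params_init <- function(C, c_out = C) {
  list(Wp = matrix(0, C * 9L, 27L), bp = rep(0, 27),
       W = he_conv(C, 3L, c_out), b = rep(0, c_out))
}

dconv_fwd <- function(x, pr, training = FALSE) {
  x <- as_fm4(x)
  d <- dim(x)
  pred <- conv2d_fwd(x, pr$Wp, pr$bp, 3L)
  off <- pred[1:18, , , , drop = FALSE]
  modp <- pred[19:27, , , , drop = FALSE]
  mod <- sigmoid(modp)
  dim(off) <- c(18L, d[2], d[3], d[4])
  dim(mod) <- c(9L, d[2], d[3], d[4])
  cols <- .deform_im2col(x, off, mod, base_offsets_3x3())
  out <- crossprod(pr$W, cols) + pr$b
  dim(out) <- c(ncol(pr$W), d[2], d[3], d[4])
  cache <- if (training) list(cols = cols, off = off, mod = mod) else NULL
  list(out = out, cache = cache)
}

dconv_bwd <- function(dout, x, pr, cache) {
  x <- as_fm4(x); dout <- as_fm4(dout)
  dd <- dim(dout); d <- dim(x)
  dmat <- dout; dim(dmat) <- c(dd[1], prod(dd[2:4]))
  g <- list(Wp = NULL, bp = NULL, W = cache$cols %*% t(dmat), b = rowSums(dmat))
  dcols <- pr$W %*% dmat
  r <- .deform_im2col_bwd(x, cache$off, cache$mod, base_offsets_3x3(), dcols)
  dmod_pre <- r$dmodulations * cache$mod * (1 - cache$mod)
  dpred <- array(0, c(27L, d[2], d[3], d[4]))
  dpred[1:18, , , ] <- r$doffsets
  dpred[19:27, , , ] <- dmod_pre
  cb <- conv2d_bwd(dpred, x, pr$Wp, 3L)
  g$Wp <- cb$dW; g$bp <- cb$db
  list(dx = r$dx + cb$dx, grads = g)
}
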