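# Internal neural-network machinery: convolution / transposed convolution
# (im2col + BLAS gemm), batch normalisation, pooling, dense layers,
# activations, dropout, and Adam. Forward functions return caches; backward
# functions consume them and return gradients shaped like the parameters.
#
# Feature maps are numeric arrays with dim (C, H, W, N). Convolution weights
# are stored as matrices (C_in * k * k) x C_out whose row order matches the
# im2col row order (channel fastest, then kernel row, then kernel column).

as_fm4 <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("feature map must be an array")
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  else if (length(d) != 4L) stop("feature map must be (C,H,W) or (C,H,W,N)")
  x
}

fm_drop <- function(x) {
  d <- dim(x)
  if (length(d) == 4L && d[4] == 1L) dim(x) <- d[1:3]
  x
}

# --- weight initialisation ---------------------------------------------------

he_conv <- function(c_in, k, c_out) {
  matrix(rnorm(c_in * k * k * c_out, sd = sqrt(2 / (c_in * k * k))),
         c_in * k * k, c_out)
}

he_dense <- function(n_in, n_out) {
  matrix(rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_out, n_in)
}

xavier_mat <- function(n_in, n_out) {
  matrix(rnorm(n_in * n_out, sd = sqrt(1 / n_in)), n_in, n_out)
}

# --- convolution -------------------------------------------------------------

conv2d_fwd <- function(x, W, b, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  x <- as_fm4(x)
  d <- dim(x)
  if (k == 1L && stride == 1L) {          # 1x1: a plain channel gemm
    xm <- x; dim(xm) <- c(d[1], prod(d[2:4]))
    out <- crossprod(W, xm) + b
    dim(out) <- c(ncol(W), d[2], d[3], d[4])
    return(out)
  }
  if (k == 3L && stride == 1L && pad == 1L)
    return(.conv3_fwd(x, W, as.numeric(b)))
  cols <- .im2col(x, k, k, stride, stride, pad, pad)
  out <- crossprod(W, cols)              # C_out x (Ho*Wo*N)
  out <- out + b
  ho <- (d[2] + 2L * pad - k) %/% stride + 1L
  wo <- (d[3] + 2L * pad - k) %/% stride + 1L
  dim(out) <- c(ncol(W), ho, wo, d[4])
  out
}

conv2d_bwd <- function(dout, x, W, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  x <- as_fm4(x); dout <- as_fm4(dout)
  d <- dim(x); dd <- dim(dout)
  if (k == 1L && stride == 1L) {
    dmat <- dout; dim(dmat) <- c(dd[1], prod(dd[2:4]))
    xm <- x; dim(xm) <- c(d[1], prod(d[2:4]))
    dx <- W %*% dmat
    dim(dx) <- d
    return(list(dx = dx, dW = tcrossprod(xm, dmat), db = rowSums(dmat)))
  }
  if (k == 3L && stride == 1L && pad == 1L) {
    r <- .conv3_bwd(x, W, dout)
    return(r)
  }
  dmat <- dout; dim(dmat) <- c(dd[1], prod(dd[2:4]))
  cols <- .im2col(x, k, k, stride, stride, pad, pad)
  dW <- cols %*% t(dmat)
  db <- rowSums(dmat)
  dcols <- W %*% dmat
  dx <- .col2im(dcols, d[1], d[2], d[3], d[4], k, k, stride, stride, pad, pad)
  list(dx = dx, dW = dW, db = db)
}

# transposed convolution; W has dim (C_out * k * k) x C_in
tconv2d_fwd <- function(x, W, b, k, stride, pad) {
  x <- as_fm4(x)
  d <- dim(x)
  c_out <- nrow(W) %/% (k * k)
  xmat <- x; dim(xmat) <- c(d[1], prod(d[2:4]))
  cols <- W %*% xmat
  ho <- (d[2] - 1L) * stride - 2L * pad + k
  wo <- (d[3] - 1L) * stride - 2L * pad + k
  out <- .col2im(cols, c_out, ho, wo, d[4], k, k, stride, stride, pad, pad)
  # channel-wise bias add (channel is the fastest dimension, so b recycles)
  out + b
}

tconv2d_bwd <- function(dout, x, W, k, stride, pad) {
  x <- as_fm4(x); dout <- as_fm4(dout)
  d <- dim(x); dd <- dim(dout)
  cols_d <- .im2col(dout, k, k, stride, stride, pad, pad)  # (C_out*k*k) x (H*W*N)
  dxmat <- crossprod(W, cols_d)                            # C_in x (H*W*N)
  dx <- dxmat; dim(dx) <- d
  xmat <- x; dim(xmat) <- c(d[1], prod(d[2:4]))
  dW <- cols_d %*% t(xmat)
  dmat <- dout; dim(dmat) <- c(dd[1], prod(dd[2:4]))
  db <- rowSums(dmat)
  list(dx = dx, dW = dW, db = db)
}

# --- batch normalisation -----------------------------------------------------

bn_fwd <- function(x, gamma, beta, running_mean, running_var,
                   training = TRUE, momentum = 0.1, eps = 1e-5) {
  x <- as_fm4(x)
  d <- dim(x)
  xm <- x; dim(xm) <- c(d[1], prod(d[2:4]))
  if (training) {
    mu <- rowMeans(xm)
    v <- rowMeans(xm * xm) - mu^2
    running_mean <- (1 - momentum) * running_mean + momentum * mu
    running_var <- (1 - momentum) * running_var + momentum * v
  } else {
    mu <- running_mean
    v <- running_var
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- (xm - mu) * invstd
  out <- gamma * xhat + beta
  dim(out) <- d
  list(out = out, xhat = xhat, invstd = invstd, training = training,
       running_mean = running_mean, running_var = running_var)
}

bn_bwd <- function(dout, cache, gamma) {
  dout <- as_fm4(dout)
  d <- dim(dout)
  dm <- dout; dim(dm) <- c(d[1], prod(d[2:4]))
  xhat <- cache$xhat
  dgamma <- rowSums(dm * xhat)
  dbeta <- rowSums(dm)
  dxhat <- dm * gamma
  # in eval mode the normalisation statistics are constants
  dx <- if (cache$training)
    cache$invstd * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  else cache$invstd * dxhat
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

bn_init <- function(C) {
  list(gamma = rep(1, C), beta = rep(0, C))
}

# --- activations -------------------------------------------------------------

relu_fwd <- function(x) pmax(x, 0)
relu_bwd <- function(dout, x) dout * (x > 0)

leaky_fwd <- function(x, a = 0.01) ifelse(x >= 0, x, a * x)
leaky_bwd <- function(dout, x, a = 0.01) dout * ifelse(x >= 0, 1, a)

sigmoid <- function(x) 1 / (1 + exp(-x))

# --- pooling -----------------------------------------------------------------

maxpool_fwd_r <- function(x, k = 2L, s = 2L) {
  x <- as_fm4(x)
  res <- .maxpool_fwd(x, k, s)
  res$in_dim <- dim(x)
  res
}

maxpool_bwd_r <- function(dout, cache) {
  .maxpool_bwd(as.numeric(dout), cache$argmax,
               cache$in_dim[1], cache$in_dim[2], cache$in_dim[3], cache$in_dim[4])
}

# --- dense layers (features x batch matrices) --------------------------------

dense_fwd <- function(x, W, b) W %*% x + b
dense_bwd <- function(dout, x, W) {
  list(dx = crossprod(W, dout), dW = tcrossprod(dout, x), db = rowSums(dout))
}

# --- softmax + cross entropy -------------------------------------------------

softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

# labels: integer vector (1-based class index per column)
softmax_ce_fwd <- function(logits, labels, eps = 1e-12) {
  p <- softmax_cols(logits)
  n <- ncol(p)
  idx <- cbind(labels, seq_len(n))
  loss <- -mean(log(pmax(p[idx], eps)))
  list(loss = loss, probs = p)
}

softmax_ce_bwd <- function(probs, labels) {
  n <- ncol(probs)
  d <- probs
  idx <- cbind(labels, seq_len(n))
  d[idx] <- d[idx] - 1
  d / n
}

# --- dropout -----------------------------------------------------------------

dropout_fwd <- function(x, p, training) {
  if (!training || p <= 0) return(list(out = x, mask = NULL))
  mask <- (runif(length(x)) >= p) / (1 - p)
  dim(mask) <- dim(x)
  list(out = x * mask, mask = mask)
}

dropout_bwd <- function(dout, mask) {
  if (is.null(mask)) dout else dout * mask
}

# --- parameter-tree utilities ------------------------------------------------

zero_like <- function(p) {
  if (is.list(p)) lapply(p, zero_like)
  else { z <- p; z[] <- 0; z }
}

tree_add <- function(a, b) {
  if (is.list(a)) mapply(tree_add, a, b, SIMPLIFY = FALSE)
  else a + b
}

tree_scale <- function(a, s) {
  if (is.list(a)) lapply(a, tree_scale, s = s)
  else a * s
}

flatten_params <- function(p, prefix = "") {
  if (!is.list(p)) return(setNames(list(p), prefix))
  out <- list()
  for (nm in names(p))
    out <- c(out, flatten_params(p[[nm]], paste0(prefix, if (nzchar(prefix)) "." else "", nm)))
  out
}

n_params <- function(p) sum(vapply(flatten_params(p), length, integer(1)))

# --- Adam --------------------------------------------------------------------

adam_init <- function(params) {
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-4,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  # recurse by NAME so gradient trees may order their fields freely
  step_rec <- function(p, g, m, v) {
    if (is.list(p)) {
      pn <- p; mn <- m; vn <- v
      for (nm in names(p)) {
        res <- step_rec(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        pn[[nm]] <- res$p; mn[[nm]] <- res$m; vn[[nm]] <- res$v
      }
      return(list(p = pn, m = mn, v = vn))
    }
    if (!is.double(p)) return(list(p = p, m = m, v = v))  # config leaves
    if (is.null(g)) stop("adam_step: missing gradient for a parameter leaf")
    # in-place update: the optimiser state and parameter tree are owned
    # exclusively by the training loop that created them
    .adam_update(p, g, m, v, lr, beta1, beta2, eps, t)
    list(p = p, m = m, v = v)
  }
  res <- step_rec(params, grads, state$m, state$v)
  list(params = res$p, state = list(m = res$m, v = res$v, t = t))
}

# numerically safe row softmax; max.col is C-level and far faster than apply
.softmax_rows <- function(S) {
  mx <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  A <- exp(S - mx)
  A / rowSums(A)
}
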