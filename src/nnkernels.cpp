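// Dense-algebra kernels for the convolutional networks.
// Feature maps are column-major R arrays with dim (C, H, W, N), so the
// linear index of (c,h,w,n) is c + C*(h + H*(w + W*n)). im2col rows are
// ordered channel-fastest, then kernel row, then kernel column:
// row = c + C*(ki + KH*kj). The deformable sampler uses the same row order
// with tap index k = ki + 3*kj, so a deformable convolution with zero
// offsets and unit modulation shares its weight layout with a standard
// 3x3 convolution.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline void get_dims4(const NumericVector& x, int d[4]) {
  IntegerVector dim = x.attr("dim");
  if (dim.size() != 4) stop("expected a 4-D (C,H,W,N) array");
  for (int i = 0; i < 4; ++i) d[i] = dim[i];
}

// [[Rcpp::export(name = ".im2col")]]
NumericMatrix im2col_cpp(NumericVector x, int kh, int kw, int sh, int sw,
                         int ph, int pw) {
  int d[4]; get_dims4(x, d);
  int C = d[0], H = d[1], W = d[2], N = d[3];
  int Ho = (H + 2 * ph - kh) / sh + 1;
  int Wo = (W + 2 * pw - kw) / sw + 1;
  if (Ho < 1 || Wo < 1) stop("kernel larger than padded input");
  int K = C * kh * kw;
  R_xlen_t M = (R_xlen_t)Ho * Wo * N;
  NumericMatrix cols(K, M);
  const double* xp = x.begin();
  double* cp = cols.begin();
  for (int n = 0; n < N; ++n)
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        R_xlen_t m = (R_xlen_t)ho + (R_xlen_t)Ho * (wo + (R_xlen_t)Wo * n);
        double* col = cp + m * K;
        for (int kj = 0; kj < kw; ++kj) {
          int w = wo * sw - pw + kj;
          for (int ki = 0; ki < kh; ++ki) {
            int h = ho * sh - ph + ki;
            double* dst = col + C * (ki + kh * kj);
            if (h < 0 || h >= H || w < 0 || w >= W) {
              for (int c = 0; c < C; ++c) dst[c] = 0.0;
            } else {
              const double* src = xp + (R_xlen_t)C * (h + (R_xlen_t)H * (w + (R_xlen_t)W * n));
              for (int c = 0; c < C; ++c) dst[c] = src[c];
            }
          }
        }
      }
  return cols;
}

// adjoint of im2col: scatter-add columns back into an input-shaped array
// [[Rcpp::export(name = ".col2im")]]
NumericVector col2im_cpp(NumericMatrix cols, int C, int H, int W, int N,
                         int kh, int kw, int sh, int sw, int ph, int pw) {
  int Ho = (H + 2 * ph - kh) / sh + 1;
  int Wo = (W + 2 * pw - kw) / sw + 1;
  if ((R_xlen_t)Ho * Wo * N != cols.ncol() || C * kh * kw != cols.nrow())
    stop("col2im: geometry mismatch");
  NumericVector x((R_xlen_t)C * H * W * N);
  double* xp = x.begin();
  const double* cp = cols.begin();
  int K = C * kh * kw;
  for (int n = 0; n < N; ++n)
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        R_xlen_t m = (R_xlen_t)ho + (R_xlen_t)Ho * (wo + (R_xlen_t)Wo * n);
        const double* col = cp + m * K;
        for (int kj = 0; kj < kw; ++kj) {
          int w = wo * sw - pw + kj;
          if (w < 0 || w >= W) continue;
          for (int ki = 0; ki < kh; ++ki) {
            int h = ho * sh - ph + ki;
            if (h < 0 || h >= H) continue;
            const double* src = col + C * (ki + kh * kj);
            double* dst = xp + (R_xlen_t)C * (h + (R_xlen_t)H * (w + (R_xlen_t)W * n));
            for (int c = 0; c < C; ++c) dst[c] += src[c];
          }
        }
      }
  x.attr("dim") = IntegerVector::create(C, H, W, N);
  return x;
}

// [[Rcpp::export(name = ".maxpool_fwd")]]
List maxpool_fwd_cpp(NumericVector x, int k, int s) {
  int d[4]; get_dims4(x, d);
  int C = d[0], H = d[1], W = d[2], N = d[3];
  int Ho = (H - k) / s + 1, Wo = (W - k) / s + 1;
  NumericVector out((R_xlen_t)C * Ho * Wo * N);
  IntegerVector arg((R_xlen_t)C * Ho * Wo * N);
  const double* xp = x.begin();
  double* op = out.begin();
  int* ap = arg.begin();
  for (int n = 0; n < N; ++n)
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho)
        for (int c = 0; c < C; ++c) {
          double best = R_NegInf; R_xlen_t besti = -1;
          for (int kj = 0; kj < k; ++kj)
            for (int ki = 0; ki < k; ++ki) {
              int h = ho * s + ki, w = wo * s + kj;
              R_xlen_t idx = c + (R_xlen_t)C * (h + (R_xlen_t)H * (w + (R_xlen_t)W * n));
              if (xp[idx] > best) { best = xp[idx]; besti = idx; }
            }
          R_xlen_t o = c + (R_xlen_t)C * (ho + (R_xlen_t)Ho * (wo + (R_xlen_t)Wo * n));
          op[o] = best;
          ap[o] = (int)besti;
        }
  out.attr("dim") = IntegerVector::create(C, Ho, Wo, N);
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export(name = ".maxpool_bwd")]]
NumericVector maxpool_bwd_cpp(NumericVector dout, IntegerVector argmax,
                              int C, int H, int W, int N) {
  NumericVector dx((R_xlen_t)C * H * W * N);
  double* dp = dx.begin();
  const double* gp = dout.begin();
  const int* ap = argmax.begin();
  R_xlen_t M = dout.size();
  for (R_xlen_t i = 0; i < M; ++i) dp[ap[i]] += gp[i];
  dx.attr("dim") = IntegerVector::create(C, H, W, N);
  return dx;
}

static inline double bilin_sample(const double* plane, int H, int W, int C,
                                  int c, double hs, double ws) {
  // plane points at the (n-th image) base; reads outside the raster are 0
  if (hs <= -1.0 || hs >= (double)H || ws <= -1.0 || ws >= (double)W) return 0.0;
  int h0 = (int)std::floor(hs), w0 = (int)std::floor(ws);
  double ah = hs - h0, aw = ws - w0;
  double v = 0.0;
  for (int dh = 0; dh < 2; ++dh)
    for (int dw = 0; dw < 2; ++dw) {
      int h = h0 + dh, w = w0 + dw;
      if (h < 0 || h >= H || w < 0 || w >= W) continue;
      double wgt = (dh ? ah : 1.0 - ah) * (dw ? aw : 1.0 - aw);
      v += wgt * plane[c + (R_xlen_t)C * (h + (R_xlen_t)H * w)];
    }
  return v;
}

// Build the sampled-column matrix for a 3x3 deformable convolution:
// row (c + C*k) of column m holds gamma_k * z(r + q_k + delta_k) for
// position r = (h,w) of image n, sampled bilinearly with zeros outside.
// offsets: (18,H,W,N), channel 2k = row shift, 2k+1 = column shift;
// modulations: (9,H,W,N); base: 9x2 integer matrix of (dr,dc).
// [[Rcpp::export(name = ".deform_im2col")]]
NumericMatrix deform_im2col_cpp(NumericVector x, NumericVector offsets,
                                NumericVector modulations, IntegerMatrix base) {
  int d[4]; get_dims4(x, d);
  int C = d[0], H = d[1], W = d[2], N = d[3];
  if (base.nrow() != 9 || base.ncol() != 2) stop("base offsets must be 9x2");
  const double* xp = x.begin();
  const double* op = offsets.begin();
  const double* mp = modulations.begin();
  R_xlen_t M = (R_xlen_t)H * W * N;
  NumericMatrix cols(C * 9, M);
  double* cp = cols.begin();
  for (int n = 0; n < N; ++n) {
    const double* img = xp + (R_xlen_t)C * H * W * n;
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        R_xlen_t m = (R_xlen_t)h + (R_xlen_t)H * (w + (R_xlen_t)W * n);
        R_xlen_t pix = (R_xlen_t)h + (R_xlen_t)H * (w + (R_xlen_t)W * n);
        double* col = cp + m * (R_xlen_t)(C * 9);
        for (int k = 0; k < 9; ++k) {
          double dr = op[2 * k + 18 * pix];
          double dc = op[2 * k + 1 + 18 * pix];
          double g = mp[k + 9 * pix];
          double hs = h + base(k, 0) + dr;
          double ws = w + base(k, 1) + dc;
          for (int c = 0; c < C; ++c)
            col[c + C * k] = g * bilin_sample(img, H, W, C, c, hs, ws);
        }
      }
  }
  return cols;
}

// Backward of deform_im2col: given the gradient w.r.t. the sampled columns,
// accumulate gradients for the input, the offsets and the modulations.
// [[Rcpp::export(name = ".deform_im2col_bwd")]]
List deform_im2col_bwd_cpp(NumericVector x, NumericVector offsets,
                           NumericVector modulations, IntegerMatrix base,
                           NumericMatrix dcols) {
  int d[4]; get_dims4(x, d);
  int C = d[0], H = d[1], W = d[2], N = d[3];
  const double* xp = x.begin();
  const double* op = offsets.begin();
  const double* mp = modulations.begin();
  const double* gp = dcols.begin();
  NumericVector dx((R_xlen_t)C * H * W * N);
  NumericVector doff((R_xlen_t)18 * H * W * N);
  NumericVector dmod((R_xlen_t)9 * H * W * N);
  double* dxp = dx.begin();
  double* dop = doff.begin();
  double* dmp = dmod.begin();
  for (int n = 0; n < N; ++n) {
    const double* img = xp + (R_xlen_t)C * H * W * n;
    double* dimg = dxp + (R_xlen_t)C * H * W * n;
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        R_xlen_t pix = (R_xlen_t)h + (R_xlen_t)H * (w + (R_xlen_t)W * n);
        const double* gcol = gp + pix * (R_xlen_t)(C * 9);
        for (int k = 0; k < 9; ++k) {
          double dr = op[2 * k + 18 * pix];
          double dc = op[2 * k + 1 + 18 * pix];
          double g = mp[k + 9 * pix];
          double hs = h + base(k, 0) + dr;
          double ws = w + base(k, 1) + dc;
          double acc_mod = 0.0, acc_dh = 0.0, acc_dw = 0.0;
          bool inside = (hs > -1.0 && hs < (double)H && ws > -1.0 && ws < (double)W);
          int h0 = 0, w0 = 0; double ah = 0.0, aw = 0.0;
          if (inside) {
            h0 = (int)std::floor(hs); w0 = (int)std::floor(ws);
            ah = hs - h0; aw = ws - w0;
          }
          for (int c = 0; c < C; ++c) {
            double gk = gcol[c + C * k];
            if (!inside) continue;
            double v00 = 0, v01 = 0, v10 = 0, v11 = 0;
            if (h0 >= 0 && h0 < H && w0 >= 0 && w0 < W)
              v00 = img[c + (R_xlen_t)C * (h0 + (R_xlen_t)H * w0)];
            if (h0 >= 0 && h0 < H && w0 + 1 >= 0 && w0 + 1 < W)
              v01 = img[c + (R_xlen_t)C * (h0 + (R_xlen_t)H * (w0 + 1))];
            if (h0 + 1 >= 0 && h0 + 1 < H && w0 >= 0 && w0 < W)
              v10 = img[c + (R_xlen_t)C * (h0 + 1 + (R_xlen_t)H * w0)];
            if (h0 + 1 >= 0 && h0 + 1 < H && w0 + 1 >= 0 && w0 + 1 < W)
              v11 = img[c + (R_xlen_t)C * (h0 + 1 + (R_xlen_t)H * (w0 + 1))];
            double samp = (1 - ah) * (1 - aw) * v00 + (1 - ah) * aw * v01 +
                          ah * (1 - aw) * v10 + ah * aw * v11;
            acc_mod += gk * samp;
            double gs = gk * g;  // gradient w.r.t. the raw sample
            acc_dh += gs * ((1 - aw) * (v10 - v00) + aw * (v11 - v01));
            acc_dw += gs * ((1 - ah) * (v01 - v00) + ah * (v11 - v10));
            // scatter into dx
            if (h0 >= 0 && h0 < H && w0 >= 0 && w0 < W)
              dimg[c + (R_xlen_t)C * (h0 + (R_xlen_t)H * w0)] += gs * (1 - ah) * (1 - aw);
            if (h0 >= 0 && h0 < H && w0 + 1 >= 0 && w0 + 1 < W)
              dimg[c + (R_xlen_t)C * (h0 + (R_xlen_t)H * (w0 + 1))] += gs * (1 - ah) * aw;
            if (h0 + 1 >= 0 && h0 + 1 < H && w0 >= 0 && w0 < W)
              dimg[c + (R_xlen_t)C * (h0 + 1 + (R_xlen_t)H * w0)] += gs * ah * (1 - aw);
            if (h0 + 1 >= 0 && h0 + 1 < H && w0 + 1 >= 0 && w0 + 1 < W)
              dimg[c + (R_xlen_t)C * (h0 + 1 + (R_xlen_t)H * (w0 + 1))] += gs * ah * aw;
          }
          dmp[k + 9 * pix] += acc_mod;
          dop[2 * k + 18 * pix] += acc_dh;
          dop[2 * k + 1 + 18 * pix] += acc_dw;
        }
      }
  }
  dx.attr("dim") = IntegerVector::create(C, H, W, N);
  doff.attr("dim") = IntegerVector::create(18, H, W, N);
  dmod.attr("dim") = IntegerVector::create(9, H, W, N);
  return List::create(_["dx"] = dx, _["doffsets"] = doff, _["dmodulations"] = dmod);
}

// column-wise softmax (queries as columns): one pass, no temporaries
// [[Rcpp::export(name = ".softmax_cols_cpp")]]
NumericMatrix softmax_cols_cpp(NumericMatrix S) {
  int P = S.nrow(), M = S.ncol();
  NumericMatrix A(P, M);
  for (int j = 0; j < M; ++j) {
    const double* s = &S(0, j);
    double* a = &A(0, j);
    double mx = s[0];
    for (int i = 1; i < P; ++i) if (s[i] > mx) mx = s[i];
    double sum = 0.0;
    for (int i = 0; i < P; ++i) { a[i] = std::exp(s[i] - mx); sum += a[i]; }
    double inv = 1.0 / sum;
    for (int i = 0; i < P; ++i) a[i] *= inv;
  }
  return A;
}

// backward of column-wise softmax: dS = A * (dA - colsum(dA * A))
// [[Rcpp::export(name = ".softmax_cols_bwd_cpp")]]
NumericMatrix softmax_cols_bwd_cpp(NumericMatrix A, NumericMatrix dA) {
  int P = A.nrow(), M = A.ncol();
  NumericMatrix dS(P, M);
  for (int j = 0; j < M; ++j) {
    const double* a = &A(0, j);
    const double* g = &dA(0, j);
    double* o = &dS(0, j);
    double dot = 0.0;
    for (int i = 0; i < P; ++i) dot += a[i] * g[i];
    for (int i = 0; i < P; ++i) o[i] = a[i] * (g[i] - dot);
  }
  return dS;
}

// Fused Adam update, in place: the training loops hold the only live
// references to their parameter/moment vectors, so mutating them avoids
// three parameter-sized allocations per step (significant when the dense
// head holds tens of millions of weights).
// [[Rcpp::export(name = ".adam_update")]]
void adam_update_cpp(NumericVector p, NumericVector g, NumericVector m,
                     NumericVector v, double lr, double b1, double b2,
                     double eps, int t) {
  R_xlen_t n = p.size();
  double c1 = 1.0 - std::pow(b1, (double)t);
  double c2 = 1.0 - std::pow(b2, (double)t);
  double* pp = p.begin(); const double* gp = g.begin();
  double* mp = m.begin(); double* vp = v.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    double mi = b1 * mp[i] + (1.0 - b1) * gp[i];
    double vi = b2 * vp[i] + (1.0 - b2) * gp[i] * gp[i];
    mp[i] = mi; vp[i] = vi;
    pp[i] -= lr * (mi / c1) / (std::sqrt(vi / c2) + eps);
  }
}

#include <R_ext/BLAS.h>

// Direct 3x3 stride-1 pad-1 convolution: pad once, then one large dgemm per
// kernel tap against a shifted contiguous slice of the padded array (the
// pad ring absorbs the shifts; ring outputs are discarded on extraction).
// Roughly an order of magnitude less memory traffic than im2col.
static void pad_chwn(const double* x, double* xp, int C, int H, int W, int N,
                     R_xlen_t slack) {
  int Hp = H + 2, Wp = W + 2;
  R_xlen_t total = (R_xlen_t)C * ((R_xlen_t)Hp * Wp * N + slack);
  std::memset(xp, 0, total * sizeof(double));
  for (int n = 0; n < N; ++n)
    for (int w = 0; w < W; ++w) {
      const double* src = x + (R_xlen_t)C * (0 + (R_xlen_t)H * (w + (R_xlen_t)W * n));
      double* dst = xp + (R_xlen_t)C * (1 + (R_xlen_t)Hp * (w + 1 + (R_xlen_t)Wp * n));
      std::memcpy(dst, src, (size_t)C * H * sizeof(double));
    }
}

// [[Rcpp::export(name = ".conv3_fwd")]]
NumericVector conv3_fwd_cpp(NumericVector x, NumericMatrix Wm, NumericVector b) {
  int d[4]; get_dims4(x, d);
  int C = d[0], H = d[1], W = d[2], N = d[3];
  int Co = Wm.ncol();
  if (Wm.nrow() != C * 9) stop("conv3_fwd: weight rows must be C*9");
  int Hp = H + 2, Wp = W + 2;
  R_xlen_t J = (R_xlen_t)Hp * Wp * N;
  R_xlen_t slack = 2 * Hp + 4;
  std::vector<double> xpad((R_xlen_t)C * (J + slack));
  pad_chwn(x.begin(), xpad.data(), C, H, W, N, slack);
  std::vector<double> outf((R_xlen_t)Co * J, 0.0);
  const double one = 1.0;
  int Jt = (int)J;  // dims fit int for our problem sizes
  int K9 = C * 9;
  for (int k = 0; k < 9; ++k) {
    int ki = k % 3, kj = k / 3;
    R_xlen_t off = ki + (R_xlen_t)Hp * kj;
    F77_CALL(dgemm)("T", "N", &Co, &Jt, &C, &one,
                    Wm.begin() + (R_xlen_t)C * k, &K9,
                    xpad.data() + (R_xlen_t)C * off, &C, &one,
                    outf.data(), &Co FCONE FCONE);
  }
  // with nonnegative tap offsets the valid output block sits at padded
  // position (h, w), not (h+1, w+1)
  NumericVector out((R_xlen_t)Co * H * W * N);
  double* op = out.begin();
  for (int n = 0; n < N; ++n)
    for (int w = 0; w < W; ++w) {
      const double* src = outf.data() + (R_xlen_t)Co * (0 + (R_xlen_t)Hp * (w + (R_xlen_t)Wp * n));
      double* dst = op + (R_xlen_t)Co * (0 + (R_xlen_t)H * (w + (R_xlen_t)W * n));
      std::memcpy(dst, src, (size_t)Co * H * sizeof(double));
    }
  if (b.size() == Co) {
    R_xlen_t M = (R_xlen_t)H * W * N;
    for (R_xlen_t m = 0; m < M; ++m)
      for (int c = 0; c < Co; ++c) op[c + (R_xlen_t)Co * m] += b[c];
  }
  out.attr("dim") = IntegerVector::create(Co, H, W, N);
  return out;
}

// [[Rcpp::export(name = ".conv3_bwd")]]
List conv3_bwd_cpp(NumericVector x, NumericMatrix Wm, NumericVector dout) {
  int d[4]; get_dims4(x, d);
  int C = d[0], H = d[1], W = d[2], N = d[3];
  int Co = Wm.ncol();
  int Hp = H + 2, Wp = W + 2;
  R_xlen_t J = (R_xlen_t)Hp * Wp * N;
  R_xlen_t slack = 2 * Hp + 4;
  // padded input (for dW) and padded dout (ring zeros keep sums valid)
  std::vector<double> xpad((R_xlen_t)C * (J + slack));
  pad_chwn(x.begin(), xpad.data(), C, H, W, N, slack);
  std::vector<double> dof((R_xlen_t)Co * J, 0.0);
  const double* dp = dout.begin();
  // mirror of the forward extraction: the gradient block sits at (h, w)
  for (int n = 0; n < N; ++n)
    for (int w = 0; w < W; ++w) {
      const double* src = dp + (R_xlen_t)Co * (0 + (R_xlen_t)H * (w + (R_xlen_t)W * n));
      double* dst = dof.data() + (R_xlen_t)Co * (0 + (R_xlen_t)Hp * (w + (R_xlen_t)Wp * n));
      std::memcpy(dst, src, (size_t)Co * H * sizeof(double));
    }
  std::vector<double> dxpad((R_xlen_t)C * (J + slack), 0.0);
  NumericMatrix dW(C * 9, Co);
  const double one = 1.0;
  int Jt = (int)J;
  int K9 = C * 9;
  for (int k = 0; k < 9; ++k) {
    int ki = k % 3, kj = k / 3;
    R_xlen_t off = ki + (R_xlen_t)Hp * kj;
    // dxpad[:, off + j] += W_tap %*% dout_full[:, j]
    F77_CALL(dgemm)("N", "N", &C, &Jt, &Co, &one,
                    Wm.begin() + (R_xlen_t)C * k, &K9,
                    dof.data(), &Co, &one,
                    dxpad.data() + (R_xlen_t)C * off, &C FCONE FCONE);
    // dW_tap += xpad[:, off:off+J] %*% t(dout_full)
    F77_CALL(dgemm)("N", "T", &C, &Co, &Jt, &one,
                    xpad.data() + (R_xlen_t)C * off, &C,
                    dof.data(), &Co, &one,
                    dW.begin() + (R_xlen_t)C * k, &K9 FCONE FCONE);
  }
  NumericVector dx((R_xlen_t)C * H * W * N);
  double* dxo = dx.begin();
  for (int n = 0; n < N; ++n)
    for (int w = 0; w < W; ++w) {
      const double* src = dxpad.data() + (R_xlen_t)C * (1 + (R_xlen_t)Hp * (w + 1 + (R_xlen_t)Wp * n));
      double* dst = dxo + (R_xlen_t)C * (0 + (R_xlen_t)H * (w + (R_xlen_t)W * n));
      std::memcpy(dst, src, (size_t)C * H * sizeof(double));
    }
  NumericVector db(Co);
  R_xlen_t M = (R_xlen_t)H * W * N;
  for (R_xlen_t m = 0; m < M; ++m)
    for (int c = 0; c < Co; ++c) db[c] += dp[c + (R_xlen_t)Co * m];
  dx.attr("dim") = IntegerVector::create(C, H, W, N);
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

#ifdef __GLIBC__
#include <malloc.h>
#endif

// Large feature maps and parameter blocks are allocated and freed every
// training step. glibc's default mmap/trim thresholds hand such blocks back
// to the kernel immediately, so every step pays the page-fault cost again
// (crippling inside lightweight VMs). Keeping blocks in the arena makes the
// allocations cheap after warm-up.
// [[Rcpp::init]]
void retinasr_tune_allocator(DllInfo* dll) {
#ifdef __GLIBC__
  mallopt(M_MMAP_THRESHOLD, 128 << 20);
  mallopt(M_TRIM_THRESHOLD, 128 << 20);
#endif
}
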