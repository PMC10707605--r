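// Low-level numerical kernels for the convolutional autoencoder.
//
// All image batches use the R array layout (H, W, C, N), column-major:
//   x[h + H*(w + W*(c + C*n))]
// Convolution weights are (kh, kw, C_in, C_out); transposed-convolution
// weights are (kh, kw, C_out, C_in).  Forward passes are implemented with
// im2col + GEMM; backward passes reuse the same gather/scatter maps, so
// each adjoint is exact (machine precision) with respect to its forward.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_size_conv(int in, int k, int s, int p) {
  return (in + 2 * p - k) / s + 1;
}

// Gather im2col matrix: K = kh*kw*Cin rows, R = Ho*Wo*N columns.
// Column r = ho + Ho*(wo + Wo*n); row k = dh + kh*(dw + kw*ci).
static arma::mat im2col(const double* x, int H, int W, int C, int N,
                        int kh, int kw, int s, int p, int Ho, int Wo) {
  const int K = kh * kw * C;
  const arma::uword R = (arma::uword)Ho * Wo * N;
  arma::mat col(K, R, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const arma::uword r = (arma::uword)ho + (arma::uword)Ho * (wo + (arma::uword)Wo * n);
        double* colptr = col.colptr(r);
        for (int ci = 0; ci < C; ++ci) {
          const double* xc = x + (size_t)H * W * (ci + (size_t)C * n);
          for (int dw = 0; dw < kw; ++dw) {
            const int wi = wo * s - p + dw;
            const bool w_ok = (wi >= 0 && wi < W);
            for (int dh = 0; dh < kh; ++dh) {
              const int hi = ho * s - p + dh;
              double v = 0.0;
              if (w_ok && hi >= 0 && hi < H) v = xc[hi + (size_t)H * wi];
              colptr[dh + kh * (dw + kw * ci)] = v;
            }
          }
        }
      }
    }
  }
  return col;
}

// Adjoint of im2col: scatter-add columns back into an (H,W,C,N) array.
static void col2im_add(double* dx, const arma::mat& col,
                       int H, int W, int C, int N,
                       int kh, int kw, int s, int p, int Ho, int Wo) {
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const arma::uword r = (arma::uword)ho + (arma::uword)Ho * (wo + (arma::uword)Wo * n);
        const double* colptr = col.colptr(r);
        for (int ci = 0; ci < C; ++ci) {
          double* xc = dx + (size_t)H * W * (ci + (size_t)C * n);
          for (int dw = 0; dw < kw; ++dw) {
            const int wi = wo * s - p + dw;
            if (wi < 0 || wi >= W) continue;
            for (int dh = 0; dh < kh; ++dh) {
              const int hi = ho * s - p + dh;
              if (hi < 0 || hi >= H) continue;
              xc[hi + (size_t)H * wi] += colptr[dh + kh * (dw + kw * ci)];
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                             int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Ci = wd[2], Co = wd[3];
  if (Ci != C) stop("conv2d: input has %d channels, weights expect %d", C, Ci);
  const int Ho = out_size_conv(H, kh, stride, pad);
  const int Wo = out_size_conv(W, kw, stride, pad);
  if (Ho < 1 || Wo < 1) stop("conv2d: output would be empty");

  arma::mat col = im2col(x.begin(), H, W, C, N, kh, kw, stride, pad, Ho, Wo);
  const arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * C, Co, false, true);
  arma::mat Y = Wm.t() * col;  // Co x R

  NumericVector y((R_xlen_t)Ho * Wo * Co * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Co, N);
  double* yp = y.begin();
  const double* bp = b.begin();
  for (int n = 0; n < N; ++n)
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        const arma::uword r = (arma::uword)ho + (arma::uword)Ho * (wo + (arma::uword)Wo * n);
        for (int co = 0; co < Co; ++co)
          yp[ho + (size_t)Ho * (wo + (size_t)Wo * (co + (size_t)Co * n))] = Y(co, r) + bp[co];
      }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                    int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = dy.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Co = wd[3];
  const int Ho = yd[0], Wo = yd[1];

  // gather dY as Co x R
  const arma::uword R = (arma::uword)Ho * Wo * N;
  arma::mat dY(Co, R);
  const double* dyp = dy.begin();
  for (int n = 0; n < N; ++n)
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        const arma::uword r = (arma::uword)ho + (arma::uword)Ho * (wo + (arma::uword)Wo * n);
        for (int co = 0; co < Co; ++co)
          dY(co, r) = dyp[ho + (size_t)Ho * (wo + (size_t)Wo * (co + (size_t)Co * n))];
      }

  arma::mat col = im2col(x.begin(), H, W, C, N, kh, kw, stride, pad, Ho, Wo);
  arma::mat dW = col * dY.t();                       // K x Co
  const arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * C, Co, false, true);
  arma::mat dcol = Wm * dY;                          // K x R
  arma::vec db = arma::sum(dY, 1);

  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  col2im_add(dx.begin(), dcol, H, W, C, N, kh, kw, stride, pad, Ho, Wo);

  NumericVector dwv(dW.memptr(), dW.memptr() + dW.n_elem);
  dwv.attr("dim") = wd;
  return List::create(_["dx"] = dx, _["dw"] = dwv,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// Weight/bias gradients only (input gradient skipped): used for the first
// layer of a network where dL/dx is never consumed.
// [[Rcpp::export]]
List cpp_conv2d_bwd_nodx(NumericVector x, NumericVector w, NumericVector dy,
                         int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = dy.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Co = wd[3];
  const int Ho = yd[0], Wo = yd[1];
  const arma::uword R = (arma::uword)Ho * Wo * N;
  arma::mat dY(Co, R);
  const double* dyp = dy.begin();
  for (int n = 0; n < N; ++n)
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        const arma::uword r = (arma::uword)ho + (arma::uword)Ho * (wo + (arma::uword)Wo * n);
        for (int co = 0; co < Co; ++co)
          dY(co, r) = dyp[ho + (size_t)Ho * (wo + (size_t)Wo * (co + (size_t)Co * n))];
      }
  arma::mat col = im2col(x.begin(), H, W, C, N, kh, kw, stride, pad, Ho, Wo);
  arma::mat dW = col * dY.t();
  arma::vec db = arma::sum(dY, 1);
  NumericVector dwv(dW.memptr(), dW.memptr() + dW.n_elem);
  dwv.attr("dim") = wd;
  return List::create(_["dw"] = dwv,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// Transposed convolution: y size = (in - 1)*stride - 2*pad + k.
// Weight layout (kh, kw, Co, Ci).
// [[Rcpp::export]]
NumericVector cpp_convt2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                              int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int Hi = xd[0], Wi = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Co = wd[2], Ci = wd[3];
  if (Ci != C) stop("convt2d: input has %d channels, weights expect %d", C, Ci);
  const int Ho = (Hi - 1) * stride - 2 * pad + kh;
  const int Wo = (Wi - 1) * stride - 2 * pad + kw;
  if (Ho < 1 || Wo < 1) stop("convt2d: output would be empty");

  // X as Ci x R with r = hi + Hi*(wi + Wi*n)
  const arma::uword R = (arma::uword)Hi * Wi * N;
  arma::mat X(C, R);
  const double* xp = x.begin();
  for (int n = 0; n < N; ++n)
    for (int wi = 0; wi < Wi; ++wi)
      for (int hi = 0; hi < Hi; ++hi) {
        const arma::uword r = (arma::uword)hi + (arma::uword)Hi * (wi + (arma::uword)Wi * n);
        for (int c = 0; c < C; ++c)
          X(c, r) = xp[hi + (size_t)Hi * (wi + (size_t)Wi * (c + (size_t)C * n))];
      }
  const arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * Co, C, false, true);
  arma::mat colY = Wm * X;  // (kh*kw*Co) x R

  NumericVector y((R_xlen_t)Ho * Wo * Co * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Co, N);
  // scatter-add: column r contributes at ho = hi*stride - pad + dh
  col2im_add(y.begin(), colY, Ho, Wo, Co, N, kh, kw, stride, pad, Hi, Wi);
  double* yp = y.begin();
  const double* bp = b.begin();
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Co; ++co) {
      double* yc = yp + (size_t)Ho * Wo * (co + (size_t)Co * n);
      for (size_t i = 0; i < (size_t)Ho * Wo; ++i) yc[i] += bp[co];
    }
  return y;
}

// [[Rcpp::export]]
List cpp_convt2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                     int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = dy.attr("dim");
  const int Hi = xd[0], Wi = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Co = wd[2];
  const int Ho = yd[0], Wo = yd[1];

  // dcol = im2col of dy over the convT geometry (columns indexed by input pos)
  arma::mat dcol = im2col(dy.begin(), Ho, Wo, Co, N, kh, kw, stride, pad, Hi, Wi);
  const arma::uword R = (arma::uword)Hi * Wi * N;
  arma::mat X(C, R);
  const double* xp = x.begin();
  for (int n = 0; n < N; ++n)
    for (int wi = 0; wi < Wi; ++wi)
      for (int hi = 0; hi < Hi; ++hi) {
        const arma::uword r = (arma::uword)hi + (arma::uword)Hi * (wi + (arma::uword)Wi * n);
        for (int c = 0; c < C; ++c)
          X(c, r) = xp[hi + (size_t)Hi * (wi + (size_t)Wi * (c + (size_t)C * n))];
      }

  const arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * Co, C, false, true);
  arma::mat dX = Wm.t() * dcol;    // C x R
  arma::mat dW = dcol * X.t();     // (kh*kw*Co) x C

  NumericVector dx((R_xlen_t)Hi * Wi * C * N);
  dx.attr("dim") = xd;
  double* dxp = dx.begin();
  for (int n = 0; n < N; ++n)
    for (int wi = 0; wi < Wi; ++wi)
      for (int hi = 0; hi < Hi; ++hi) {
        const arma::uword r = (arma::uword)hi + (arma::uword)Hi * (wi + (arma::uword)Wi * n);
        for (int c = 0; c < C; ++c)
          dxp[hi + (size_t)Hi * (wi + (size_t)Wi * (c + (size_t)C * n))] = dX(c, r);
      }

  // bias gradient: sum of dy per output channel
  arma::vec db(Co, arma::fill::zeros);
  const double* dyp = dy.begin();
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Co; ++co) {
      const double* yc = dyp + (size_t)Ho * Wo * (co + (size_t)Co * n);
      for (size_t i = 0; i < (size_t)Ho * Wo; ++i) db(co) += yc[i];
    }

  NumericVector dwv(dW.memptr(), dW.memptr() + dW.n_elem);
  dwv.attr("dim") = wd;
  return List::create(_["dx"] = dx, _["dw"] = dwv,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// Symmetric (mirror) reflection of a continuous coordinate into [0, n-1].
static inline double reflect_coord(double t, int n) {
  if (n == 1) return 0.0;
  const double period = 2.0 * n;
  t -= period * std::floor(t / period);  // reduce into [0, period)
  if (t >= n) t = period - t - 1e-9;  // mirror, keep inside [0, n)
  if (t > n - 1) t = n - 1;
  return t;
}

static inline double bilinear_at(const double* img, int H, int W,
                                 double sh, double sw) {
  sh = reflect_coord(sh, H);
  sw = reflect_coord(sw, W);
  const int h0 = (int)std::floor(sh), w0 = (int)std::floor(sw);
  const int h1 = std::min(h0 + 1, H - 1), w1 = std::min(w0 + 1, W - 1);
  const double fh = sh - h0, fw = sw - w0;
  const double v00 = img[h0 + (size_t)H * w0], v10 = img[h1 + (size_t)H * w0];
  const double v01 = img[h0 + (size_t)H * w1], v11 = img[h1 + (size_t)H * w1];
  return (1 - fh) * (1 - fw) * v00 + fh * (1 - fw) * v10 +
         (1 - fh) * fw * v01 + fh * fw * v11;
}

// Per-patch affine warp.  params is a 4 x N matrix with rows
// (angle_rad, shift_h_px, shift_w_px, scale); the same transform is applied
// to every channel of a patch.  Inverse mapping about the patch centre with
// bilinear interpolation and mirror padding.
// [[Rcpp::export]]
NumericVector cpp_affine_warp(NumericVector x, NumericMatrix params) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  if (params.ncol() != N) stop("affine: need one parameter column per patch");
  NumericVector y((R_xlen_t)H * W * C * N);
  y.attr("dim") = xd;
  const double cy = (H - 1) / 2.0, cx = (W - 1) / 2.0;
  for (int n = 0; n < N; ++n) {
    const double th = params(0, n), ty = params(1, n), tx = params(2, n),
                 sc = params(3, n);
    if (sc <= 0) stop("affine: scale must be positive");
    const double ct = std::cos(th) / sc, st = std::sin(th) / sc;
    for (int c = 0; c < C; ++c) {
      const double* src = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      double* dst = y.begin() + (size_t)H * W * (c + (size_t)C * n);
      for (int w = 0; w < W; ++w) {
        const double u = w - cx - tx;
        for (int h = 0; h < H; ++h) {
          const double v = h - cy - ty;
          const double sw = ct * u + st * v + cx;
          const double sh = -st * u + ct * v + cy;
          dst[h + (size_t)H * w] = bilinear_at(src, H, W, sh, sw);
        }
      }
    }
  }
  return y;
}

// Bilinear resize of an (H,W,C,N) batch to (out_h, out_w), half-pixel centres.
// [[Rcpp::export]]
NumericVector cpp_resize_bilinear(NumericVector x, int out_h, int out_w) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  NumericVector y((R_xlen_t)out_h * out_w * C * N);
  y.attr("dim") = IntegerVector::create(out_h, out_w, C, N);
  const double sh_scale = (double)H / out_h, sw_scale = (double)W / out_w;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* src = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      double* dst = y.begin() + (size_t)out_h * out_w * (c + (size_t)C * n);
      for (int w = 0; w < out_w; ++w) {
        double sw = (w + 0.5) * sw_scale - 0.5;
        if (sw < 0) sw = 0; if (sw > W - 1) sw = W - 1;
        for (int h = 0; h < out_h; ++h) {
          double sh = (h + 0.5) * sh_scale - 0.5;
          if (sh < 0) sh = 0; if (sh > H - 1) sh = H - 1;
          dst[h + (size_t)out_h * w] = bilinear_at(src, H, W, sh, sw);
        }
      }
    }
  return y;
}
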