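// Dense numeric kernels for the CNN layers and image geometry.
// Tensor layout throughout: activations (H, W, C, N), conv weights
// (KH, KW, Cin, Cout), all column-major R arrays of doubles.
#include <RcppArmadillo.h>
using namespace Rcpp;

static inline int out_size(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// Gather sample n of x into a (KH*KW*C) x (Ho*Wo) column matrix.
static void im2col(const double* x, int H, int W, int C, int n,
                   int KH, int KW, int stride, int pad,
                   int Ho, int Wo, arma::mat& col) {
  col.zeros();
  const double* xn = x + (size_t)H * W * C * n;
  for (int c = 0; c < C; ++c) {
    const double* xc = xn + (size_t)H * W * c;
    for (int kj = 0; kj < KW; ++kj) {
      for (int ki = 0; ki < KH; ++ki) {
        int r = ki + KH * (kj + KW * c);
        for (int oj = 0; oj < Wo; ++oj) {
          int jj = oj * stride + kj - pad;
          if (jj < 0 || jj >= W) continue;
          const double* xcol = xc + (size_t)H * jj;
          double* crow = col.memptr() + r + (size_t)col.n_rows * Ho * oj;
          for (int oi = 0; oi < Ho; ++oi) {
            int ii = oi * stride + ki - pad;
            if (ii < 0 || ii >= H) continue;
            crow[(size_t)col.n_rows * oi] = xcol[ii];
          }
        }
      }
    }
  }
}

// Scatter-add a column matrix back into sample n of dx (adjoint of im2col).
static void col2im(const arma::mat& col, double* dx, int H, int W, int C, int n,
                   int KH, int KW, int stride, int pad, int Ho, int Wo) {
  double* xn = dx + (size_t)H * W * C * n;
  for (int c = 0; c < C; ++c) {
    double* xc = xn + (size_t)H * W * c;
    for (int kj = 0; kj < KW; ++kj) {
      for (int ki = 0; ki < KH; ++ki) {
        int r = ki + KH * (kj + KW * c);
        for (int oj = 0; oj < Wo; ++oj) {
          int jj = oj * stride + kj - pad;
          if (jj < 0 || jj >= W) continue;
          double* xcol = xc + (size_t)H * jj;
          const double* crow = col.memptr() + r + (size_t)col.n_rows * Ho * oj;
          for (int oi = 0; oi < Ho; ++oi) {
            int ii = oi * stride + ki - pad;
            if (ii < 0 || ii >= H) continue;
            xcol[ii] += crow[(size_t)col.n_rows * oi];
          }
        }
      }
    }
  }
}

// Pack the (KH,KW,Cin,Cout) weight array as a (Cout x KH*KW*Cin) GEMM matrix.
static arma::mat weight_matrix(const NumericVector& w, int KH, int KW, int C, int K) {
  arma::mat Wm(K, (size_t)KH * KW * C);
  const double* wp = w.begin();
  for (int k = 0; k < K; ++k)
    for (int c = 0; c < C; ++c)
      for (int kj = 0; kj < KW; ++kj)
        for (int ki = 0; ki < KH; ++ki)
          Wm(k, ki + KH * (kj + KW * c)) =
            wp[ki + (size_t)KH * (kj + KW * (c + (size_t)C * k))];
  return Wm;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_forward(NumericVector x, NumericVector w,
                                 int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int KH = wd[0], KW = wd[1], K = wd[3];
  if (wd[2] != C) stop("channel mismatch between input and kernel");
  int Ho = out_size(H, KH, stride, pad), Wo = out_size(W, KW, stride, pad);
  if (Ho < 1 || Wo < 1) stop("input too small for kernel/stride/pad");
  NumericVector y((size_t)Ho * Wo * K * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, K, N);
  arma::mat Wm = weight_matrix(w, KH, KW, C, K);
  arma::mat col((size_t)KH * KW * C, (size_t)Ho * Wo);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin(), H, W, C, n, KH, KW, stride, pad, Ho, Wo, col);
    arma::mat res = Wm * col; // K x P
    double* yn = y.begin() + (size_t)Ho * Wo * K * n;
    for (int k = 0; k < K; ++k)
      for (size_t p = 0; p < (size_t)Ho * Wo; ++p)
        yn[p + (size_t)Ho * Wo * k] = res(k, p);
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_backward(NumericVector x, NumericVector w, NumericVector dy,
                         int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = dy.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int KH = wd[0], KW = wd[1], K = wd[3];
  int Ho = yd[0], Wo = yd[1];
  arma::mat Wm = weight_matrix(w, KH, KW, C, K);
  arma::mat dWm(K, (size_t)KH * KW * C, arma::fill::zeros);
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = xd;
  arma::mat col((size_t)KH * KW * C, (size_t)Ho * Wo);
  arma::mat dyn(K, (size_t)Ho * Wo);
  for (int n = 0; n < N; ++n) {
    const double* dp = dy.begin() + (size_t)Ho * Wo * K * n;
    for (int k = 0; k < K; ++k)
      for (size_t p = 0; p < (size_t)Ho * Wo; ++p)
        dyn(k, p) = dp[p + (size_t)Ho * Wo * k];
    im2col(x.begin(), H, W, C, n, KH, KW, stride, pad, Ho, Wo, col);
    dWm += dyn * col.t();
    arma::mat dcol = Wm.t() * dyn;
    col2im(dcol, dx.begin(), H, W, C, n, KH, KW, stride, pad, Ho, Wo);
  }
  NumericVector dw((size_t)KH * KW * C * K);
  dw.attr("dim") = wd;
  double* dwp = dw.begin();
  for (int k = 0; k < K; ++k)
    for (int c = 0; c < C; ++c)
      for (int kj = 0; kj < KW; ++kj)
        for (int ki = 0; ki < KH; ++ki)
          dwp[ki + (size_t)KH * (kj + KW * (c + (size_t)C * k))] =
            dWm(k, ki + KH * (kj + KW * c));
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// 2x2 max pooling, stride 2; odd trailing rows/cols are dropped.
// [[Rcpp::export]]
List cpp_maxpool2_forward(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  IntegerVector idx((size_t)Ho * Wo * C * N); // 0-based offset into x
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double* xp = x.begin();
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      size_t base = (size_t)H * W * (c + (size_t)C * n);
      for (int oj = 0; oj < Wo; ++oj)
        for (int oi = 0; oi < Ho; ++oi, ++o) {
          size_t i0 = base + 2 * oi + (size_t)H * 2 * oj;
          size_t best = i0; double bv = xp[i0];
          size_t cand[3] = {i0 + 1, i0 + (size_t)H, i0 + (size_t)H + 1};
          for (int t = 0; t < 3; ++t)
            if (xp[cand[t]] > bv) { bv = xp[cand[t]]; best = cand[t]; }
          y[o] = bv; idx[o] = (int)best;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_backward(NumericVector dy, IntegerVector idx,
                                    IntegerVector xdim) {
  size_t nx = (size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(nx);
  dx.attr("dim") = xdim;
  for (R_xlen_t o = 0; o < dy.size(); ++o) dx[idx[o]] += dy[o];
  return dx;
}

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Bilinear resampling with half-pixel centers, edge clamped. img: (H,W,C).
// [[Rcpp::export]]
NumericVector cpp_bilinear_resize(NumericVector img, int oh, int ow) {
  IntegerVector d = img.attr("dim");
  int H = d[0], W = d[1], C = d[2];
  NumericVector out((size_t)oh * ow * C);
  out.attr("dim") = IntegerVector::create(oh, ow, C);
  double sy = (double)H / oh, sx = (double)W / ow;
  for (int c = 0; c < C; ++c) {
    const double* ic = img.begin() + (size_t)H * W * c;
    double* oc = out.begin() + (size_t)oh * ow * c;
    for (int j = 0; j < ow; ++j) {
      double fx = clampd((j + 0.5) * sx - 0.5, 0, W - 1);
      int x0 = (int)fx; int x1 = x0 + 1 < W ? x0 + 1 : x0;
      double wx = fx - x0;
      for (int i = 0; i < oh; ++i) {
        double fy = clampd((i + 0.5) * sy - 0.5, 0, H - 1);
        int y0 = (int)fy; int y1 = y0 + 1 < H ? y0 + 1 : y0;
        double wy = fy - y0;
        double v = (1 - wy) * ((1 - wx) * ic[y0 + (size_t)H * x0] + wx * ic[y0 + (size_t)H * x1])
                 + wy * ((1 - wx) * ic[y1 + (size_t)H * x0] + wx * ic[y1 + (size_t)H * x1]);
        oc[i + (size_t)oh * j] = v;
      }
    }
  }
  return out;
}

// Rotation (degrees, about the image centre) plus translation (pixels),
// bilinear sampling, constant fill outside the source. img: (H,W,C).
// [[Rcpp::export]]
NumericVector cpp_affine_warp(NumericVector img, double angle_deg,
                              double tx, double ty, double fill) {
  IntegerVector d = img.attr("dim");
  int H = d[0], W = d[1], C = d[2];
  NumericVector out((size_t)H * W * C);
  out.attr("dim") = d;
  double th = angle_deg * M_PI / 180.0;
  double ca = cos(th), sa = sin(th);
  double cy = (H - 1) / 2.0, cx = (W - 1) / 2.0;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      // inverse map: undo translation, then rotate back about centre
      double yd = i - ty - cy, xd = j - tx - cx;
      double ys = ca * yd + sa * xd + cy;
      double xs = -sa * yd + ca * xd + cx;
      for (int c = 0; c < C; ++c) {
        double v;
        if (ys < 0 || ys > H - 1 || xs < 0 || xs > W - 1) {
          v = fill;
        } else {
          int y0 = (int)ys, x0 = (int)xs;
          int y1 = y0 + 1 < H ? y0 + 1 : y0, x1 = x0 + 1 < W ? x0 + 1 : x0;
          double wy = ys - y0, wx = xs - x0;
          const double* ic = img.begin() + (size_t)H * W * c;
          v = (1 - wy) * ((1 - wx) * ic[y0 + (size_t)H * x0] + wx * ic[y0 + (size_t)H * x1])
            + wy * ((1 - wx) * ic[y1 + (size_t)H * x0] + wx * ic[y1 + (size_t)H * x1]);
        }
        out[i + (size_t)H * (j + (size_t)W * c)] = v;
      }
    }
  }
  return out;
}
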