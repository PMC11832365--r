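// Convolution / pooling kernels used by the autodiff engine.
// Array layout everywhere: (H, W, C, N), column-major (R native).
// Weight layout: (KH, KW, Cin, Cout).
//
// GEMMs run in single precision: the networks trained here are small and
// float32 is ample for SGD-style optimisation, while sgemm roughly halves
// the dominant cost on one CPU. Inputs/outputs stay double on the R side.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline void im2col_f(const double *x, int H, int W, int C,
                            int KH, int KW, int stride, int pad,
                            int Ho, int Wo, arma::fmat &col, int row0) {
  for (int c = 0; c < C; ++c) {
    const double *xc = x + (size_t)c * H * W;
    for (int kw = 0; kw < KW; ++kw) {
      for (int kh = 0; kh < KH; ++kh) {
        int j = (c * KW + kw) * KH + kh;
        float *dst = col.colptr(j) + row0;
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pad + kw;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride - pad + kh;
            double v = 0.0;
            if (hi >= 0 && hi < H && wi >= 0 && wi < W)
              v = xc[(size_t)wi * H + hi];
            dst[(size_t)wo * Ho + ho] = (float)v;
          }
        }
      }
    }
  }
}

static inline void col2im_add(const arma::fmat &col, int row0, double *gx,
                              int H, int W, int C, int KH, int KW,
                              int stride, int pad, int Ho, int Wo) {
  for (int c = 0; c < C; ++c) {
    double *gxc = gx + (size_t)c * H * W;
    for (int kw = 0; kw < KW; ++kw) {
      for (int kh = 0; kh < KH; ++kh) {
        int j = (c * KW + kw) * KH + kh;
        const float *src = col.colptr(j) + row0;
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pad + kw;
          if (wi < 0 || wi >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride - pad + kh;
            if (hi < 0 || hi >= H) continue;
            gxc[(size_t)wi * H + hi] += (double)src[(size_t)wo * Ho + ho];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fw(NumericVector x, NumericVector w, NumericVector b,
                        int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int KH = wd[0], KW = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: channel mismatch");
  int Ho = (H + 2 * pad - KH) / stride + 1;
  int Wo = (W + 2 * pad - KW) / stride + 1;
  arma::fmat Wm(KH * KW * Cin, Cout);
  for (size_t i = 0; i < (size_t)w.size(); ++i) Wm[i] = (float)w[i];
  NumericVector y((size_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::fmat col(Ho * Wo * N, KH * KW * Cin);
  for (int n = 0; n < N; ++n)
    im2col_f(x.begin() + (size_t)n * H * W * C,
             H, W, C, KH, KW, stride, pad, Ho, Wo, col, n * Ho * Wo);
  arma::fmat out = col * Wm;            // (Ho*Wo*N, Cout)
  for (int n = 0; n < N; ++n) {
    double *yn = y.begin() + (size_t)n * Ho * Wo * Cout;
    for (int co = 0; co < Cout; ++co) {
      const float *src = out.colptr(co) + (size_t)n * Ho * Wo;
      double *dst = yn + (size_t)co * Ho * Wo;
      for (int k = 0; k < Ho * Wo; ++k) dst[k] = (double)src[k] + b[co];
    }
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bw(NumericVector x, NumericVector w, NumericVector gy,
               int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int KH = wd[0], KW = wd[1], Cin = wd[2], Cout = wd[3];
  int Ho = (H + 2 * pad - KH) / stride + 1;
  int Wo = (W + 2 * pad - KW) / stride + 1;
  arma::fmat Wm(KH * KW * Cin, Cout);
  for (size_t i = 0; i < (size_t)w.size(); ++i) Wm[i] = (float)w[i];
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = xd;
  NumericVector gw((size_t)KH * KW * Cin * Cout);
  gw.attr("dim") = wd;
  NumericVector gb(Cout);
  arma::fmat col(Ho * Wo * N, KH * KW * Cin);
  arma::fmat gyb(Ho * Wo * N, Cout);
  for (int n = 0; n < N; ++n) {
    im2col_f(x.begin() + (size_t)n * H * W * C,
             H, W, C, KH, KW, stride, pad, Ho, Wo, col, n * Ho * Wo);
    const double *gyn = gy.begin() + (size_t)n * Ho * Wo * Cout;
    for (int co = 0; co < Cout; ++co) {
      float *dst = gyb.colptr(co) + (size_t)n * Ho * Wo;
      const double *src = gyn + (size_t)co * Ho * Wo;
      for (int k = 0; k < Ho * Wo; ++k) dst[k] = (float)src[k];
    }
  }
  arma::fmat gWm = col.t() * gyb;
  for (size_t i = 0; i < (size_t)gw.size(); ++i) gw[i] = (double)gWm[i];
  arma::fmat gcol = gyb * Wm.t();       // (Ho*Wo*N, KH*KW*Cin)
  for (int n = 0; n < N; ++n)
    col2im_add(gcol, n * Ho * Wo, gx.begin() + (size_t)n * H * W * C,
               H, W, C, KH, KW, stride, pad, Ho, Wo);
  for (int co = 0; co < Cout; ++co) {
    double acc = 0;
    const float *src = gyb.colptr(co);
    for (size_t k = 0; k < (size_t)Ho * Wo * N; ++k) acc += src[k];
    gb[co] = acc;
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Nearest-neighbour 2x upsampling.
// [[Rcpp::export]]
NumericVector upsample2_fw(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  NumericVector y((size_t)4 * H * W * C * N);
  y.attr("dim") = IntegerVector::create(2 * H, 2 * W, C, N);
  int H2 = 2 * H;
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double *xs = x.begin() + cn * H * W;
    double *ys = y.begin() + cn * 4 * H * W;
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        double v = xs[(size_t)w * H + h];
        size_t b0 = (size_t)(2 * w) * H2 + 2 * h;
        ys[b0] = v; ys[b0 + 1] = v;
        ys[b0 + H2] = v; ys[b0 + H2 + 1] = v;
      }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector upsample2_bw(NumericVector gy, int H, int W) {
  IntegerVector gd = gy.attr("dim");
  int C = gd[2], N = gd[3], H2 = gd[0];
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double *gs = gy.begin() + cn * 4 * H * W;
    double *xs = gx.begin() + cn * H * W;
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        size_t b0 = (size_t)(2 * w) * H2 + 2 * h;
        xs[(size_t)w * H + h] =
          gs[b0] + gs[b0 + 1] + gs[b0 + H2] + gs[b0 + H2 + 1];
      }
  }
  return gx;
}

// 2x average pooling (H, W even).
// [[Rcpp::export]]
NumericVector avgpool2_fw(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double *xs = x.begin() + cn * H * W;
    double *ys = y.begin() + cn * Ho * Wo;
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h) {
        size_t b0 = (size_t)(2 * w) * H + 2 * h;
        ys[(size_t)w * Ho + h] =
          0.25 * (xs[b0] + xs[b0 + 1] + xs[b0 + H] + xs[b0 + H + 1]);
      }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector avgpool2_bw(NumericVector gy) {
  IntegerVector gd = gy.attr("dim");
  int Ho = gd[0], Wo = gd[1], C = gd[2], N = gd[3];
  int H = 2 * Ho, W = 2 * Wo;
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double *gs = gy.begin() + cn * Ho * Wo;
    double *xs = gx.begin() + cn * H * W;
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h) {
        double v = 0.25 * gs[(size_t)w * Ho + h];
        size_t b0 = (size_t)(2 * w) * H + 2 * h;
        xs[b0] = v; xs[b0 + 1] = v; xs[b0 + H] = v; xs[b0 + H + 1] = v;
      }
  }
  return gx;
}
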