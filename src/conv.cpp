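// 2-D convolution kernels (im2col + GEMM) on [H, W, C, N] arrays.
// The autodiff layer in R/layers.R dispatches here; gradients for input,
// weights and bias are computed by the matching backward entry points.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void im2col_fill(const double* xn, int H, int W, int Cin,
                        int kh, int kw, int stride, int pad,
                        int Ho, int Wo, arma::mat& X) {
  double* Xp = X.memptr();
  for (int ci = 0; ci < Cin; ++ci) {
    const double* xc = xn + (size_t)ci * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        int q = ci * kh * kw + kj * kh + ki;
        double* col = Xp + (size_t)q * Ho * Wo;
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride + kj - pad;
          bool wok = (wi >= 0 && wi < W);
          const double* xcw = xc + (size_t)wi * H;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride + ki - pad;
            col[(size_t)wo * Ho + ho] =
              (wok && hi >= 0 && hi < H) ? xcw[hi] : 0.0;
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = "conv2dForwardCpp")]]
NumericVector conv2dForwardCpp(NumericVector x, NumericVector w,
                               Nullable<NumericVector> bias,
                               int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cout = wd[3];
  int Ho = (H + 2 * pad - kh) / stride + 1;
  int Wo = (W + 2 * pad - kw) / stride + 1;
  arma::mat Wm(w.begin(), (size_t)kh * kw * Cin, Cout, false, true);
  NumericVector y((R_xlen_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat X((size_t)Ho * Wo, (size_t)kh * kw * Cin);
  for (int n = 0; n < N; ++n) {
    im2col_fill(x.begin() + (size_t)n * H * W * Cin, H, W, Cin,
                kh, kw, stride, pad, Ho, Wo, X);
    arma::mat Y = X * Wm;
    std::copy(Y.memptr(), Y.memptr() + Y.n_elem,
              y.begin() + (size_t)n * Ho * Wo * Cout);
  }
  if (bias.isNotNull()) {
    NumericVector b(bias);
    double* yp = y.begin();
    for (int n = 0; n < N; ++n)
      for (int co = 0; co < Cout; ++co) {
        double bv = b[co];
        double* yc = yp + ((size_t)n * Cout + co) * Ho * Wo;
        for (int i = 0; i < Ho * Wo; ++i) yc[i] += bv;
      }
  }
  return y;
}

// [[Rcpp::export(name = "conv2dBackwardCpp")]]
List conv2dBackwardCpp(NumericVector x, NumericVector w, NumericVector gy,
                       int stride, int pad, bool withBias) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cout = wd[3];
  int Ho = (H + 2 * pad - kh) / stride + 1;
  int Wo = (W + 2 * pad - kw) / stride + 1;
  arma::mat Wm(w.begin(), (size_t)kh * kw * Cin, Cout, false, true);
  NumericVector gx((R_xlen_t)H * W * Cin * N);
  gx.attr("dim") = IntegerVector::create(H, W, Cin, N);
  NumericVector gw((R_xlen_t)kh * kw * Cin * Cout);
  gw.attr("dim") = IntegerVector::create(kh, kw, Cin, Cout);
  arma::mat GW(gw.begin(), (size_t)kh * kw * Cin, Cout, false, true);
  NumericVector gb(Cout);
  arma::mat X((size_t)Ho * Wo, (size_t)kh * kw * Cin);
  for (int n = 0; n < N; ++n) {
    arma::mat G(gy.begin() + (size_t)n * Ho * Wo * Cout,
                (size_t)Ho * Wo, Cout, false, true);
    im2col_fill(x.begin() + (size_t)n * H * W * Cin, H, W, Cin,
                kh, kw, stride, pad, Ho, Wo, X);
    GW += X.t() * G;
    arma::mat D = G * Wm.t();        // [HoWo, kh*kw*Cin]
    // col2im scatter-add
    double* gxn = gx.begin() + (size_t)n * H * W * Cin;
    const double* Dp = D.memptr();
    for (int ci = 0; ci < Cin; ++ci) {
      double* gxc = gxn + (size_t)ci * H * W;
      for (int kj = 0; kj < kw; ++kj) {
        for (int ki = 0; ki < kh; ++ki) {
          int q = ci * kh * kw + kj * kh + ki;
          const double* col = Dp + (size_t)q * Ho * Wo;
          for (int wo = 0; wo < Wo; ++wo) {
            int wi = wo * stride + kj - pad;
            if (wi < 0 || wi >= W) continue;
            double* gxw = gxc + (size_t)wi * H;
            for (int ho = 0; ho < Ho; ++ho) {
              int hi = ho * stride + ki - pad;
              if (hi >= 0 && hi < H)
                gxw[hi] += col[(size_t)wo * Ho + ho];
            }
          }
        }
      }
    }
    if (withBias) {
      for (int co = 0; co < Cout; ++co) {
        const double* gc = gy.begin() + ((size_t)n * Cout + co) * Ho * Wo;
        double s = 0.0;
        for (int i = 0; i < Ho * Wo; ++i) s += gc[i];
        gb[co] += s;
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}
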