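// Strided 2-D convolution primitives for the autoencoder backbones.
// Tensors are R arrays in column-major layout:
//   activations  H x W x C x N
//   conv weights k x k x Cin x Cout
// A transposed convolution (upsampling decoder layer) is the adjoint of a
// strided convolution, so the three primitives below cover forward and
// backward passes of both layer types.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int H, int k, int stride, int pad) {
  return (H + 2 * pad - k) / stride + 1;
}

// gather image n of x into col (k*k*Cin rows, Ho*Wo cols)
static void im2col(const double* x, int H, int W, int Cin,
                   int k, int stride, int pad, int Ho, int Wo,
                   arma::mat& col) {
  for (int ow = 0; ow < Wo; ++ow) {
    for (int oh = 0; oh < Ho; ++oh) {
      const int p = oh + Ho * ow;
      double* cp = col.colptr(p);
      for (int c = 0; c < Cin; ++c) {
        const double* xc = x + (size_t)H * W * c;
        for (int kj = 0; kj < k; ++kj) {
          const int j = ow * stride - pad + kj;
          for (int ki = 0; ki < k; ++ki) {
            const int i = oh * stride - pad + ki;
            const int r = ki + k * (kj + k * c);
            cp[r] = (i >= 0 && i < H && j >= 0 && j < W)
                      ? xc[i + (size_t)H * j] : 0.0;
          }
        }
      }
    }
  }
}

// scatter-add col back onto image n of gx (adjoint of im2col)
static void col2im(const arma::mat& col, int H, int W, int Cin,
                   int k, int stride, int pad, int Ho, int Wo,
                   double* gx) {
  for (int ow = 0; ow < Wo; ++ow) {
    for (int oh = 0; oh < Ho; ++oh) {
      const int p = oh + Ho * ow;
      const double* cp = col.colptr(p);
      for (int c = 0; c < Cin; ++c) {
        double* gc = gx + (size_t)H * W * c;
        for (int kj = 0; kj < k; ++kj) {
          const int j = ow * stride - pad + kj;
          if (j < 0 || j >= W) continue;
          for (int ki = 0; ki < k; ++ki) {
            const int i = oh * stride - pad + ki;
            if (i < 0 || i >= H) continue;
            gc[i + (size_t)H * j] += cp[ki + k * (kj + k * c)];
          }
        }
      }
    }
  }
}

static IntegerVector dims_of(const NumericVector& a, int need) {
  IntegerVector d = a.attr("dim");
  if (d.size() != need) stop("tensor with %d dimensions expected", need);
  return d;
}

// y[.,.,co,n] = sum_ci x[.,.,ci,n] * w[.,.,ci,co] + b[co]
// [[Rcpp::export(rng = false)]]
NumericVector conv_fwd(NumericVector x, NumericVector w, NumericVector b,
                       int stride, int pad) {
  IntegerVector dx = dims_of(x, 4), dw = dims_of(w, 4);
  const int H = dx[0], W = dx[1], Cin = dx[2], N = dx[3];
  const int k = dw[0], Cout = dw[3];
  if (dw[1] != k || dw[2] != Cin) stop("weight shape mismatch");
  const int Ho = out_size(H, k, stride, pad), Wo = out_size(W, k, stride, pad);
  const int kkC = k * k * Cin, P = Ho * Wo;

  NumericVector y((R_xlen_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat Wm(w.begin(), kkC, Cout, false, true);
  arma::mat col(kkC, P);
  arma::vec bv(b.begin(), Cout, false, true);

  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * Cin * n, H, W, Cin,
           k, stride, pad, Ho, Wo, col);
    // (P x Cout) result written channel-major into y
    arma::mat ym(y.begin() + (size_t)Ho * Wo * Cout * n, P, Cout, false, true);
    ym = col.t() * Wm;
    ym.each_row() += bv.t();
  }
  // y currently laid out (Ho*Wo, Cout) per image which matches H x W x C
  return y;
}

// gradient of conv_fwd w.r.t. x; H, W are the *input* spatial dims
// [[Rcpp::export(rng = false)]]
NumericVector conv_bwd_input(NumericVector gy, NumericVector w,
                             int stride, int pad, int H, int W) {
  IntegerVector dg = dims_of(gy, 4), dw = dims_of(w, 4);
  const int Ho = dg[0], Wo = dg[1], Cout = dg[2], N = dg[3];
  const int k = dw[0], Cin = dw[2];
  if (dw[3] != Cout) stop("weight/grad channel mismatch");
  if (out_size(H, k, stride, pad) != Ho || out_size(W, k, stride, pad) != Wo)
    stop("spatial size inconsistent with stride/pad");
  const int kkC = k * k * Cin, P = Ho * Wo;

  NumericVector gx((R_xlen_t)H * W * Cin * N);
  gx.attr("dim") = IntegerVector::create(H, W, Cin, N);
  std::fill(gx.begin(), gx.end(), 0.0);
  arma::mat Wm(w.begin(), kkC, Cout, false, true);
  arma::mat col(kkC, P);

  for (int n = 0; n < N; ++n) {
    arma::mat gm(gy.begin() + (size_t)Ho * Wo * Cout * n, P, Cout, false, true);
    col = Wm * gm.t();
    col2im(col, H, W, Cin, k, stride, pad, Ho, Wo,
           gx.begin() + (size_t)H * W * Cin * n);
  }
  return gx;
}

// gradients of conv_fwd w.r.t. w and b, accumulated over the batch
// [[Rcpp::export(rng = false)]]
List conv_bwd_weight(NumericVector x, NumericVector gy, int k,
                     int stride, int pad) {
  IntegerVector dx = dims_of(x, 4), dg = dims_of(gy, 4);
  const int H = dx[0], W = dx[1], Cin = dx[2], N = dx[3];
  const int Ho = dg[0], Wo = dg[1], Cout = dg[2];
  if (dg[3] != N) stop("batch mismatch");
  const int kkC = k * k * Cin, P = Ho * Wo;

  NumericVector gw((R_xlen_t)k * k * Cin * Cout);
  gw.attr("dim") = IntegerVector::create(k, k, Cin, Cout);
  std::fill(gw.begin(), gw.end(), 0.0);
  NumericVector gb(Cout);
  arma::mat gwm(gw.begin(), kkC, Cout, false, true);
  arma::vec gbv(gb.begin(), Cout, false, true);
  arma::mat col(kkC, P);

  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * Cin * n, H, W, Cin,
           k, stride, pad, Ho, Wo, col);
    arma::mat gm(gy.begin() + (size_t)Ho * Wo * Cout * n, P, Cout, false, true);
    gwm += col * gm;
    gbv += arma::sum(gm, 0).t();
  }
  return List::create(_["gw"] = gw, _["gb"] = gb);
}
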