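// im2col / col2im kernels for k x k convolutions on (N,H,W,C) column-major
// arrays. The surrounding R code performs the actual contraction as a single
// BLAS matrix product; these kernels only move memory. Column j of the patch
// matrix corresponds to kernel offset (di, dj) and input channel ci with
// j = di + K*(dj + K*ci), matching matrix(W, K*K*Cin, Cout) flattening; row r
// corresponds to (n, oh, ow) with r = n + N*(oh + OH*ow), matching
// array(y, c(N, OH, OW, Cout)).

#include <Rcpp.h>
using namespace Rcpp;

static inline int out_side(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

static inline int clamp_lo(int d, int pad, int stride) {
  int num = pad - d;
  if (num <= 0) return 0;
  return (num + stride - 1) / stride;
}

static inline int clamp_hi(int d, int pad, int stride, int in, int out) {
  int hi = (in - 1 + pad - d) / stride;
  return hi < out - 1 ? hi : out - 1;
}

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int k, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  const int N = xd[0], H = xd[1], W = xd[2], Cin = xd[3];
  const int OH = out_side(H, k, stride, pad), OW = out_side(W, k, stride, pad);
  const R_xlen_t rows = static_cast<R_xlen_t>(N) * OH * OW;
  NumericMatrix cols(rows, k * k * Cin);
  const double *xp = x.begin();
  double *cp = cols.begin();

  for (int ci = 0; ci < Cin; ++ci) {
    const double *xc = xp + static_cast<R_xlen_t>(ci) * N * H * W;
    for (int dj = 0; dj < k; ++dj) {
      const int ow_lo = clamp_lo(dj, pad, stride);
      const int ow_hi = clamp_hi(dj, pad, stride, W, OW);
      for (int di = 0; di < k; ++di) {
        const int oh_lo = clamp_lo(di, pad, stride);
        const int oh_hi = clamp_hi(di, pad, stride, H, OH);
        double *col = cp + rows * (di + k * (dj + static_cast<R_xlen_t>(k) * ci));
        if (oh_hi < oh_lo) continue;
        for (int ow = ow_lo; ow <= ow_hi; ++ow) {
          const int iw = ow * stride + dj - pad;
          double *dst = col + static_cast<R_xlen_t>(N) * (oh_lo + static_cast<R_xlen_t>(OH) * ow);
          const double *src = xc + static_cast<R_xlen_t>(N) * ((oh_lo * stride + di - pad) + static_cast<R_xlen_t>(H) * iw);
          if (stride == 1) {
            memcpy(dst, src, sizeof(double) * N * (oh_hi - oh_lo + 1));
          } else {
            for (int oh = oh_lo; oh <= oh_hi; ++oh) {
              memcpy(dst, src, sizeof(double) * N);
              dst += N;
              src += static_cast<R_xlen_t>(N) * stride;
            }
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, int n, int h, int w, int cin,
                         int k, int stride, int pad) {
  const int OH = out_side(h, k, stride, pad), OW = out_side(w, k, stride, pad);
  const R_xlen_t rows = static_cast<R_xlen_t>(n) * OH * OW;
  NumericVector dx(static_cast<R_xlen_t>(n) * h * w * cin);
  dx.attr("dim") = IntegerVector::create(n, h, w, cin);
  double *dxp = dx.begin();
  const double *cp = cols.begin();

  for (int ci = 0; ci < cin; ++ci) {
    double *dxc = dxp + static_cast<R_xlen_t>(ci) * n * h * w;
    for (int dj = 0; dj < k; ++dj) {
      const int ow_lo = clamp_lo(dj, pad, stride);
      const int ow_hi = clamp_hi(dj, pad, stride, w, OW);
      for (int di = 0; di < k; ++di) {
        const int oh_lo = clamp_lo(di, pad, stride);
        const int oh_hi = clamp_hi(di, pad, stride, h, OH);
        const double *col = cp + rows * (di + k * (dj + static_cast<R_xlen_t>(k) * ci));
        if (oh_hi < oh_lo) continue;
        for (int ow = ow_lo; ow <= ow_hi; ++ow) {
          const int iw = ow * stride + dj - pad;
          const double *src = col + static_cast<R_xlen_t>(n) * (oh_lo + static_cast<R_xlen_t>(OH) * ow);
          double *dst = dxc + static_cast<R_xlen_t>(n) * ((oh_lo * stride + di - pad) + static_cast<R_xlen_t>(h) * iw);
          if (stride == 1) {
            const int len = n * (oh_hi - oh_lo + 1);
            const double *__restrict__ s = src;
            double *__restrict__ d = dst;
            for (int i = 0; i < len; ++i) d[i] += s[i];
          } else {
            for (int oh = oh_lo; oh <= oh_hi; ++oh) {
              for (int i = 0; i < n; ++i) dst[i] += src[i];
              src += n;
              dst += static_cast<R_xlen_t>(n) * stride;
            }
          }
        }
      }
    }
  }
  return dx;
}

// AdamW moment update. m and v are private optimizer state and are updated
// in place; the returned array is the Adam step direction
// mhat / (sqrt(vhat) + eps). Weights are updated on the R side.
// [[Rcpp::export]]
NumericVector adamw_update_cpp(NumericVector g, NumericVector m,
                               NumericVector v, double b1, double b2,
                               double eps, int t) {
  const R_xlen_t n = g.size();
  NumericVector upd(n);
  double *mp = m.begin(), *vp = v.begin(), *up = upd.begin();
  const double *gp = g.begin();
  const double c1 = 1.0 - std::pow(b1, t), c2 = 1.0 - std::pow(b2, t);
  for (R_xlen_t i = 0; i < n; ++i) {
    mp[i] = b1 * mp[i] + (1.0 - b1) * gp[i];
    vp[i] = b2 * vp[i] + (1.0 - b2) * gp[i] * gp[i];
    up[i] = (mp[i] / c1) / (std::sqrt(vp[i] / c2) + eps);
  }
  return upd;
}
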