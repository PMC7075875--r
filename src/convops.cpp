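// Data-movement kernels for the CNN engine: im2col / col2im and
// channel-major reshapes.  Tensors are dense column-major arrays
// [H, W, C, B]; the col matrix has rows indexed (ki, kj, c) fastest-first
// and columns indexed (oh, ow, b), matching the R-side weight layout
// [k, k, Cin, Cout].

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix im2col_cpp(const NumericVector& x, int H, int W, int C, int B,
                         int k, int stride, int pad, int oH, int oW) {
  const int kk = k * k;
  const int rows = kk * C;
  NumericMatrix col(rows, oH * (R_xlen_t)oW * B);
  const double* xp = x.begin();
  double* cp = col.begin();
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < C; ++c) {
      const double* xs = xp + ((R_xlen_t)b * C + c) * H * W;
      for (int ow = 0; ow < oW; ++ow) {
        for (int kj = 0; kj < k; ++kj) {
          const int wj = ow * stride + kj - pad;
          if (wj < 0 || wj >= W) continue;
          const double* xcolumn = xs + (R_xlen_t)H * wj;
          for (int ki = 0; ki < k; ++ki) {
            const int r = ki + k * kj + kk * c;
            double* cbase = cp + r +
              (R_xlen_t)rows * (oH * ((R_xlen_t)ow + (R_xlen_t)oW * b));
            for (int oh = 0; oh < oH; ++oh) {
              const int hi = oh * stride + ki - pad;
              if (hi < 0 || hi >= H) continue;
              cbase[(R_xlen_t)rows * oh] = xcolumn[hi];
            }
          }
        }
      }
    }
  }
  return col;
}

// [[Rcpp::export]]
NumericVector col2im_cpp(const NumericVector& dcol, int H, int W, int C,
                         int B, int k, int stride, int pad, int oH, int oW) {
  const int kk = k * k;
  const int rows = kk * C;
  NumericVector dx((R_xlen_t)H * W * C * B);
  const double* cp = dcol.begin();
  double* xp = dx.begin();
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < C; ++c) {
      double* xs = xp + ((R_xlen_t)b * C + c) * H * W;
      for (int ow = 0; ow < oW; ++ow) {
        for (int kj = 0; kj < k; ++kj) {
          const int wj = ow * stride + kj - pad;
          if (wj < 0 || wj >= W) continue;
          double* xcolumn = xs + (R_xlen_t)H * wj;
          for (int ki = 0; ki < k; ++ki) {
            const int r = ki + k * kj + kk * c;
            const double* cbase = cp + r +
              (R_xlen_t)rows * (oH * ((R_xlen_t)ow + (R_xlen_t)oW * b));
            for (int oh = 0; oh < oH; ++oh) {
              const int hi = oh * stride + ki - pad;
              if (hi < 0 || hi >= H) continue;
              xcolumn[hi] += cbase[(R_xlen_t)rows * oh];
            }
          }
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(H, W, C, B);
  return dx;
}

// [H, W, C, B] -> [C, H*W*B] (channel-major matrix for gemm).
// [[Rcpp::export]]
NumericMatrix chan_first_cpp(const NumericVector& x, int H, int W, int C,
                             int B) {
  NumericMatrix m(C, (R_xlen_t)H * W * B);
  const double* xp = x.begin();
  double* mp = m.begin();
  const R_xlen_t plane = (R_xlen_t)H * W;
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      const double* xs = xp + ((R_xlen_t)b * C + c) * plane;
      double* ms = mp + c + (R_xlen_t)C * plane * b;
      for (R_xlen_t i = 0; i < plane; ++i) ms[(R_xlen_t)C * i] = xs[i];
    }
  return m;
}

// [C, H*W*B] -> [H, W, C, B].
// [[Rcpp::export]]
NumericVector chan_last_cpp(const NumericVector& m, int H, int W, int C,
                            int B) {
  NumericVector x((R_xlen_t)H * W * C * B);
  const double* mp = m.begin();
  double* xp = x.begin();
  const R_xlen_t plane = (R_xlen_t)H * W;
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      double* xs = xp + ((R_xlen_t)b * C + c) * plane;
      const double* ms = mp + c + (R_xlen_t)C * plane * b;
      for (R_xlen_t i = 0; i < plane; ++i) xs[i] = ms[(R_xlen_t)C * i];
    }
  x.attr("dim") = IntegerVector::create(H, W, C, B);
  return x;
}
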