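#include <Rcpp.h>
using namespace Rcpp;

// Feature maps are R arrays with dim (H, W, C), column-major. im2col unrolls
// kh x kw x C patches into a (kh*kw*C) x (oH*oW) matrix so that convolution
// becomes one GEMM (done in R with %*%, which hits BLAS).

// [[Rcpp::export(name = ".cpp_im2col")]]
NumericMatrix cpp_im2col(NumericVector x, int H, int W, int C,
                         int kh, int kw, int stride, int pad) {
  const int oH = (H + 2 * pad - kh) / stride + 1;
  const int oW = (W + 2 * pad - kw) / stride + 1;
  NumericMatrix col(kh * kw * C, oH * oW);
  const double *xp = x.begin();
  double *cp = col.begin();
  for (int ow = 0; ow < oW; ++ow) {
    for (int oh = 0; oh < oH; ++oh) {
      const int colidx = oh + oH * ow;
      double *dst = cp + (R_xlen_t)colidx * (kh * kw * C);
      for (int c = 0; c < C; ++c) {
        for (int kj = 0; kj < kw; ++kj) {
          const int w = ow * stride - pad + kj;
          for (int ki = 0; ki < kh; ++ki) {
            const int h = oh * stride - pad + ki;
            const int r = ki + kh * kj + kh * kw * c;
            dst[r] = (h >= 0 && h < H && w >= 0 && w < W)
                       ? xp[h + H * w + (R_xlen_t)H * W * c]
                       : 0.0;
          }
        }
      }
    }
  }
  return col;
}

// Scatter-add inverse of im2col: dcol -> dx.
// [[Rcpp::export(name = ".cpp_col2im")]]
NumericVector cpp_col2im(NumericMatrix dcol, int H, int W, int C,
                         int kh, int kw, int stride, int pad) {
  const int oH = (H + 2 * pad - kh) / stride + 1;
  const int oW = (W + 2 * pad - kw) / stride + 1;
  NumericVector dx((R_xlen_t)H * W * C);
  double *xp = dx.begin();
  const double *cp = dcol.begin();
  for (int ow = 0; ow < oW; ++ow) {
    for (int oh = 0; oh < oH; ++oh) {
      const int colidx = oh + oH * ow;
      const double *src = cp + (R_xlen_t)colidx * (kh * kw * C);
      for (int c = 0; c < C; ++c) {
        for (int kj = 0; kj < kw; ++kj) {
          const int w = ow * stride - pad + kj;
          if (w < 0 || w >= W) continue;
          for (int ki = 0; ki < kh; ++ki) {
            const int h = oh * stride - pad + ki;
            if (h < 0 || h >= H) continue;
            const int r = ki + kh * kj + kh * kw * c;
            xp[h + H * w + (R_xlen_t)H * W * c] += src[r];
          }
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(H, W, C);
  return dx;
}
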