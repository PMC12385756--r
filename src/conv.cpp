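#include <Rcpp.h>
using namespace Rcpp;

// Patch extraction / scattering for 2-D convolution over H x W x C x B
// arrays (column-major, as R stores them). The multiply itself happens in
// R via BLAS; these kernels only lay out the patches.
//
// Column layout of the patch matrix: row index runs over (kh, kw, ci) with
// kh fastest (matching the column-major layout of a kh x kw x Ci x Co
// weight array); column index runs over (ho, wo, b) with ho fastest.

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, IntegerVector xd,
                         int kh, int kw, int stride, int pad) {
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  NumericMatrix cols(kh * kw * C, Ho * Wo * B);
  const double *px = x.begin();
  double *pc = cols.begin();
  const int nrow = kh * kw * C;
  for (int b = 0; b < B; ++b) {
    const double *xb = px + (R_xlen_t)H * W * C * b;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        double *col = pc + (R_xlen_t)nrow * (ho + Ho * (wo + (R_xlen_t)Wo * b));
        for (int ci = 0; ci < C; ++ci) {
          const double *xc = xb + (R_xlen_t)H * W * ci;
          for (int j = 0; j < kw; ++j) {
            const int win = wo * stride + j - pad;
            double *dst = col + kh * (j + kw * ci);
            if (win < 0 || win >= W) {
              for (int i = 0; i < kh; ++i) dst[i] = 0.0;
              continue;
            }
            const double *xcol = xc + (R_xlen_t)H * win;
            for (int i = 0; i < kh; ++i) {
              const int hin = ho * stride + i - pad;
              dst[i] = (hin < 0 || hin >= H) ? 0.0 : xcol[hin];
            }
          }
        }
      }
  }
  return cols;
}

// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, IntegerVector xd,
                         int kh, int kw, int stride, int pad) {
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  NumericVector x((R_xlen_t)H * W * C * B);
  double *px = x.begin();
  const double *pc = cols.begin();
  const int nrow = kh * kw * C;
  for (int b = 0; b < B; ++b) {
    double *xb = px + (R_xlen_t)H * W * C * b;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        const double *col = pc + (R_xlen_t)nrow * (ho + Ho * (wo + (R_xlen_t)Wo * b));
        for (int ci = 0; ci < C; ++ci) {
          double *xc = xb + (R_xlen_t)H * W * ci;
          for (int j = 0; j < kw; ++j) {
            const int win = wo * stride + j - pad;
            if (win < 0 || win >= W) continue;
            const double *src = col + kh * (j + kw * ci);
            double *xcol = xc + (R_xlen_t)H * win;
            for (int i = 0; i < kh; ++i) {
              const int hin = ho * stride + i - pad;
              if (hin >= 0 && hin < H) xcol[hin] += src[i];
            }
          }
        }
      }
  }
  x.attr("dim") = xd;
  return x;
}
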