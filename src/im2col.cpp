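#include <Rcpp.h>
using namespace Rcpp;

// Patch extraction / accumulation kernels backing the 3x3 (and general kxk,
// stride-1) convolutions. Activations are laid out H x W x C x N, column-major.
// Row index of the patch matrix: i + oh*(j + ow*n)   (0-based)
// Column index:                  kh + k*(kw + k*c)
// which matches matrix(W, k*k*Cin, Cout) for a kernel array [k, k, Cin, Cout].

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int H, int W, int C, int N,
                         int k, int pad) {
  const int oh = H + 2 * pad - k + 1;
  const int ow = W + 2 * pad - k + 1;
  NumericMatrix out(oh * ow * N, k * k * C);
  const double *px = x.begin();
  double *po = out.begin();
  const R_xlen_t nrow = (R_xlen_t)oh * ow * N;
  for (int c = 0; c < C; ++c) {
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const R_xlen_t col = kh + (R_xlen_t)k * (kw + (R_xlen_t)k * c);
        double *dst0 = po + col * nrow;
        for (int n = 0; n < N; ++n) {
          const double *src0 = px + (R_xlen_t)H * W * (c + (R_xlen_t)C * n);
          for (int j = 0; j < ow; ++j) {
            const int xj = j + kw - pad;
            if (xj < 0 || xj >= W) continue;
            double *dst = dst0 + (R_xlen_t)oh * (j + (R_xlen_t)ow * n);
            const double *src = src0 + (R_xlen_t)H * xj;
            for (int i = 0; i < oh; ++i) {
              const int xi = i + kh - pad;
              if (xi < 0 || xi >= H) continue;
              dst[i] = src[xi];
            }
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col_cpp: scatter-add patch-matrix gradients back onto the
// input grid. dP has the same layout im2col_cpp produces.
// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix dP, int H, int W, int C, int N,
                         int k, int pad) {
  const int oh = H + 2 * pad - k + 1;
  const int ow = W + 2 * pad - k + 1;
  NumericVector dx((R_xlen_t)H * W * C * N);
  const double *pp = dP.begin();
  double *pd = dx.begin();
  const R_xlen_t nrow = (R_xlen_t)oh * ow * N;
  for (int c = 0; c < C; ++c) {
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const R_xlen_t col = kh + (R_xlen_t)k * (kw + (R_xlen_t)k * c);
        const double *src0 = pp + col * nrow;
        for (int n = 0; n < N; ++n) {
          double *dst0 = pd + (R_xlen_t)H * W * (c + (R_xlen_t)C * n);
          for (int j = 0; j < ow; ++j) {
            const int xj = j + kw - pad;
            if (xj < 0 || xj >= W) continue;
            const double *src = src0 + (R_xlen_t)oh * (j + (R_xlen_t)ow * n);
            double *dst = dst0 + (R_xlen_t)H * xj;
            for (int i = 0; i < oh; ++i) {
              const int xi = i + kh - pad;
              if (xi < 0 || xi >= H) continue;
              dst[xi] += src[i];
            }
          }
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  return dx;
}
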