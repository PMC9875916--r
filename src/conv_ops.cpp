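#include <Rcpp.h>
using namespace Rcpp;

// Patch extraction for 2D convolution on channels-first [C, H, W, N] arrays.
// Rows of the result are ordered (c, ki, kj) fastest-first; columns are
// (i_out, j_out, n). Out-of-bounds reads (zero padding) contribute 0.
// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int C, int H, int W, int N,
                         int k, int stride, int pad) {
  const int Hout = (H + 2 * pad - k) / stride + 1;
  const int Wout = (W + 2 * pad - k) / stride + 1;
  const int kkC = k * k * C;
  NumericMatrix out(kkC, Hout * Wout * N);
  const double *xp = REAL(x);
  double *op = REAL(out);
  const int kC = k * C;
  for (int n = 0; n < N; ++n) {
    const double *xn = xp + (R_xlen_t)n * C * H * W;
    for (int j = 0; j < Wout; ++j) {
      for (int i = 0; i < Hout; ++i) {
        double *col = op + (R_xlen_t)kkC * (i + (R_xlen_t)Hout * (j + (R_xlen_t)Wout * n));
        const int a0 = i * stride - pad;
        for (int kj = 0; kj < k; ++kj) {
          int b = j * stride + kj - pad;
          double *dst = col + (R_xlen_t)kj * kC;
          if (b < 0 || b >= W) {
            std::fill(dst, dst + kC, 0.0);
            continue;
          }
          const double *xb = xn + (R_xlen_t)b * C * H;
          if (a0 >= 0 && a0 + k <= H) {
            // interior: the (c, ki) block is one contiguous run in x
            std::copy(xb + (R_xlen_t)a0 * C, xb + (R_xlen_t)(a0 + k) * C, dst);
          } else {
            for (int ki = 0; ki < k; ++ki) {
              int a = a0 + ki;
              if (a < 0 || a >= H)
                std::fill(dst + ki * C, dst + (ki + 1) * C, 0.0);
              else
                std::copy(xb + (R_xlen_t)a * C, xb + (R_xlen_t)(a + 1) * C,
                          dst + ki * C);
            }
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col_cpp: scatter-add patch gradients back onto the input grid.
// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, int C, int H, int W, int N,
                         int k, int stride, int pad) {
  const int Hout = (H + 2 * pad - k) / stride + 1;
  const int Wout = (W + 2 * pad - k) / stride + 1;
  const int kkC = k * k * C;
  NumericVector x((R_xlen_t)C * H * W * N);
  x.attr("dim") = IntegerVector::create(C, H, W, N);
  double *xp = REAL(x);
  const double *cp = REAL(cols);
  const int kC = k * C;
  for (int n = 0; n < N; ++n) {
    double *xn = xp + (R_xlen_t)n * C * H * W;
    for (int j = 0; j < Wout; ++j) {
      for (int i = 0; i < Hout; ++i) {
        const double *col = cp + (R_xlen_t)kkC * (i + (R_xlen_t)Hout * (j + (R_xlen_t)Wout * n));
        const int a0 = i * stride - pad;
        for (int kj = 0; kj < k; ++kj) {
          int b = j * stride + kj - pad;
          if (b < 0 || b >= W) continue;
          const double *src = col + (R_xlen_t)kj * kC;
          double *xb = xn + (R_xlen_t)b * C * H;
          if (a0 >= 0 && a0 + k <= H) {
            double *dst = xb + (R_xlen_t)a0 * C;
            for (int q = 0; q < kC; ++q) dst[q] += src[q];
          } else {
            for (int ki = 0; ki < k; ++ki) {
              int a = a0 + ki;
              if (a < 0 || a >= H) continue;
              double *dst = xb + (R_xlen_t)a * C;
              for (int c = 0; c < C; ++c) dst[c] += src[ki * C + c];
            }
          }
        }
      }
    }
  }
  return x;
}
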