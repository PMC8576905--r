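#include <Rcpp.h>
using namespace Rcpp;

// Activation batches are stored as (H*W*N) x C matrices, column-major within
// each image: row index = h + H*w + H*W*n (0-based), one column per channel.
// Convolutions are expressed as im2col + GEMM; the GEMM itself runs in R
// through the BLAS, these kernels only gather/scatter patches.

static inline int conv_out(int len, int k, int stride, int pad) {
  return (len + 2 * pad - k) / stride + 1;
}

// Patch matrix P: (Ho*Wo*N) x (C*k*k); row = ho + Ho*wo + Ho*Wo*n,
// column = kh + k*kw + k*k*c. Out-of-image taps stay zero (zero padding).
// [[Rcpp::export]]
NumericMatrix conv_im2col(const NumericMatrix& A, int H, int W, int N,
                          int k, int stride, int pad) {
  const int C = A.ncol();
  const int Ho = conv_out(H, k, stride, pad);
  const int Wo = conv_out(W, k, stride, pad);
  NumericMatrix P(Ho * Wo * N, C * k * k);
  for (int c = 0; c < C; ++c) {
    const double* Ac = &A(0, c);
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        double* Pc = &P(0, (size_t)c * k * k + (size_t)kw * k + kh);
        for (int n = 0; n < N; ++n) {
          const double* An = Ac + (size_t)n * H * W;
          double* Pn = Pc + (size_t)n * Ho * Wo;
          for (int wo = 0; wo < Wo; ++wo) {
            const int w_in = wo * stride - pad + kw;
            if (w_in < 0 || w_in >= W) continue;
            const double* Aw = An + (size_t)w_in * H;
            double* Pw = Pn + (size_t)wo * Ho;
            for (int ho = 0; ho < Ho; ++ho) {
              const int h_in = ho * stride - pad + kh;
              if (h_in >= 0 && h_in < H) Pw[ho] = Aw[h_in];
            }
          }
        }
      }
    }
  }
  return P;
}

// Adjoint of conv_im2col: scatter-add patch gradients back onto the image
// grid. dP is (Ho*Wo*N) x (C*k*k); returns (H*W*N) x C.
// [[Rcpp::export]]
NumericMatrix conv_col2im(const NumericMatrix& dP, int H, int W, int N,
                          int C, int k, int stride, int pad) {
  const int Ho = conv_out(H, k, stride, pad);
  const int Wo = conv_out(W, k, stride, pad);
  NumericMatrix dA(H * W * N, C);
  for (int c = 0; c < C; ++c) {
    double* Ac = &dA(0, c);
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const double* Pc = &dP(0, (size_t)c * k * k + (size_t)kw * k + kh);
        for (int n = 0; n < N; ++n) {
          double* An = Ac + (size_t)n * H * W;
          const double* Pn = Pc + (size_t)n * Ho * Wo;
          for (int wo = 0; wo < Wo; ++wo) {
            const int w_in = wo * stride - pad + kw;
            if (w_in < 0 || w_in >= W) continue;
            double* Aw = An + (size_t)w_in * H;
            const double* Pw = Pn + (size_t)wo * Ho;
            for (int ho = 0; ho < Ho; ++ho) {
              const int h_in = ho * stride - pad + kh;
              if (h_in >= 0 && h_in < H) Aw[h_in] += Pw[ho];
            }
          }
        }
      }
    }
  }
  return dA;
}

// Block-average pooling with window `win` (stride == window); the grid is
// covered by a ceiling partition so trailing blocks may be smaller.
// [[Rcpp::export]]
NumericMatrix pool_avg_fwd(const NumericMatrix& A, int H, int W, int N,
                           int win) {
  const int C = A.ncol();
  const int Ho = (H + win - 1) / win;
  const int Wo = (W + win - 1) / win;
  NumericMatrix O(Ho * Wo * N, C);
  for (int c = 0; c < C; ++c) {
    const double* Ac = &A(0, c);
    double* Oc = &O(0, c);
    for (int n = 0; n < N; ++n) {
      const double* An = Ac + (size_t)n * H * W;
      double* On = Oc + (size_t)n * Ho * Wo;
      for (int wo = 0; wo < Wo; ++wo) {
        const int w0 = wo * win, w1 = std::min(W, w0 + win);
        for (int ho = 0; ho < Ho; ++ho) {
          const int h0 = ho * win, h1 = std::min(H, h0 + win);
          double s = 0.0;
          for (int w = w0; w < w1; ++w)
            for (int h = h0; h < h1; ++h) s += An[(size_t)w * H + h];
          On[(size_t)wo * Ho + ho] = s / ((w1 - w0) * (h1 - h0));
        }
      }
    }
  }
  return O;
}

// [[Rcpp::export]]
NumericMatrix pool_avg_bwd(const NumericMatrix& dO, int H, int W, int N,
                           int win) {
  const int C = dO.ncol();
  const int Ho = (H + win - 1) / win;
  const int Wo = (W + win - 1) / win;
  NumericMatrix dA(H * W * N, C);
  for (int c = 0; c < C; ++c) {
    const double* Oc = &dO(0, c);
    double* Ac = &dA(0, c);
    for (int n = 0; n < N; ++n) {
      const double* On = Oc + (size_t)n * Ho * Wo;
      double* An = Ac + (size_t)n * H * W;
      for (int wo = 0; wo < Wo; ++wo) {
        const int w0 = wo * win, w1 = std::min(W, w0 + win);
        for (int ho = 0; ho < Ho; ++ho) {
          const int h0 = ho * win, h1 = std::min(H, h0 + win);
          const double g =
              On[(size_t)wo * Ho + ho] / ((w1 - w0) * (h1 - h0));
          for (int w = w0; w < w1; ++w)
            for (int h = h0; h < h1; ++h) An[(size_t)w * H + h] += g;
        }
      }
    }
  }
  return dA;
}
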