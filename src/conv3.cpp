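#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
#include <cstring>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Fast 3x3 same-padding convolution layers for channels-last
// activations (H*W*n rows, C columns; rows pixel-fastest, column-major
// over the H x W grid, then sample). The im2col patch matrix lives in a
// persistent scratch buffer (no R allocation, no GC traffic); the
// contraction itself is one BLAS dgemm. The backward pass recomputes
// the two patch matrices it needs into the same buffers and returns
// exact gradients.

static std::vector<double> buf_a;   // patch matrix of the forward input
static std::vector<double> buf_b;   // patch matrix of the upstream gradient

// assemble the (rows x 9C) patch matrix of x into buf
static void im2col3_into(const double* xp, int H, int W, int n, int C,
                         std::vector<double>& buf) {
  const int HW = H * W;
  const R_xlen_t rows = (R_xlen_t)HW * n;
  buf.resize((size_t)rows * 9 * C);
  double* pp = buf.data();
  const size_t dbl = sizeof(double);
  for (int k = 0; k < 9; ++k) {
    const int di = k % 3 - 1;
    const int dj = k / 3 - 1;
    const int lo = std::max(0, -di);
    const int hi = std::min(H, H - di);
    const int runlen = hi - lo;
    for (int c = 0; c < C; ++c) {
      double* dst0 = pp + (R_xlen_t)(k * C + c) * rows;
      const double* src0 = xp + (R_xlen_t)c * rows;
      for (int s = 0; s < n; ++s) {
        const R_xlen_t base = (R_xlen_t)s * HW;
        for (int j = 0; j < W; ++j) {
          const int jj = j + dj;
          double* dst = dst0 + base + (R_xlen_t)j * H;
          if (jj < 0 || jj >= W) { std::memset(dst, 0, (size_t)H * dbl); continue; }
          if (lo > 0) dst[0] = 0.0;
          if (hi < H) dst[H - 1] = 0.0;
          std::memcpy(dst + lo, src0 + base + (R_xlen_t)jj * H + lo + di,
                      (size_t)runlen * dbl);
        }
      }
    }
  }
}

// y (rows x cout) = P (rows x 9C) %*% t(W (cout x 9C)) + b
// [[Rcpp::export]]
NumericMatrix cpp_conv3_fw(const NumericMatrix& x, const NumericMatrix& Wm,
                           const NumericVector& b, int H, int W, int n) {
  const int C = x.ncol();
  const int cout = Wm.nrow();
  const int K = 9 * C;
  const R_xlen_t rows = (R_xlen_t)H * W * n;
  if (Wm.ncol() != K) stop("weight shape mismatch");
  im2col3_into(x.begin(), H, W, n, C, buf_a);
  NumericMatrix y = no_init((int)rows, cout);
  const double one = 1.0, zero = 0.0;
  const int m = (int)rows;
  F77_CALL(dgemm)("N", "T", &m, &cout, &K, &one, buf_a.data(), &m,
                  Wm.begin(), &cout, &zero, y.begin(), &m FCONE FCONE);
  for (int c = 0; c < cout; ++c) {
    double* yc = y.begin() + (R_xlen_t)c * rows;
    const double bc = b[c];
    for (R_xlen_t i = 0; i < rows; ++i) yc[i] += bc;
  }
  return y;
}

// gradients of the same layer: dW = t(dy) %*% P(x); db = colSums(dy);
// dx = P(dy) %*% t(flip(W)) computed via the kernel-flipped weights
// [[Rcpp::export]]
List cpp_conv3_bw(const NumericMatrix& x, const NumericMatrix& dy,
                  const NumericMatrix& Wm, int H, int W, int n,
                  bool want_dx) {
  const int C = x.ncol();
  const int cout = dy.ncol();
  const int K = 9 * C;
  const R_xlen_t rows = (R_xlen_t)H * W * n;
  const int m = (int)rows;
  const double one = 1.0, zero = 0.0;

  im2col3_into(x.begin(), H, W, n, C, buf_a);
  NumericMatrix dW = no_init(cout, K);
  F77_CALL(dgemm)("T", "N", &cout, &K, &m, &one, dy.begin(), &m,
                  buf_a.data(), &m, &zero, dW.begin(), &cout FCONE FCONE);

  NumericVector db(cout);
  for (int c = 0; c < cout; ++c) {
    const double* dc = dy.begin() + (R_xlen_t)c * rows;
    double acc = 0.0;
    for (R_xlen_t i = 0; i < rows; ++i) acc += dc[i];
    db[c] = acc;
  }

  if (!want_dx) return List::create(_["dW"] = dW, _["db"] = db);

  // flipped weights: W2 (C x 9*cout), W2[ci, co + m2*cout] = W[co, ci + (8-m2)*C]
  std::vector<double> W2((size_t)C * 9 * cout);
  for (int k = 0; k < 9; ++k)
    for (int co = 0; co < cout; ++co)
      for (int ci = 0; ci < C; ++ci)
        W2[(size_t)(k * cout + co) * C + ci] =
          Wm((R_xlen_t)co, (R_xlen_t)(8 - k) * C + ci);

  im2col3_into(dy.begin(), H, W, n, cout, buf_b);
  NumericMatrix dx = no_init(m, C);
  const int K2 = 9 * cout;
  F77_CALL(dgemm)("N", "T", &m, &C, &K2, &one, buf_b.data(), &m,
                  W2.data(), &C, &zero, dx.begin(), &m FCONE FCONE);
  return List::create(_["dW"] = dW, _["db"] = db, _["dx"] = dx);
}
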