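// Direct same-padding 3x3 convolution via BLAS dgemm on row-offset views.
//
// A feature blob dim c(H, W, B, C) flattens (column-major) so that the
// (H*W*B) x C matrix X has row index r = i + j*H + b*H*W.  Shifting a pixel
// by (di, dj) shifts r by off = di + dj*H, so the contribution of kernel
// offset (di, dj) is a dgemm on a contiguous row window of X — no im2col
// copy.  Rows whose shift crosses the canvas border pick up a wrapped
// (wrong) contribution; those rows are corrected explicitly afterwards.
// Rows whose shifted index falls outside the matrix entirely always cross
// the border too, so skipping them is exact.

#include <Rcpp.h>
#include <R_ext/BLAS.h>
using namespace Rcpp;

static inline bool bad_pixel(int i, int j, int di, int dj, int H, int W) {
  const int ii = i + di, jj = j + dj;
  return ii < 0 || ii >= H || jj < 0 || jj >= W;
}

// Repack kernel offset (di, dj) of W dim c(3,3,C,Co) into a C x Co buffer.
static void pack_wk(const double* W, int C, int Co, int di, int dj,
                    std::vector<double>& wk) {
  wk.resize((size_t)C * Co);
  const int base = (di + 1) + 3 * (dj + 1);
  for (int co = 0; co < Co; ++co)
    for (int c = 0; c < C; ++c)
      wk[c + (size_t)C * co] = W[base + 9 * c + (size_t)9 * C * co];
}

// [[Rcpp::export]]
NumericVector conv3_gemm_fwd(const NumericVector& blob,
                             const NumericVector& W,
                             const NumericVector& bias,
                             int H, int Wd, int B, int C, int Co) {
  const R_xlen_t rows = (R_xlen_t)H * Wd * B;
  NumericVector out(rows * Co);
  double* y = REAL(out);
  const double* x = REAL(blob);
  const double* w = REAL(W);
  const double* bi = REAL(bias);
  for (int co = 0; co < Co; ++co) {        // bias broadcast
    double* yc = y + (R_xlen_t)co * rows;
    const double v = bi[co];
    for (R_xlen_t r = 0; r < rows; ++r) yc[r] = v;
  }
  const int m_all = (int)rows;
  const double one = 1.0;
  std::vector<double> wk;
  for (int dj = -1; dj <= 1; ++dj) {
    for (int di = -1; di <= 1; ++di) {
      pack_wk(w, C, Co, di, dj, wk);
      const int off = di + dj * H;
      const int r0 = std::max(0, -off);
      const int r1 = m_all - std::max(0, off);
      const int m = r1 - r0;
      if (m <= 0) continue;
      F77_CALL(dgemm)("N", "N", &m, &Co, &C, &one, x + (r0 + off), &m_all,
                      wk.data(), &C, &one, y + r0, &m_all FCONE FCONE);
      if (di == 0 && dj == 0) continue;
      // subtract wrapped contributions on border rows
      for (int b = 0; b < B; ++b) {
        for (int j = 0; j < Wd; ++j) {
          for (int i = 0; i < H; ++i) {
            if (!bad_pixel(i, j, di, dj, H, Wd)) continue;
            const R_xlen_t r = i + (R_xlen_t)j * H + (R_xlen_t)b * H * Wd;
            if (r < r0 || r >= r1) continue;   // nothing was added
            const double* xr = x + (r + off);
            double* yr = y + r;
            for (int co = 0; co < Co; ++co) {
              double s = 0.0;
              const double* wc = wk.data() + (size_t)C * co;
              for (int c = 0; c < C; ++c) s += xr[(R_xlen_t)c * rows] * wc[c];
              yr[(R_xlen_t)co * rows] -= s;
            }
          }
        }
      }
    }
  }
  return out;
}

// Backward pass: given dY, the cached input blob and the kernel, produce
// dX (optional), dW and db in one sweep.
// [[Rcpp::export]]
List conv3_gemm_bwd(const NumericVector& blob,
                    const NumericVector& W,
                    const NumericVector& dY,
                    int H, int Wd, int B, int C, int Co,
                    bool need_dx) {
  const R_xlen_t rows = (R_xlen_t)H * Wd * B;
  const int m_all = (int)rows;
  const double one = 1.0, zero = 0.0;
  const double* x = REAL(blob);
  const double* w = REAL(W);
  const double* dy = REAL(dY);
  NumericVector dW((R_xlen_t)9 * C * Co);
  double* dwp = REAL(dW);
  NumericVector db(Co);
  double* dbp = REAL(db);
  for (int co = 0; co < Co; ++co) {
    const double* dyc = dy + (R_xlen_t)co * rows;
    double s = 0.0;
    for (R_xlen_t r = 0; r < rows; ++r) s += dyc[r];
    dbp[co] = s;
  }
  NumericVector dX(need_dx ? rows * C : 0);
  double* dx = need_dx ? REAL(dX) : nullptr;
  std::vector<double> wk, dwk((size_t)C * Co);
  for (int dj = -1; dj <= 1; ++dj) {
    for (int di = -1; di <= 1; ++di) {
      const int off = di + dj * H;
      const int r0 = std::max(0, -off);
      const int r1 = m_all - std::max(0, off);
      const int m = r1 - r0;
      if (m <= 0) continue;
      // dW_k = X[r0+off .. r1+off)^T . dY[r0 .. r1)
      F77_CALL(dgemm)("T", "N", &C, &Co, &m, &one, x + (r0 + off), &m_all,
                      dy + r0, &m_all, &zero, dwk.data(), &C FCONE FCONE);
      if (need_dx) {
        pack_wk(w, C, Co, di, dj, wk);
        // dX[r+off, ] += dY[r, ] . Wk^T
        F77_CALL(dgemm)("N", "T", &m, &C, &Co, &one, dy + r0, &m_all,
                        wk.data(), &C, &one, dx + (r0 + off), &m_all
                        FCONE FCONE);
      }
      if (!(di == 0 && dj == 0)) {
        for (int b = 0; b < B; ++b) {
          for (int j = 0; j < Wd; ++j) {
            for (int i = 0; i < H; ++i) {
              if (!bad_pixel(i, j, di, dj, H, Wd)) continue;
              const R_xlen_t r = i + (R_xlen_t)j * H + (R_xlen_t)b * H * Wd;
              if (r < r0 || r >= r1) continue;
              const double* xr = x + (r + off);
              const double* dyr = dy + r;
              for (int co = 0; co < Co; ++co) {       // rank-1 removal
                const double g = dyr[(R_xlen_t)co * rows];
                double* dcol = dwk.data() + (size_t)C * co;
                for (int c = 0; c < C; ++c)
                  dcol[c] -= xr[(R_xlen_t)c * rows] * g;
              }
              if (need_dx) {
                double* dxr = dx + (r + off);
                for (int c = 0; c < C; ++c) {
                  double s = 0.0;
                  const double* wr = wk.data() + c;
                  for (int co = 0; co < Co; ++co)
                    s += dyr[(R_xlen_t)co * rows] * wr[(size_t)C * co];
                  dxr[(R_xlen_t)c * rows] -= s;
                }
              }
            }
          }
        }
      }
      const int base = (di + 1) + 3 * (dj + 1);       // scatter dW_k
      for (int co = 0; co < Co; ++co)
        for (int c = 0; c < C; ++c)
          dwp[base + 9 * c + (size_t)9 * C * co] = dwk[c + (size_t)C * co];
    }
  }
  return List::create(_["dx"] = dX, _["dW"] = dW, _["db"] = db);
}
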