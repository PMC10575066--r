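#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Feature blobs are 4-d arrays with dim c(H, W, B, C): column-major, so the
// linear index of (i, j, b, c) (0-based) is i + j*H + b*H*W + c*H*W*B.

// 2x2 max pooling with stride 2.  Returns the pooled blob and the 1-based
// linear index of each winning input element (windows are disjoint, so the
// backward pass is a plain scatter).  Ties go to the earliest element in
// column-major order, which keeps the pass deterministic.
// [[Rcpp::export]]
List maxpool2x2(const NumericVector& blob, int H, int W, int B, int C) {
  const int Ho = H / 2, Wo = W / 2;
  const R_xlen_t n = (R_xlen_t)Ho * Wo * B * C;
  NumericVector out(n);
  NumericVector arg(n);
  const double* x = REAL(blob);
  double* o = REAL(out);
  double* a = REAL(arg);
  R_xlen_t idx = 0;
  const R_xlen_t nplanes = (R_xlen_t)B * C;
  for (R_xlen_t bc = 0; bc < nplanes; ++bc) {
    const double* xp = x + bc * H * W;
    const R_xlen_t base = bc * H * W;
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        const R_xlen_t p00 = (R_xlen_t)(2 * j) * H + 2 * i;
        R_xlen_t best = p00;
        if (xp[p00 + 1] > xp[best]) best = p00 + 1;
        if (xp[p00 + H] > xp[best]) best = p00 + H;
        if (xp[p00 + H + 1] > xp[best]) best = p00 + H + 1;
        o[idx] = xp[best];
        a[idx] = (double)(base + best + 1);
        ++idx;
      }
    }
  }
  return List::create(_["out"] = out, _["argmax"] = arg);
}
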