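#include <Rcpp.h>
using namespace Rcpp;

// Stamp filled discs (max with current canvas) at the given centers/radii.
// Centers are 1-based row/col coordinates; equivalent to repeated
// per-disc max-stamping but in one pass.
// [[Rcpp::export]]
NumericMatrix cpp_stamp_discs(NumericMatrix canvas, NumericVector cr,
                              NumericVector cc, NumericVector radius,
                              double value = 1.0) {
  const int H = canvas.nrow(), W = canvas.ncol();
  NumericMatrix out = clone(canvas);
  for (int k = 0; k < cr.size(); ++k) {
    double r = radius[k], r2 = r * r;
    int r0 = std::max(1, (int)std::floor(cr[k] - r));
    int r1 = std::min(H, (int)std::ceil(cr[k] + r));
    int c0 = std::max(1, (int)std::floor(cc[k] - r));
    int c1 = std::min(W, (int)std::ceil(cc[k] + r));
    for (int c = c0; c <= c1; ++c) {
      double dc = c - cc[k];
      for (int rr = r0; rr <= r1; ++rr) {
        double dr = rr - cr[k];
        if (dr * dr + dc * dc <= r2 && out(rr - 1, c - 1) < value)
          out(rr - 1, c - 1) = value;
      }
    }
  }
  return out;
}
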