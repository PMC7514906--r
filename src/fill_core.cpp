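#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Ring-by-ring constrained fill.
//
// Pixels where `known` is TRUE keep their values.  Unknown pixels are filled
// outward in rings: every unknown pixel 8-adjacent to at least one known
// pixel receives the mean of its currently-known neighbours (values from the
// same ring are not used within that ring), then the whole ring is marked
// known and the process repeats until the frame is full.  Used both for
// extending the retinal background outside the FOV and for inpainting the
// bright-border artifact region.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
NumericVector cpp_ring_fill(NumericVector img, LogicalVector known, int H, int W) {
  const R_xlen_t plane = (R_xlen_t)H * W;
  const int nch = img.size() / plane;
  NumericVector out = clone(img);
  std::vector<char> kn(plane);
  for (R_xlen_t p = 0; p < plane; ++p) kn[p] = known[p] ? 1 : 0;

  std::vector<R_xlen_t> frontier;
  frontier.reserve(plane / 4);
  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

  bool progress = true;
  while (progress) {
    progress = false;
    frontier.clear();
    for (int c = 0; c < W; ++c) {
      for (int r = 0; r < H; ++r) {
        R_xlen_t p = r + (R_xlen_t)c * H;
        if (kn[p]) continue;
        bool adj = false;
        for (int k = 0; k < 8 && !adj; ++k) {
          int r2 = r + dr[k], c2 = c + dc[k];
          if (r2 >= 0 && r2 < H && c2 >= 0 && c2 < W && kn[r2 + (R_xlen_t)c2 * H])
            adj = true;
        }
        if (adj) frontier.push_back(p);
      }
    }
    if (frontier.empty()) break;
    for (R_xlen_t p : frontier) {
      int r = (int)(p % H), c = (int)(p / H);
      for (int ch = 0; ch < nch; ++ch) {
        double s = 0.0; int cnt = 0;
        for (int k = 0; k < 8; ++k) {
          int r2 = r + dr[k], c2 = c + dc[k];
          if (r2 < 0 || r2 >= H || c2 < 0 || c2 >= W) continue;
          R_xlen_t q = r2 + (R_xlen_t)c2 * H;
          if (kn[q]) { s += out[q + ch * plane]; ++cnt; }
        }
        out[p + ch * plane] = s / cnt;
      }
    }
    for (R_xlen_t p : frontier) kn[p] = 1;
    progress = true;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Greyscale morphological reconstruction by dilation, 8-connectivity.
//
// Repeated raster forward/backward sweeps propagate marker values under the
// ceiling `mask` until stable (marker is first clamped to marker <= mask).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
NumericMatrix cpp_reconstruct_dilation(NumericMatrix marker, NumericMatrix mask) {
  const int H = marker.nrow(), W = marker.ncol();
  NumericMatrix J(H, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r)
      J(r, c) = std::min(marker(r, c), mask(r, c));

  bool changed = true;
  int sweeps = 0;
  while (changed && sweeps < 2000) {
    changed = false;
    ++sweeps;
    // forward sweep: N, W, NW, NE neighbours
    for (int c = 0; c < W; ++c) {
      for (int r = 0; r < H; ++r) {
        double v = J(r, c);
        if (r > 0) v = std::max(v, J(r - 1, c));
        if (c > 0) v = std::max(v, J(r, c - 1));
        if (r > 0 && c > 0) v = std::max(v, J(r - 1, c - 1));
        if (r < H - 1 && c > 0) v = std::max(v, J(r + 1, c - 1));
        v = std::min(v, mask(r, c));
        if (v > J(r, c)) { J(r, c) = v; changed = true; }
      }
    }
    // backward sweep: S, E, SE, SW neighbours
    for (int c = W - 1; c >= 0; --c) {
      for (int r = H - 1; r >= 0; --r) {
        double v = J(r, c);
        if (r < H - 1) v = std::max(v, J(r + 1, c));
        if (c < W - 1) v = std::max(v, J(r, c + 1));
        if (r < H - 1 && c < W - 1) v = std::max(v, J(r + 1, c + 1));
        if (r > 0 && c < W - 1) v = std::max(v, J(r - 1, c + 1));
        v = std::min(v, mask(r, c));
        if (v > J(r, c)) { J(r, c) = v; changed = true; }
      }
    }
  }
  return J;
}
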