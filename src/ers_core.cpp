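#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// t*log(t) with the 0*log(0) := 0 convention (natural log).
static inline double xlogx(double t) { return (t <= 0.0) ? 0.0 : t * std::log(t); }

// ---------------------------------------------------------------------------
// 8-neighbour lattice graph over a 3-channel darkness map.
//
// Vertices are pixels in column-major order (idx = row + col * H, 0-based).
// For every pixel, edges to its S, E, SE and NE neighbours are emitted in
// that order while scanning columns outer, rows inner; this fixed edge
// enumeration is what the greedy tie-break (lowest edge index) refers to.
// d(vi, vj) = Euclidean distance of the two 0-255-scaled 3-channel values,
// multiplied by the spatial distance (1 or sqrt(2));  w = exp(-d^2 / (2*sigma)),
// floored at 1e-12 so vertex strengths stay strictly positive.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_lattice_graph(NumericVector dark, int H, int W, double sigma) {
  if (sigma <= 0.0) stop("sigma must be > 0");
  const double *d0 = REAL(dark);
  const R_xlen_t plane = (R_xlen_t)H * W;
  const int dr[4] = {1, 0, 1, -1};
  const int dc[4] = {0, 1, 1, 1};
  const double sp[4] = {1.0, 1.0, M_SQRT2, M_SQRT2};

  R_xlen_t nmax = 4 * plane;
  std::vector<int> ei, ej;
  std::vector<double> ew;
  ei.reserve(nmax); ej.reserve(nmax); ew.reserve(nmax);
  NumericVector wi(plane);

  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      R_xlen_t p = r + (R_xlen_t)c * H;
      for (int k = 0; k < 4; ++k) {
        int r2 = r + dr[k], c2 = c + dc[k];
        if (r2 < 0 || r2 >= H || c2 >= W) continue;
        R_xlen_t q = r2 + (R_xlen_t)c2 * H;
        double s = 0.0;
        for (int ch = 0; ch < 3; ++ch) {
          double dv = 255.0 * (d0[p + ch * plane] - d0[q + ch * plane]);
          s += dv * dv;
        }
        double dist2 = s * sp[k] * sp[k];           // (d * spatial)^2
        double w = std::exp(-dist2 / (2.0 * sigma));
        if (w < 1e-12) w = 1e-12;
        ei.push_back((int)p);
        ej.push_back((int)q);
        ew.push_back(w);
        wi[p] += w; wi[q] += w;
      }
    }
  }
  double total = 0.0;
  for (R_xlen_t p = 0; p < plane; ++p) total += wi[p];
  List out;
  out["ei"] = wrap(ei);
  out["ej"] = wrap(ej);
  out["ew"] = wrap(ew);
  out["wi"] = wi;
  out["n_vertices"] = (double)plane;
  out["total_weight"] = total;
  out["sigma"] = sigma;
  return out;
}

struct QEntry {
  double gain; int edge;
  bool operator<(const QEntry &o) const {
    if (gain != o.gain) return gain < o.gain;   // max-heap on gain
    return edge > o.edge;                       // then lowest edge index first
  }
};

struct DSU {
  std::vector<int> parent, size;
  DSU(int n) : parent(n), size(n, 1) { for (int i = 0; i < n; ++i) parent[i] = i; }
  int find(int x) { while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; } return x; }
  void unite(int a, int b) {
    a = find(a); b = find(b);
    if (size[a] < size[b]) std::swap(a, b);
    parent[b] = a; size[a] += size[b];
  }
};

// ---------------------------------------------------------------------------
// Lazy greedy maximization of H(A) + gamma * B(A).
//
// Starts from the empty selection (every vertex a singleton, self-loop
// probability 1); repeatedly adds the inter-component edge with the largest
// objective gain until exactly K components remain.  Both marginal gains are
// exact closed forms:
//   dH(e=(i,j,w)) = mu_i [xlogx(L_i) - xlogx(L_i - c_i) - xlogx(c_i)] + (j term)
//     with c_i = w / w_i the transition probability of the new edge and L_i
//     the current self-loop probability of vertex i (monotonically consumed);
//   dB(merge a,b)  = xlogx(a/n) + xlogx(b/n) - xlogx((a+b)/n) + 1.
// Both shrink as the selection grows (submodularity), so stale heap entries
// are upper bounds and the standard lazy re-evaluation on pop is exact
// greedy.  Ties break toward the lowest edge index.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_ers_greedy(IntegerVector ei, IntegerVector ej, NumericVector ew,
                    NumericVector wi, double total_w, double gamma,
                    int n, int K, bool trace = false) {
  const int m = ei.size();
  if (K < 1 || K > n) stop("K must be between 1 and the number of vertices");
  DSU dsu(n);
  std::vector<double> loopP(n, 1.0);
  const double invW = 1.0 / total_w;
  const double invN = 1.0 / n;

  auto gainH = [&](int e) {
    int i = ei[e], j = ej[e];
    double ci = ew[e] / wi[i], cj = ew[e] / wi[j];
    double Li = loopP[i], Lj = loopP[j];
    double gi = xlogx(Li) - xlogx(std::max(0.0, Li - ci)) - xlogx(ci);
    double gj = xlogx(Lj) - xlogx(std::max(0.0, Lj - cj)) - xlogx(cj);
    return (wi[i] * invW) * gi + (wi[j] * invW) * gj;
  };
  auto gainB = [&](int e) {
    int a = dsu.size[dsu.find(ei[e])], b = dsu.size[dsu.find(ej[e])];
    return xlogx(a * invN) + xlogx(b * invN) - xlogx((a + b) * invN) + 1.0;
  };

  std::priority_queue<QEntry> pq;
  for (int e = 0; e < m; ++e)
    pq.push({gainH(e) + gamma * gainB(e), e});

  int ncomp = n;
  std::vector<int> added; added.reserve(n - K);
  std::vector<double> dH, dB;
  while (ncomp > K && !pq.empty()) {
    QEntry top = pq.top(); pq.pop();
    int e = top.edge;
    if (dsu.find(ei[e]) == dsu.find(ej[e])) continue;   // internal edge: never added
    double gh = gainH(e), gb = gainB(e);
    double g = gh + gamma * gb;
    if (!pq.empty()) {
      const QEntry &nxt = pq.top();
      bool still_best = (g > nxt.gain) || (g == nxt.gain && e < nxt.edge);
      if (!still_best) { pq.push({g, e}); continue; }
    }
    // accept
    int i = ei[e], j = ej[e];
    loopP[i] = std::max(0.0, loopP[i] - ew[e] / wi[i]);
    loopP[j] = std::max(0.0, loopP[j] - ew[e] / wi[j]);
    dsu.unite(i, j);
    --ncomp;
    added.push_back(e);
    if (trace) { dH.push_back(gh); dB.push_back(gb); }
  }
  if (ncomp > K) stop("graph is too disconnected to reach K components");

  // labels 1..K in order of first appearance (vertex scan order)
  IntegerVector labels(n);
  std::vector<int> lab_of(n, 0);
  int next = 0;
  for (int v = 0; v < n; ++v) {
    int r = dsu.find(v);
    if (lab_of[r] == 0) lab_of[r] = ++next;
    labels[v] = lab_of[r];
  }
  List out = List::create(_["labels"] = labels, _["n_components"] = next,
                          _["selected"] = wrap(added));
  if (trace) { out["dH"] = wrap(dH); out["dB"] = wrap(dB); }
  return out;
}
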