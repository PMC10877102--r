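#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Two-pass union-find connected-component labeling, 8-connectivity.
// Nonzero entries are foreground. Labels are 1..K in raster-scan order of
// each component's first pixel.
// [[Rcpp::export(name = ".label8")]]
IntegerMatrix label8(const IntegerMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> parent(1, 0);
  auto find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  auto unite = [&](int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  };
  int next = 0;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (mask(r, c) == 0) continue;
      int best = 0;
      // previously-scanned 8-neighbors in column-major order:
      // (r-1, c), (r-1, c-1), (r, c-1), (r+1, c-1)
      const int nr[4] = { r - 1, r - 1, r,     r + 1 };
      const int nc[4] = { c,     c - 1, c - 1, c - 1 };
      for (int k = 0; k < 4; ++k) {
        if (nr[k] < 0 || nr[k] >= H || nc[k] < 0) continue;
        const int l = lab(nr[k], nc[k]);
        if (l > 0) {
          if (best == 0) best = l;
          else unite(best, l);
        }
      }
      if (best == 0) {
        best = ++next;
        parent.push_back(best);
      }
      lab(r, c) = best;
    }
  }
  // flatten and renumber in raster order of first occurrence
  std::vector<int> remap(next + 1, 0);
  int K = 0;
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r)
      if (lab(r, c) > 0) {
        const int root = find(lab(r, c));
        if (remap[root] == 0) remap[root] = ++K;
        lab(r, c) = remap[root];
      }
  return lab;
}

// Hungarian algorithm (augmenting paths with potentials) on a square cost
// matrix; returns for each row the assigned column (1-based).
// [[Rcpp::export(name = ".hungarian")]]
IntegerVector hungarian(const NumericMatrix& cost) {
  const int n = cost.nrow();
  if (n == 0) return IntegerVector(0);
  const double INF = 1e100;
  std::vector<double> u(n + 1, 0.0), v(n + 1, 0.0);
  std::vector<int> p(n + 1, 0), way(n + 1, 0);
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(n + 1, INF);
    std::vector<char> used(n + 1, 0);
    do {
      used[j0] = 1;
      const int i0 = p[j0];
      double delta = INF;
      int j1 = -1;
      for (int j = 1; j <= n; ++j) {
        if (used[j]) continue;
        const double cur = cost(i0 - 1, j - 1) - u[i0] - v[j];
        if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
        if (minv[j] < delta) { delta = minv[j]; j1 = j; }
      }
      for (int j = 0; j <= n; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do {
      const int j1 = way[j0];
      p[j0] = p[j1];
      j0 = j1;
    } while (j0);
  }
  IntegerVector ans(n);
  for (int j = 1; j <= n; ++j)
    if (p[j] > 0) ans[p[j] - 1] = j;
  return ans;
}
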