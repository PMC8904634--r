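#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// Union-find with path halving.
static int uf_find(std::vector<int>& parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

static void uf_union(std::vector<int>& parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra < rb) parent[rb] = ra; else if (rb < ra) parent[ra] = rb;
}

// Two-pass connected-component labeling of a 0/1 matrix.
// connectivity: 4 or 8. Returns an integer matrix with labels 1..n
// (compact, in raster order of first appearance), background 0.
// [[Rcpp::export]]
IntegerMatrix cc_label_cpp(const IntegerMatrix& mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> parent;
  parent.reserve(256);
  int next = 0;  // provisional labels are 0-based internally

  // First pass: column-major scan; prior neighbours are up, left, and (for
  // 8-connectivity) the two left diagonals.
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (mask(r, c) == 0) continue;
      int best = -1;
      int cand[4][2] = {{r - 1, c}, {r, c - 1}, {r - 1, c - 1}, {r + 1, c - 1}};
      int ncand = (connectivity == 8) ? 4 : 2;
      int found[4];
      int nfound = 0;
      for (int k = 0; k < ncand; ++k) {
        int rr = cand[k][0], cc = cand[k][1];
        if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
        if (mask(rr, cc) != 0) {
          int l = lab(rr, cc) - 1;
          found[nfound++] = l;
          if (best < 0 || l < best) best = l;
        }
      }
      if (best < 0) {
        parent.push_back(next);
        lab(r, c) = ++next;  // stored 1-based
      } else {
        lab(r, c) = best + 1;
        for (int k = 0; k < nfound; ++k) uf_union(parent, best, found[k]);
      }
    }
  }

  // Resolve provisional labels to compact 1..n in raster (column-major) order.
  std::vector<int> compact(parent.size(), 0);
  int n = 0;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (mask(r, c) == 0) continue;
      int root = uf_find(parent, lab(r, c) - 1);
      if (compact[root] == 0) compact[root] = ++n;
      lab(r, c) = compact[root];
    }
  }
  return lab;
}
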