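#include <Rcpp.h>
using namespace Rcpp;

// Two-pass connected-component labeling with 8-connectivity on a binary
// matrix (column-major). Background = 0; components numbered 1..k in
// first-encounter order after relabeling.

static int find_root(std::vector<int> &parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

// [[Rcpp::export(name = ".label8")]]
IntegerMatrix label8(const LogicalMatrix &img) {
  const int nr = img.nrow(), nc = img.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent(1, 0); // parent[0] unused
  int next = 1;

  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!img(r, c)) continue;
      // previously visited 8-neighbors: (r-1,c), (r-1,c-1), (r,c-1), (r+1,c-1)
      int neigh[4];
      int nn = 0;
      if (r > 0 && img(r - 1, c)) neigh[nn++] = lab(r - 1, c);
      if (c > 0) {
        if (r > 0 && img(r - 1, c - 1)) neigh[nn++] = lab(r - 1, c - 1);
        if (img(r, c - 1)) neigh[nn++] = lab(r, c - 1);
        if (r + 1 < nr && img(r + 1, c - 1)) neigh[nn++] = lab(r + 1, c - 1);
      }
      if (nn == 0) {
        parent.push_back(next);
        lab(r, c) = next++;
      } else {
        int m = find_root(parent, neigh[0]);
        for (int k = 1; k < nn; ++k) {
          int rt = find_root(parent, neigh[k]);
          if (rt < m) { parent[m] = rt; m = rt; }
          else if (rt > m) parent[rt] = m;
        }
        lab(r, c) = m;
      }
    }
  }

  // relabel roots consecutively in scan order
  std::vector<int> newlab(parent.size(), 0);
  int k = 0;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      int l = lab(r, c);
      if (!l) continue;
      int rt = find_root(parent, l);
      if (!newlab[rt]) newlab[rt] = ++k;
      lab(r, c) = newlab[rt];
    }
  return lab;
}
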