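#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Two-pass connected-component labelling with union-find.
// connectivity: 4 or 8. Labels are 1..k in raster-scan discovery order,
// relabelled to consecutive integers.

static int uf_find(std::vector<int>& parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

static void uf_union(std::vector<int>& parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent;
  parent.push_back(0); // label 0 = background
  int next = 1;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j)) continue;
      int up   = (i > 0 && mask(i - 1, j)) ? lab(i - 1, j) : 0;
      int left = (j > 0 && mask(i, j - 1)) ? lab(i, j - 1) : 0;
      int ul = 0, dl = 0;
      if (connectivity == 8) {
        ul = (i > 0 && j > 0 && mask(i - 1, j - 1)) ? lab(i - 1, j - 1) : 0;
        dl = (i < nr - 1 && j > 0 && mask(i + 1, j - 1)) ? lab(i + 1, j - 1) : 0;
      }
      int nb[4] = {up, left, ul, dl};
      int lmin = 0;
      for (int k = 0; k < 4; ++k)
        if (nb[k] > 0 && (lmin == 0 || nb[k] < lmin)) lmin = nb[k];
      if (lmin == 0) {
        lab(i, j) = next;
        parent.push_back(next);
        ++next;
      } else {
        lab(i, j) = lmin;
        for (int k = 0; k < 4; ++k)
          if (nb[k] > 0) uf_union(parent, nb[k], lmin);
      }
    }
  }
  // resolve + compact labels
  std::vector<int> remap(next, 0);
  int out = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (lab(i, j) > 0) {
        int r = uf_find(parent, lab(i, j));
        if (remap[r] == 0) remap[r] = ++out;
        lab(i, j) = remap[r];
      }
  lab.attr("n_components") = out;
  return lab;
}

// Square-window median filter with edge replication (the "fine filter").
// [[Rcpp::export]]
NumericMatrix median_filter_cpp(NumericMatrix img, int radius) {
  if (radius < 1) stop("radius must be >= 1");
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  int w = 2 * radius + 1;
  std::vector<double> buf(w * w);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int n = 0;
      for (int dj = -radius; dj <= radius; ++dj) {
        int jj = std::min(std::max(j + dj, 0), nc - 1);
        for (int di = -radius; di <= radius; ++di) {
          int ii = std::min(std::max(i + di, 0), nr - 1);
          buf[n++] = img(ii, jj);
        }
      }
      std::nth_element(buf.begin(), buf.begin() + n / 2, buf.begin() + n);
      out(i, j) = buf[n / 2]; // n is odd (w^2), so this is the exact median
    }
  }
  return out;
}
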