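#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Mirror (reflect-with-edge-duplication) index: ... c b a | a b c ... | c b a
static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// Local mean and population standard deviation in a circular (disc) window of
// the given pixel radius, with reflective border padding. Used by the
// Phansalkar local adaptive threshold.
// [[Rcpp::export]]
List cpp_local_mean_sd(NumericMatrix img, int radius) {
  int nr = img.nrow(), nc = img.ncol();
  // precompute disc offsets
  std::vector<int> dr, dc;
  int r2 = radius * radius;
  for (int a = -radius; a <= radius; ++a)
    for (int b = -radius; b <= radius; ++b)
      if (a * a + b * b <= r2) { dr.push_back(a); dc.push_back(b); }
  int nwin = (int)dr.size();
  NumericMatrix m(nr, nc), s(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double sum = 0.0, sumsq = 0.0;
      for (int k = 0; k < nwin; ++k) {
        int ii = reflect_idx(i + dr[k], nr);
        int jj = reflect_idx(j + dc[k], nc);
        double v = img(ii, jj);
        sum += v; sumsq += v * v;
      }
      double mu = sum / nwin;
      double var = sumsq / nwin - mu * mu;
      if (var < 0) var = 0;
      m(i, j) = mu;
      s(i, j) = std::sqrt(var);
    }
  }
  return List::create(_["mean"] = m, _["sd"] = s);
}

// Binary median (majority vote) over a disc window with reflective padding.
// [[Rcpp::export]]
IntegerMatrix cpp_median_disc(IntegerMatrix mask, int radius) {
  int nr = mask.nrow(), nc = mask.ncol();
  std::vector<int> dr, dc;
  int r2 = radius * radius;
  for (int a = -radius; a <= radius; ++a)
    for (int b = -radius; b <= radius; ++b)
      if (a * a + b * b <= r2) { dr.push_back(a); dc.push_back(b); }
  int nwin = (int)dr.size();
  IntegerMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int cnt = 0;
      for (int k = 0; k < nwin; ++k) {
        int ii = reflect_idx(i + dr[k], nr);
        int jj = reflect_idx(j + dc[k], nc);
        if (mask(ii, jj) != 0) ++cnt;
      }
      out(i, j) = (2 * cnt > nwin) ? 1 : 0;
    }
  }
  return out;
}

// 8-connected labeling of a binary mask; labels are consecutive positive
// integers in raster order of first appearance.
// [[Rcpp::export]]
IntegerMatrix cpp_label8(IntegerMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  int n = nr * nc;
  std::vector<int> lab(n, 0);
  std::vector<int> parent;
  parent.push_back(0); // label 0 unused
  // find with path compression
  struct UF {
    std::vector<int>& p;
    UF(std::vector<int>& p_) : p(p_) {}
    int find(int x) { while (p[x] != x) { p[x] = p[p[x]]; x = p[x]; } return x; }
    void unite(int a, int b) { a = find(a); b = find(b); if (a < b) p[b] = a; else if (b < a) p[a] = b; }
  } uf(parent);
  int next = 1;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (mask(i, j) == 0) continue;
      int idx = j * nr + i;
      // previously-visited 8-neighbors in column-major raster order
      int best = 0;
      int ni[4] = { i - 1, i - 1, i, i + 1 };
      int nj[4] = { j,     j - 1, j - 1, j - 1 };
      for (int k = 0; k < 4; ++k) {
        if (ni[k] < 0 || ni[k] >= nr || nj[k] < 0 || nj[k] >= nc) continue;
        int l = lab[nj[k] * nr + ni[k]];
        if (l > 0) {
          if (best == 0) best = l; else uf.unite(best, l);
        }
      }
      if (best == 0) { parent.push_back(next); lab[idx] = next; ++next; }
      else lab[idx] = best;
    }
  }
  // flatten and renumber consecutively in order of first appearance
  std::vector<int> remap(next, 0);
  int k = 0;
  IntegerMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int l = lab[j * nr + i];
      if (l == 0) { out(i, j) = 0; continue; }
      int root = uf.find(l);
      if (remap[root] == 0) remap[root] = ++k;
      out(i, j) = remap[root];
    }
  }
  return out;
}

// Separable Gaussian blur with reflective border padding; sigma in pixels.
// [[Rcpp::export]]
NumericMatrix cpp_gaussian_blur(NumericMatrix img, double sigma) {
  int nr = img.nrow(), nc = img.ncol();
  int radius = std::max(1, (int)std::ceil(4.0 * sigma));
  std::vector<double> kern(2 * radius + 1);
  double ksum = 0.0;
  for (int k = -radius; k <= radius; ++k) {
    double v = std::exp(-0.5 * k * k / (sigma * sigma));
    kern[k + radius] = v; ksum += v;
  }
  for (size_t k = 0; k < kern.size(); ++k) kern[k] /= ksum;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int k = -radius; k <= radius; ++k)
        acc += kern[k + radius] * img(reflect_idx(i + k, nr), j);
      tmp(i, j) = acc;
    }
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int k = -radius; k <= radius; ++k)
        acc += kern[k + radius] * tmp(i, reflect_idx(j + k, nc));
      out(i, j) = acc;
    }
  return out;
}

// Assign watershed separation lines to background: a labeled pixel becomes a
// line pixel when an 8-neighbor carries a different, smaller positive label.
// [[Rcpp::export]]
IntegerMatrix cpp_watershed_lines(IntegerMatrix labels) {
  int nr = labels.nrow(), nc = labels.ncol();
  IntegerMatrix out = clone(labels);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int l = labels(i, j);
      if (l <= 0) continue;
      bool line = false;
      for (int a = -1; a <= 1 && !line; ++a) {
        for (int b = -1; b <= 1 && !line; ++b) {
          if (a == 0 && b == 0) continue;
          int ii = i + a, jj = j + b;
          if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
          int m = labels(ii, jj);
          if (m > 0 && m < l) line = true;
        }
      }
      if (line) out(i, j) = 0;
    }
  }
  return out;
}
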