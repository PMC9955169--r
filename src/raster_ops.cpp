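#include <Rcpp.h>
#include <queue>
#include <algorithm>
using namespace Rcpp;

// Low-level raster primitives shared by the preprocessing and edge-detection
// stages.  All filters use cross-correlation (filter2 convention) and operate
// on plain numeric matrices; S4 wrapping happens on the R side.

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// 2-D cross-correlation, output same size as input.
// pad = 0: zero padding outside the frame; pad = 1: edge replication.
// [[Rcpp::export]]
NumericMatrix conv2_rcpp(NumericMatrix x, NumericMatrix k, int pad) {
  int nr = x.nrow(), nc = x.ncol();
  int kr = k.nrow(), kc = k.ncol();
  int cr = kr / 2, cc = kc / 2;
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int kj = 0; kj < kc; ++kj) {
        int sj = j + kj - cc;
        for (int ki = 0; ki < kr; ++ki) {
          int si = i + ki - cr;
          double v;
          if (si < 0 || si >= nr || sj < 0 || sj >= nc) {
            if (pad == 1)
              v = x(clampi(si, 0, nr - 1), clampi(sj, 0, nc - 1));
            else
              v = 0.0;
          } else {
            v = x(si, sj);
          }
          acc += v * k(ki, kj);
        }
      }
      out(i, j) = acc;
    }
  }
  return out;
}

// Square median filter with edge-replication padding; w must be odd.
// [[Rcpp::export]]
NumericMatrix median_filter_rcpp(NumericMatrix x, int w) {
  int nr = x.nrow(), nc = x.ncol();
  int h = w / 2;
  NumericMatrix out(nr, nc);
  std::vector<double> buf(w * w);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int n = 0;
      for (int dj = -h; dj <= h; ++dj)
        for (int di = -h; di <= h; ++di)
          buf[n++] = x(clampi(i + di, 0, nr - 1), clampi(j + dj, 0, nc - 1));
      std::nth_element(buf.begin(), buf.begin() + n / 2, buf.begin() + n);
      out(i, j) = buf[n / 2];  // odd window: exact middle order statistic
    }
  }
  return out;
}

// Binary erosion (erode = true) or dilation over an arbitrary structuring
// element (logical matrix, odd dimensions).  Outside the frame counts as
// background.
// [[Rcpp::export]]
LogicalMatrix morph_rcpp(LogicalMatrix x, LogicalMatrix se, bool erode) {
  int nr = x.nrow(), nc = x.ncol();
  int kr = se.nrow(), kc = se.ncol();
  int cr = kr / 2, cc = kc / 2;
  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      bool hit = erode;  // erosion: AND over SE; dilation: OR over SE
      for (int kj = 0; kj < kc && (erode ? hit : !hit); ++kj) {
        int sj = j + kj - cc;
        for (int ki = 0; ki < kr && (erode ? hit : !hit); ++ki) {
          if (!se(ki, kj)) continue;
          int si = i + ki - cr;
          bool v = (si >= 0 && si < nr && sj >= 0 && sj < nc) ? (bool)x(si, sj) : false;
          if (erode) hit = hit && v; else hit = hit || v;
        }
      }
      out(i, j) = hit;
    }
  }
  return out;
}

// Connected-component labelling by breadth-first search.
// connectivity is 4 or 8; background pixels get label 0.
// [[Rcpp::export]]
IntegerMatrix label_components_rcpp(LogicalMatrix x, int connectivity) {
  int nr = x.nrow(), nc = x.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  const int dx8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dy8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  int ndir = (connectivity == 8) ? 8 : 4;
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!x(i, j) || lab(i, j) != 0) continue;
      lab(i, j) = ++next;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        std::pair<int, int> p = q.front(); q.pop();
        for (int d = 0; d < ndir; ++d) {
          int ni = p.first + dx8[d], nj = p.second + dy8[d];
          if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
          if (x(ni, nj) && lab(ni, nj) == 0) {
            lab(ni, nj) = next;
            q.push(std::make_pair(ni, nj));
          }
        }
      }
    }
  }
  return lab;
}

// Fill enclosed background regions: flood-fill the background (4-connected)
// from the frame border; anything neither foreground nor reachable is a hole.
// [[Rcpp::export]]
LogicalMatrix fill_holes_rcpp(LogicalMatrix x) {
  int nr = x.nrow(), nc = x.ncol();
  LogicalMatrix reach(nr, nc);
  std::fill(reach.begin(), reach.end(), false);
  std::queue<std::pair<int, int> > q;
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      bool border = (i == 0 || i == nr - 1 || j == 0 || j == nc - 1);
      if (border && !x(i, j) && !reach(i, j)) {
        reach(i, j) = true;
        q.push(std::make_pair(i, j));
      }
    }
  }
  const int dx[4] = {-1, 1, 0, 0};
  const int dy[4] = {0, 0, -1, 1};
  while (!q.empty()) {
    std::pair<int, int> p = q.front(); q.pop();
    for (int d = 0; d < 4; ++d) {
      int ni = p.first + dx[d], nj = p.second + dy[d];
      if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
      if (!x(ni, nj) && !reach(ni, nj)) {
        reach(ni, nj) = true;
        q.push(std::make_pair(ni, nj));
      }
    }
  }
  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      out(i, j) = x(i, j) || !reach(i, j);
  return out;
}
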