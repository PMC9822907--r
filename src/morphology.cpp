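#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Zhang-Suen thinning of a binary mask (rows x cols, 1 = foreground).
// Returns the 8-connected one-pixel-wide skeleton.
// [[Rcpp::export(name = ".cpp_thin")]]
IntegerMatrix cpp_thin(IntegerMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix img(clone(mask));

  // neighbour offsets P2..P9: N, NE, E, SE, S, SW, W, NW (row, col)
  const int dr[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  const int dc[8] = {0, 1, 1, 1, 0, -1, -1, -1};

  bool changed = true;
  std::vector<std::pair<int,int> > to_del;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      to_del.clear();
      for (int r = 0; r < nr; ++r) {
        for (int c = 0; c < nc; ++c) {
          if (!img(r, c)) continue;
          int p[8];
          for (int k = 0; k < 8; ++k) {
            int rr = r + dr[k], cc = c + dc[k];
            p[k] = (rr >= 0 && rr < nr && cc >= 0 && cc < nc) ? img(rr, cc) : 0;
          }
          int b = 0, a = 0;
          for (int k = 0; k < 8; ++k) {
            b += p[k];
            if (p[k] == 0 && p[(k + 1) % 8] == 1) ++a;
          }
          if (b < 2 || b > 6 || a != 1) continue;
          bool cond;
          if (pass == 0)
            cond = (p[0] * p[2] * p[4] == 0) && (p[2] * p[4] * p[6] == 0);
          else
            cond = (p[0] * p[2] * p[6] == 0) && (p[0] * p[4] * p[6] == 0);
          if (cond) to_del.push_back(std::make_pair(r, c));
        }
      }
      if (!to_del.empty()) changed = true;
      for (size_t i = 0; i < to_del.size(); ++i)
        img(to_del[i].first, to_del[i].second) = 0;
    }
  }
  return img;
}

// Local thickness: at each foreground pixel, the diameter (in pixels) of
// the largest disk fully inside the foreground that contains the pixel.
// dt is the Euclidean distance (pixels) to the nearest background pixel;
// a disk of radius dt(c) centred at c lies inside the foreground, so each
// centre paints 2*dt(c) onto every pixel it covers and the map is the
// pixelwise maximum.
// [[Rcpp::export(name = ".cpp_local_thickness")]]
NumericMatrix cpp_local_thickness(IntegerMatrix mask, NumericMatrix dt) {
  int nr = mask.nrow(), nc = mask.ncol();
  NumericMatrix out(nr, nc);
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (!mask(r, c)) continue;
      double rad = dt(r, c);
      double diam = 2.0 * rad;
      int ir = (int)std::ceil(rad);
      int r0 = std::max(0, r - ir), r1 = std::min(nr - 1, r + ir);
      int c0 = std::max(0, c - ir), c1 = std::min(nc - 1, c + ir);
      double rad2 = rad * rad;
      for (int rr = r0; rr <= r1; ++rr) {
        double dy = rr - r;
        for (int cc = c0; cc <= c1; ++cc) {
          double dx = cc - c;
          if (dy * dy + dx * dx < rad2 && mask(rr, cc) && out(rr, cc) < diam)
            out(rr, cc) = diam;
        }
      }
      if (out(r, c) < diam) out(r, c) = diam;
    }
  }
  return out;
}

// 8-connected component labelling of a binary mask.
// [[Rcpp::export(name = ".cpp_label8")]]
IntegerMatrix cpp_label8(IntegerMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  const int dr[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  const int dc[8] = {0, 1, 1, 1, 0, -1, -1, -1};
  int next = 0;
  std::queue<int> q;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c)) continue;
      lab(r, c) = ++next;
      q.push(c * nr + r);
      while (!q.empty()) {
        int idx = q.front(); q.pop();
        int rr0 = idx % nr, cc0 = idx / nr;
        for (int k = 0; k < 8; ++k) {
          int rr = rr0 + dr[k], cc = cc0 + dc[k];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (mask(rr, cc) && !lab(rr, cc)) {
            lab(rr, cc) = next;
            q.push(cc * nr + rr);
          }
        }
      }
    }
  }
  return lab;
}

// Propagate integer seed labels (0 = unlabelled) across a foreground mask
// by multi-source breadth-first search (8-connectivity). Foreground pixels
// unreachable from any seed keep label 0.
// [[Rcpp::export(name = ".cpp_propagate_labels")]]
IntegerMatrix cpp_propagate_labels(IntegerMatrix mask, IntegerMatrix seeds) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(clone(seeds));
  std::queue<int> q;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (lab(r, c) > 0 && mask(r, c)) q.push(c * nr + r);
  const int dr[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  const int dc[8] = {0, 1, 1, 1, 0, -1, -1, -1};
  while (!q.empty()) {
    int idx = q.front(); q.pop();
    int r = idx % nr, c = idx / nr;
    int l = lab(r, c);
    for (int k = 0; k < 8; ++k) {
      int rr = r + dr[k], cc = c + dc[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      if (mask(rr, cc) && lab(rr, cc) == 0) {
        lab(rr, cc) = l;
        q.push(cc * nr + rr);
      }
    }
  }
  return lab;
}
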