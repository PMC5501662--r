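#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <utility>
using namespace Rcpp;

// 8-neighbourhood, clockwise from north: N, NE, E, SE, S, SW, W, NW.
// "row" increases downwards, "col" to the right (R matrix convention).
static const int DR[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
static const int DC[8] = {0, 1, 1, 1, 0, -1, -1, -1};

static inline bool at(const std::vector<uint8_t> &m, int nr, int nc,
                      int r, int c) {
  if (r < 0 || r >= nr || c < 0 || c >= nc) return false;
  return m[(size_t)r + (size_t)c * (size_t)nr] != 0;
}

static inline void nbrs(const std::vector<uint8_t> &m, int nr, int nc,
                        int r, int c, int p[8]) {
  for (int k = 0; k < 8; k++)
    p[k] = at(m, nr, nc, r + DR[k], c + DC[k]) ? 1 : 0;
}

// Guo-Hall deletability test for sub-iteration `sub` (0 or 1);
// neighbours p[0..7] = N, NE, E, SE, S, SW, W, NW.
static bool gh_ok(const std::vector<uint8_t> &m, int nr, int nc,
                  int r, int c, int sub) {
  int p[8];
  nbrs(m, nr, nc, r, c, p);
  int C = (!p[0] && (p[1] || p[2])) + (!p[2] && (p[3] || p[4])) +
          (!p[4] && (p[5] || p[6])) + (!p[6] && (p[7] || p[0]));
  if (C != 1) return false;
  int N1 = (p[0] || p[1]) + (p[2] || p[3]) + (p[4] || p[5]) + (p[6] || p[7]);
  int N2 = (p[1] || p[2]) + (p[3] || p[4]) + (p[5] || p[6]) + (p[7] || p[0]);
  int N = N1 < N2 ? N1 : N2;
  if (N < 2 || N > 3) return false;
  if (sub == 0) {
    if ((p[1] || p[2] || !p[4]) && p[3]) return false;
  } else {
    if ((p[5] || p[6] || !p[0]) && p[7]) return false;
  }
  return true;
}

// number of 8-connected components among the foreground neighbours
static int fg_components_n8(const int p[8]) {
  bool used[8] = {false, false, false, false, false, false, false, false};
  int comp = 0;
  for (int i = 0; i < 8; i++) {
    if (!p[i] || used[i]) continue;
    comp++;
    std::vector<int> st;
    st.push_back(i);
    used[i] = true;
    while (!st.empty()) {
      int a = st.back();
      st.pop_back();
      for (int b = 0; b < 8; b++) {
        if (!p[b] || used[b]) continue;
        int dr = DR[a] - DR[b], dc = DC[a] - DC[b];
        if (dr >= -1 && dr <= 1 && dc >= -1 && dc <= 1) {
          used[b] = true;
          st.push_back(b);
        }
      }
    }
  }
  return comp;
}

// removable without changing local topology (one fg component in N8,
// at least one background 4-neighbour)
static bool simple_px(const std::vector<uint8_t> &m, int nr, int nc,
                      int r, int c) {
  int p[8];
  nbrs(m, nr, nc, r, c, p);
  if (p[0] && p[2] && p[4] && p[6]) return false;
  return fg_components_n8(p) == 1;
}

// [[Rcpp::export]]
LogicalMatrix cpp_thin(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  std::vector<uint8_t> m((size_t)nr * nc);
  for (size_t i = 0; i < m.size(); i++) m[i] = mask[i] ? 1 : 0;

  std::vector<std::pair<int, int> > cand;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int sub = 0; sub < 2; sub++) {
      // candidates fixed on the snapshot (one boundary layer per pass),
      // deleted sequentially under a simple-point guard so that
      // connectivity is never broken
      cand.clear();
      for (int c = 0; c < nc; c++)
        for (int r = 0; r < nr; r++)
          if (m[(size_t)r + (size_t)c * nr] && gh_ok(m, nr, nc, r, c, sub))
            cand.push_back(std::make_pair(r, c));
      for (size_t i = 0; i < cand.size(); i++) {
        int r = cand[i].first, c = cand[i].second;
        if (simple_px(m, nr, nc, r, c)) {
          m[(size_t)r + (size_t)c * nr] = 0;
          changed = true;
        }
      }
    }
  }

  // cleanup: remove redundant pixels (staircase corners, 2x2 leftovers,
  // pixels closing trivial 3-cycles). A non-endpoint pixel is redundant
  // when its skeleton neighbours form one mutually 8-connected group
  // without it (line interiors have two opposite neighbour groups and are
  // kept; endpoints have B == 1 and are kept).
  changed = true;
  while (changed) {
    changed = false;
    for (int c = 0; c < nc; c++)
      for (int r = 0; r < nr; r++) {
        if (!m[(size_t)r + (size_t)c * nr]) continue;
        int p[8], B = 0;
        nbrs(m, nr, nc, r, c, p);
        for (int k = 0; k < 8; k++) B += p[k];
        if (B >= 2 && simple_px(m, nr, nc, r, c)) {
          m[(size_t)r + (size_t)c * nr] = 0;
          changed = true;
        }
      }
  }

  LogicalMatrix out(nr, nc);
  for (size_t i = 0; i < m.size(); i++) out[i] = m[i] != 0;
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_label8(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<std::pair<int, int> > st;
  for (int c = 0; c < nc; c++)
    for (int r = 0; r < nr; r++) {
      if (!mask(r, c) || lab(r, c)) continue;
      next++;
      lab(r, c) = next;
      st.clear();
      st.push_back(std::make_pair(r, c));
      while (!st.empty()) {
        std::pair<int, int> p = st.back();
        st.pop_back();
        for (int k = 0; k < 8; k++) {
          int rr = p.first + DR[k], cc = p.second + DC[k];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (mask(rr, cc) && !lab(rr, cc)) {
            lab(rr, cc) = next;
            st.push_back(std::make_pair(rr, cc));
          }
        }
      }
    }
  return lab;
}

// Remove foreground pixels having >= count background 8-neighbours
// (image border counts as background), `iterations` times in parallel.
// [[Rcpp::export]]
LogicalMatrix cpp_erode_count(LogicalMatrix mask, int count, int iterations) {
  int nr = mask.nrow(), nc = mask.ncol();
  std::vector<uint8_t> m((size_t)nr * nc), m2((size_t)nr * nc);
  for (size_t i = 0; i < m.size(); i++) m[i] = mask[i] ? 1 : 0;
  for (int it = 0; it < iterations; it++) {
    for (int c = 0; c < nc; c++)
      for (int r = 0; r < nr; r++) {
        size_t i = (size_t)r + (size_t)c * nr;
        if (!m[i]) { m2[i] = 0; continue; }
        int p[8];
        nbrs(m, nr, nc, r, c, p);
        int bg = 0;
        for (int k = 0; k < 8; k++) bg += (p[k] == 0);
        m2[i] = (bg >= count) ? 0 : 1;
      }
    m.swap(m2);
  }
  LogicalMatrix out(nr, nc);
  for (size_t i = 0; i < m.size(); i++) out[i] = m[i] != 0;
  return out;
}

// Chebyshev (box) dilation by `radius`, separable max filter.
// [[Rcpp::export]]
LogicalMatrix cpp_dilate_box(LogicalMatrix mask, int radius) {
  int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix tmp(nr, nc), out(nr, nc);
  for (int c = 0; c < nc; c++)
    for (int r = 0; r < nr; r++) {
      bool v = false;
      for (int d = -radius; d <= radius && !v; d++) {
        int rr = r + d;
        if (rr >= 0 && rr < nr && mask(rr, c)) v = true;
      }
      tmp(r, c) = v;
    }
  for (int c = 0; c < nc; c++)
    for (int r = 0; r < nr; r++) {
      bool v = false;
      for (int d = -radius; d <= radius && !v; d++) {
        int cc = c + d;
        if (cc >= 0 && cc < nc && tmp(r, cc)) v = true;
      }
      out(r, c) = v;
    }
  return out;
}

// Total Euclidean length of a 1-px skeleton: unit step for 4-adjacent
// pairs, sqrt(2) for diagonal pairs that are not shortcuts across a
// 4-adjacent pixel.
// [[Rcpp::export]]
double cpp_skeleton_length(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  const double SQ2 = std::sqrt(2.0);
  double L = 0.0;
  for (int c = 0; c < nc; c++)
    for (int r = 0; r < nr; r++) {
      if (!mask(r, c)) continue;
      bool E = (c + 1 < nc) && mask(r, c + 1);
      bool S = (r + 1 < nr) && mask(r + 1, c);
      bool N = (r - 1 >= 0) && mask(r - 1, c);
      if (E) L += 1.0;
      if (S) L += 1.0;
      if ((r + 1 < nr) && (c + 1 < nc) && mask(r + 1, c + 1) && !E && !S)
        L += SQ2; // SE
      if ((r - 1 >= 0) && (c + 1 < nc) && mask(r - 1, c + 1) && !E && !N)
        L += SQ2; // NE
    }
  return L;
}

// Render tube intensity profiles: per path (n x 2 matrix of continuous
// row/col coordinates, 1-based) take the max Gaussian response within the
// path, then sum across paths (overlapping mitochondria add up).
// [[Rcpp::export]]
NumericMatrix cpp_render_paths(int nr, int nc, List paths, double sigma) {
  NumericMatrix img(nr, nc);
  std::vector<double> layer((size_t)nr * nc, 0.0);
  std::vector<size_t> touched;
  int R = (int)std::ceil(4.0 * sigma);
  double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  for (int pi = 0; pi < paths.size(); pi++) {
    NumericMatrix pt = paths[pi];
    touched.clear();
    for (int i = 0; i < pt.nrow(); i++) {
      double pr = pt(i, 0) - 1.0, pc = pt(i, 1) - 1.0;
      int r0 = std::max(0, (int)std::ceil(pr - R));
      int r1 = std::min(nr - 1, (int)std::floor(pr + R));
      int c0 = std::max(0, (int)std::ceil(pc - R));
      int c1 = std::min(nc - 1, (int)std::floor(pc + R));
      for (int c = c0; c <= c1; c++)
        for (int r = r0; r <= r1; r++) {
          double d2 = (r - pr) * (r - pr) + (c - pc) * (c - pc);
          double v = std::exp(-d2 * inv2s2);
          if (v < 1e-8) continue;
          size_t idx = (size_t)r + (size_t)c * nr;
          if (layer[idx] < v) {
            if (layer[idx] == 0.0) touched.push_back(idx);
            layer[idx] = v;
          }
        }
    }
    for (size_t t = 0; t < touched.size(); t++) {
      img[touched[t]] += layer[touched[t]];
      layer[touched[t]] = 0.0;
    }
  }
  return img;
}
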