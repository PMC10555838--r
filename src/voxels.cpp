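#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Volumes are stored as R arrays with dim = (depth, height, width) = (z, y, x);
// the first index varies fastest.  All coordinates entering these kernels are
// 0-based (z, y, x) voxel coordinates; voxel centers sit at integer positions.

static inline double getv(const NumericVector &a, int d0, int d1, int d2,
                          int i, int j, int k) {
  return a[(double)i + (double)d0 * (j + (double)d1 * k)];
}

// [[Rcpp::export(name = ".cpp_interp3")]]
NumericVector cpp_interp3(NumericVector arr, IntegerVector dim,
                          NumericMatrix coords, bool nearest,
                          double fill) {
  const int d0 = dim[0], d1 = dim[1], d2 = dim[2];
  const int n = coords.nrow();
  NumericVector out(n);
  for (int r = 0; r < n; ++r) {
    double z = coords(r, 0), y = coords(r, 1), x = coords(r, 2);
    if (nearest) {
      int iz = (int)std::lround(z), iy = (int)std::lround(y),
          ix = (int)std::lround(x);
      if (iz < 0 || iy < 0 || ix < 0 || iz >= d0 || iy >= d1 || ix >= d2)
        out[r] = fill;
      else
        out[r] = getv(arr, d0, d1, d2, iz, iy, ix);
    } else {
      // snap coordinates that fall outside the grid by round-off only
      const double tol = 1e-6;
      if (z < 0 && z > -tol) z = 0;
      if (y < 0 && y > -tol) y = 0;
      if (x < 0 && x > -tol) x = 0;
      if (z > d0 - 1 && z < d0 - 1 + tol) z = d0 - 1;
      if (y > d1 - 1 && y < d1 - 1 + tol) y = d1 - 1;
      if (x > d2 - 1 && x < d2 - 1 + tol) x = d2 - 1;
      if (z < 0 || y < 0 || x < 0 || z > d0 - 1 || y > d1 - 1 || x > d2 - 1) {
        out[r] = fill;
        continue;
      }
      int z0 = (int)std::floor(z), y0 = (int)std::floor(y),
          x0 = (int)std::floor(x);
      int z1 = std::min(z0 + 1, d0 - 1), y1 = std::min(y0 + 1, d1 - 1),
          x1 = std::min(x0 + 1, d2 - 1);
      double fz = z - z0, fy = y - y0, fx = x - x0;
      double c000 = getv(arr, d0, d1, d2, z0, y0, x0);
      double c100 = getv(arr, d0, d1, d2, z1, y0, x0);
      double c010 = getv(arr, d0, d1, d2, z0, y1, x0);
      double c110 = getv(arr, d0, d1, d2, z1, y1, x0);
      double c001 = getv(arr, d0, d1, d2, z0, y0, x1);
      double c101 = getv(arr, d0, d1, d2, z1, y0, x1);
      double c011 = getv(arr, d0, d1, d2, z0, y1, x1);
      double c111 = getv(arr, d0, d1, d2, z1, y1, x1);
      double c00 = c000 * (1 - fz) + c100 * fz;
      double c01 = c001 * (1 - fz) + c101 * fz;
      double c10 = c010 * (1 - fz) + c110 * fz;
      double c11 = c011 * (1 - fz) + c111 * fz;
      double c0 = c00 * (1 - fy) + c10 * fy;
      double c1 = c01 * (1 - fy) + c11 * fy;
      out[r] = c0 * (1 - fx) + c1 * fx;
    }
  }
  return out;
}

// 26-connected component labeling of a binary mask.
// [[Rcpp::export(name = ".cpp_label26")]]
IntegerVector cpp_label26(LogicalVector mask, IntegerVector dim) {
  const int d0 = dim[0], d1 = dim[1], d2 = dim[2];
  const R_xlen_t n = (R_xlen_t)d0 * d1 * d2;
  IntegerVector lab(n, 0);
  int cur = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++cur;
    lab[s] = cur;
    q.push(s);
    while (!q.empty()) {
      R_xlen_t v = q.front();
      q.pop();
      int i = v % d0, j = (v / d0) % d1, k = v / ((R_xlen_t)d0 * d1);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dz && !dy && !dx) continue;
            int iz = i + dz, iy = j + dy, ix = k + dx;
            if (iz < 0 || iy < 0 || ix < 0 || iz >= d0 || iy >= d1 ||
                ix >= d2)
              continue;
            R_xlen_t w = iz + (R_xlen_t)d0 * (iy + (R_xlen_t)d1 * ix);
            if (mask[w] && !lab[w]) {
              lab[w] = cur;
              q.push(w);
            }
          }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// ---- 3D thinning ----------------------------------------------------------
// Sequential 6-subiteration thinning deleting simple, non-endpoint border
// points.  Simpleness follows the Bertrand-Malandain local characterization:
// a foreground point p is simple iff (a) the foreground of its punctured
// 26-neighborhood forms exactly one 26-connected component, and (b) the
// background voxels of its 18-neighborhood that are 6-adjacent to p form
// exactly one 6-connected component within the 18-neighborhood background.

static const int NB6[6][3] = {{-1, 0, 0}, {1, 0, 0}, {0, -1, 0},
                              {0, 1, 0},  {0, 0, -1}, {0, 0, 1}};

static inline int lidx(int dz, int dy, int dx) {
  return (dz + 1) + 3 * ((dy + 1) + 3 * (dx + 1));
}

static bool is_simple(const bool nb[27]) {
  // (a) one 26-component of foreground in N26*(p)
  bool seen[27] = {false};
  int comps = 0, nfg = 0;
  for (int t = 0; t < 27; ++t)
    if (t != 13 && nb[t]) ++nfg;
  if (nfg == 0) return false;
  for (int t = 0; t < 27; ++t) {
    if (t == 13 || !nb[t] || seen[t]) continue;
    if (++comps > 1) return false;
    std::queue<int> q;
    q.push(t);
    seen[t] = true;
    while (!q.empty()) {
      int v = q.front();
      q.pop();
      int vz = v % 3 - 1, vy = (v / 3) % 3 - 1, vx = v / 9 - 1;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            int wz = vz + dz, wy = vy + dy, wx = vx + dx;
            if (wz < -1 || wz > 1 || wy < -1 || wy > 1 || wx < -1 || wx > 1)
              continue;
            int w = lidx(wz, wy, wx);
            if (w == 13 || w == v || !nb[w] || seen[w]) continue;
            seen[w] = true;
            q.push(w);
          }
    }
  }
  if (comps != 1) return false;
  // (b) one 6-component of N18 background containing a 6-neighbor of p
  bool seenb[27] = {false};
  int bcomps = 0;
  for (int s = 0; s < 6; ++s) {
    int t = lidx(NB6[s][0], NB6[s][1], NB6[s][2]);
    if (nb[t] || seenb[t]) continue;
    ++bcomps;
    if (bcomps > 1) return false;
    std::queue<int> q;
    q.push(t);
    seenb[t] = true;
    while (!q.empty()) {
      int v = q.front();
      q.pop();
      int vz = v % 3 - 1, vy = (v / 3) % 3 - 1, vx = v / 9 - 1;
      for (int s2 = 0; s2 < 6; ++s2) {
        int wz = vz + NB6[s2][0], wy = vy + NB6[s2][1], wx = vx + NB6[s2][2];
        if (wz < -1 || wz > 1 || wy < -1 || wy > 1 || wx < -1 || wx > 1)
          continue;
        // stay within the 18-neighborhood (exclude corners) and the center
        if (std::abs(wz) + std::abs(wy) + std::abs(wx) > 2) continue;
        int w = lidx(wz, wy, wx);
        if (w == 13 || nb[w] || seenb[w]) continue;
        seenb[w] = true;
        q.push(w);
      }
    }
  }
  return bcomps == 1;
}

// [[Rcpp::export(name = ".cpp_thin3d")]]
LogicalVector cpp_thin3d(LogicalVector mask, IntegerVector dim) {
  const int d0 = dim[0], d1 = dim[1], d2 = dim[2];
  const R_xlen_t n = (R_xlen_t)d0 * d1 * d2;
  std::vector<char> m(n);
  for (R_xlen_t s = 0; s < n; ++s) m[s] = mask[s] ? 1 : 0;

  auto at = [&](int i, int j, int k) -> char {
    if (i < 0 || j < 0 || k < 0 || i >= d0 || j >= d1 || k >= d2) return 0;
    return m[i + (R_xlen_t)d0 * (j + (R_xlen_t)d1 * k)];
  };
  auto fill_nb = [&](int i, int j, int k, bool nb[27]) {
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx)
          nb[lidx(dz, dy, dx)] = at(i + dz, j + dy, k + dx) != 0;
  };
  auto n26 = [&](int i, int j, int k) {
    int c = 0;
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (!dz && !dy && !dx) continue;
          if (at(i + dz, j + dy, k + dx)) ++c;
        }
    return c;
  };

  bool changed = true;
  std::vector<R_xlen_t> cand;
  while (changed) {
    changed = false;
    for (int dir = 0; dir < 6; ++dir) {
      cand.clear();
      for (R_xlen_t s = 0; s < n; ++s) {
        if (!m[s]) continue;
        int i = s % d0, j = (s / d0) % d1, k = s / ((R_xlen_t)d0 * d1);
        if (at(i + NB6[dir][0], j + NB6[dir][1], k + NB6[dir][2])) continue;
        if (n26(i, j, k) <= 1) continue;  // endpoint: keep
        bool nb[27];
        fill_nb(i, j, k, nb);
        if (is_simple(nb)) cand.push_back(s);
      }
      for (R_xlen_t s : cand) {
        int i = s % d0, j = (s / d0) % d1, k = s / ((R_xlen_t)d0 * d1);
        if (n26(i, j, k) <= 1) continue;
        bool nb[27];
        fill_nb(i, j, k, nb);
        if (is_simple(nb)) {
          m[s] = 0;
          changed = true;
        }
      }
    }
  }
  LogicalVector out(n);
  for (R_xlen_t s = 0; s < n; ++s) out[s] = m[s] != 0;
  out.attr("dim") = dim;
  return out;
}

// clipped sliding-window box sums via a 3D summed-area table
// [[Rcpp::export(name = ".cpp_boxsum3")]]
NumericVector cpp_boxsum3(NumericVector arr, IntegerVector dim, int s) {
  const int d0 = dim[0], d1 = dim[1], d2 = dim[2];
  const int r = (s - 1) / 2;
  const int p0 = d0 + 1, p1 = d1 + 1, p2 = d2 + 1;
  std::vector<double> sat((size_t)p0 * p1 * p2, 0.0);
  auto S = [&](int i, int j, int k) -> double & {
    return sat[(size_t)i + (size_t)p0 * (j + (size_t)p1 * k)];
  };
  for (int k = 1; k < p2; ++k)
    for (int j = 1; j < p1; ++j)
      for (int i = 1; i < p0; ++i) {
        double v = arr[(size_t)(i - 1) +
                       (size_t)d0 * ((j - 1) + (size_t)d1 * (k - 1))];
        S(i, j, k) = v + S(i - 1, j, k) + S(i, j - 1, k) + S(i, j, k - 1) -
                     S(i - 1, j - 1, k) - S(i - 1, j, k - 1) -
                     S(i, j - 1, k - 1) + S(i - 1, j - 1, k - 1);
      }
  NumericVector out((R_xlen_t)d0 * d1 * d2);
  for (int k = 0; k < d2; ++k) {
    int k0 = std::max(k - r, 0), k1 = std::min(k + r, d2 - 1) + 1;
    for (int j = 0; j < d1; ++j) {
      int j0 = std::max(j - r, 0), j1 = std::min(j + r, d1 - 1) + 1;
      for (int i = 0; i < d0; ++i) {
        int i0 = std::max(i - r, 0), i1 = std::min(i + r, d0 - 1) + 1;
        out[(size_t)i + (size_t)d0 * (j + (size_t)d1 * k)] =
            S(i1, j1, k1) - S(i0, j1, k1) - S(i1, j0, k1) - S(i1, j1, k0) +
            S(i0, j0, k1) + S(i0, j1, k0) + S(i1, j0, k0) - S(i0, j0, k0);
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}
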