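#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Shared helpers for 3D grids stored in R's column-major (Fortran) order:
// linear index = i + d1 * (j + d2 * k), 0-based.

static inline int lin(int i, int j, int k, const int* d) {
  return i + d[0] * (j + d[1] * k);
}

// 26-neighbourhood offsets, face-first so 6-connectivity is offs[0..5]
static void neighbour_offsets(std::vector<std::array<int, 3> >& offs) {
  offs.clear();
  const int face[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  for (int f = 0; f < 6; ++f) offs.push_back({face[f][0], face[f][1], face[f][2]});
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        int a = std::abs(di) + std::abs(dj) + std::abs(dk);
        if (a >= 2) offs.push_back({di, dj, dk});
      }
}

// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  const int d[3] = {dim[0], dim[1], dim[2]};
  const R_xlen_t n = mask.size();
  IntegerVector lab(n, 0);
  std::vector<std::array<int, 3> > offs;
  neighbour_offsets(offs);
  const int nn = (connectivity == 6) ? 6 : 26;
  int cur = 0;
  std::vector<int> stack;
  for (int k = 0; k < d[2]; ++k)
    for (int j = 0; j < d[1]; ++j)
      for (int i = 0; i < d[0]; ++i) {
        int v = lin(i, j, k, d);
        if (!mask[v] || lab[v]) continue;
        ++cur;
        lab[v] = cur;
        stack.clear();
        stack.push_back(v);
        while (!stack.empty()) {
          int u = stack.back(); stack.pop_back();
          int uk = u / (d[0] * d[1]);
          int rem = u - uk * d[0] * d[1];
          int uj = rem / d[0];
          int ui = rem - uj * d[0];
          for (int m = 0; m < nn; ++m) {
            int ni = ui + offs[m][0], nj = uj + offs[m][1], nk = uk + offs[m][2];
            if (ni < 0 || nj < 0 || nk < 0 || ni >= d[0] || nj >= d[1] || nk >= d[2])
              continue;
            int w = lin(ni, nj, nk, d);
            if (mask[w] && !lab[w]) { lab[w] = cur; stack.push_back(w); }
          }
        }
      }
  lab.attr("n_components") = cur;
  return lab;
}

// 1D squared-distance transform pass (Felzenszwalb & Huttenlocher),
// sampling step h (mm).  f holds squared distances, INF where no feature.
static void dt1d(std::vector<double>& f, double h) {
  const int n = (int) f.size();
  static std::vector<int> v;
  static std::vector<double> z, out;
  v.assign(n, 0);
  z.assign(n + 1, 0.0);
  out.assign(n, 0.0);
  const double INF = std::numeric_limits<double>::infinity();
  const double h2 = h * h;
  int kk = -1; // index of rightmost parabola in the lower envelope
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue;
    double s = 0.0;
    while (kk >= 0) {
      int p = v[kk];
      s = ((f[q] + h2 * q * q) - (f[p] + h2 * p * p)) / (2.0 * h2 * (q - p));
      if (s <= z[kk]) { --kk; } else break;
    }
    ++kk;
    v[kk] = q;
    z[kk] = (kk == 0) ? -INF : s;
    z[kk + 1] = INF;
  }
  if (kk < 0) {
    for (int q = 0; q < n; ++q) out[q] = INF;
  } else {
    int m = 0;
    for (int q = 0; q < n; ++q) {
      while (z[m + 1] < q) ++m;
      double dq = h * (q - v[m]);
      out[q] = dq * dq + f[v[m]];
    }
  }
  f = out;
}

// Exact squared Euclidean distance (mm^2) to the nearest feature voxel.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector feature, IntegerVector dim,
                         NumericVector spacing) {
  const int d[3] = {dim[0], dim[1], dim[2]};
  const double INF = std::numeric_limits<double>::infinity();
  const R_xlen_t n = feature.size();
  NumericVector g(n);
  for (R_xlen_t v = 0; v < n; ++v) g[v] = feature[v] ? 0.0 : INF;
  std::vector<double> line;
  // pass along x
  line.resize(d[0]);
  for (int k = 0; k < d[2]; ++k)
    for (int j = 0; j < d[1]; ++j) {
      for (int i = 0; i < d[0]; ++i) line[i] = g[lin(i, j, k, d)];
      dt1d(line, spacing[0]);
      for (int i = 0; i < d[0]; ++i) g[lin(i, j, k, d)] = line[i];
    }
  // pass along y
  line.resize(d[1]);
  for (int k = 0; k < d[2]; ++k)
    for (int i = 0; i < d[0]; ++i) {
      for (int j = 0; j < d[1]; ++j) line[j] = g[lin(i, j, k, d)];
      dt1d(line, spacing[1]);
      for (int j = 0; j < d[1]; ++j) g[lin(i, j, k, d)] = line[j];
    }
  // pass along z
  line.resize(d[2]);
  for (int j = 0; j < d[1]; ++j)
    for (int i = 0; i < d[0]; ++i) {
      for (int k = 0; k < d[2]; ++k) line[k] = g[lin(i, j, k, d)];
      dt1d(line, spacing[2]);
      for (int k = 0; k < d[2]; ++k) g[lin(i, j, k, d)] = line[k];
    }
  return g;
}

// Fill cavities: background voxels (6-connectivity) not reachable from the
// grid boundary become foreground.
// [[Rcpp::export]]
LogicalVector cpp_fill_holes(LogicalVector mask, IntegerVector dim) {
  const int d[3] = {dim[0], dim[1], dim[2]};
  const R_xlen_t n = mask.size();
  std::vector<char> outside(n, 0);
  std::vector<int> stack;
  for (int k = 0; k < d[2]; ++k)
    for (int j = 0; j < d[1]; ++j)
      for (int i = 0; i < d[0]; ++i) {
        if (i > 0 && i < d[0] - 1 && j > 0 && j < d[1] - 1 &&
            k > 0 && k < d[2] - 1) continue;
        int v = lin(i, j, k, d);
        if (!mask[v] && !outside[v]) { outside[v] = 1; stack.push_back(v); }
      }
  const int face[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  while (!stack.empty()) {
    int u = stack.back(); stack.pop_back();
    int uk = u / (d[0] * d[1]);
    int rem = u - uk * d[0] * d[1];
    int uj = rem / d[0];
    int ui = rem - uj * d[0];
    for (int m = 0; m < 6; ++m) {
      int ni = ui + face[m][0], nj = uj + face[m][1], nk = uk + face[m][2];
      if (ni < 0 || nj < 0 || nk < 0 || ni >= d[0] || nj >= d[1] || nk >= d[2])
        continue;
      int w = lin(ni, nj, nk, d);
      if (!mask[w] && !outside[w]) { outside[w] = 1; stack.push_back(w); }
    }
  }
  LogicalVector out(n);
  for (R_xlen_t v = 0; v < n; ++v) out[v] = mask[v] || !outside[v];
  return out;
}

// 26-connected flood fill over an allowed set, from 0-based seed rows (i,j,k).
// [[Rcpp::export]]
LogicalVector cpp_region_grow(LogicalVector allowed, IntegerVector dim,
                              IntegerMatrix seeds) {
  const int d[3] = {dim[0], dim[1], dim[2]};
  const R_xlen_t n = allowed.size();
  LogicalVector out(n, false);
  std::vector<std::array<int, 3> > offs;
  neighbour_offsets(offs);
  std::vector<int> stack;
  for (int s = 0; s < seeds.nrow(); ++s) {
    int v = lin(seeds(s, 0), seeds(s, 1), seeds(s, 2), d);
    if (allowed[v] && !out[v]) { out[v] = true; stack.push_back(v); }
  }
  while (!stack.empty()) {
    int u = stack.back(); stack.pop_back();
    int uk = u / (d[0] * d[1]);
    int rem = u - uk * d[0] * d[1];
    int uj = rem / d[0];
    int ui = rem - uj * d[0];
    for (int m = 0; m < 26; ++m) {
      int ni = ui + offs[m][0], nj = uj + offs[m][1], nk = uk + offs[m][2];
      if (ni < 0 || nj < 0 || nk < 0 || ni >= d[0] || nj >= d[1] || nk >= d[2])
        continue;
      int w = lin(ni, nj, nk, d);
      if (allowed[w] && !out[w]) { out[w] = true; stack.push_back(w); }
    }
  }
  return out;
}

// Rasterize capped cylinders (tree branches).  segs rows:
// x0 y0 z0 x1 y1 z1 radius, all in mm (world = index * spacing).
// [[Rcpp::export]]
LogicalVector cpp_draw_tubes(IntegerVector dim, NumericVector spacing,
                             NumericMatrix segs) {
  const int d[3] = {dim[0], dim[1], dim[2]};
  LogicalVector out((R_xlen_t) d[0] * d[1] * d[2], false);
  for (int s = 0; s < segs.nrow(); ++s) {
    double p0[3] = {segs(s, 0), segs(s, 1), segs(s, 2)};
    double p1[3] = {segs(s, 3), segs(s, 4), segs(s, 5)};
    double r = segs(s, 6);
    double ax[3] = {p1[0] - p0[0], p1[1] - p0[1], p1[2] - p0[2]};
    double len2 = ax[0] * ax[0] + ax[1] * ax[1] + ax[2] * ax[2];
    int lo[3], hi[3];
    for (int a = 0; a < 3; ++a) {
      double mn = std::min(p0[a], p1[a]) - r, mx = std::max(p0[a], p1[a]) + r;
      lo[a] = std::max(0, (int) std::floor(mn / spacing[a]));
      hi[a] = std::min(d[a] - 1, (int) std::ceil(mx / spacing[a]));
    }
    for (int k = lo[2]; k <= hi[2]; ++k)
      for (int j = lo[1]; j <= hi[1]; ++j)
        for (int i = lo[0]; i <= hi[0]; ++i) {
          double p[3] = {i * spacing[0], j * spacing[1], k * spacing[2]};
          double t = 0.0;
          if (len2 > 0) {
            t = ((p[0] - p0[0]) * ax[0] + (p[1] - p0[1]) * ax[1] +
                 (p[2] - p0[2]) * ax[2]) / len2;
            t = std::max(0.0, std::min(1.0, t));
          }
          double dx = p[0] - (p0[0] + t * ax[0]);
          double dy = p[1] - (p0[1] + t * ax[1]);
          double dz = p[2] - (p0[2] + t * ax[2]);
          if (dx * dx + dy * dy + dz * dz <= r * r)
            out[lin(i, j, k, d)] = true;
        }
  }
  return out;
}

// Separable Gaussian blur with reflected boundaries; sigma in voxels per
// axis (<= 0 skips the axis).  Used for the phantom's pleural partial-volume
// model.
// [[Rcpp::export]]
NumericVector cpp_gauss_blur(NumericVector vol, IntegerVector dim,
                             NumericVector sigma) {
  const int d[3] = {dim[0], dim[1], dim[2]};
  NumericVector cur = clone(vol);
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma[ax];
    if (s <= 0) continue;
    int r = (int) std::ceil(3.0 * s);
    std::vector<double> w(2 * r + 1);
    double tot = 0.0;
    for (int t = -r; t <= r; ++t) {
      w[t + r] = std::exp(-0.5 * t * t / (s * s));
      tot += w[t + r];
    }
    for (double& x : w) x /= tot;
    NumericVector nxt((R_xlen_t) d[0] * d[1] * d[2]);
    const int step = (ax == 0) ? 1 : (ax == 1 ? d[0] : d[0] * d[1]);
    const int n_ax = d[ax];
    R_xlen_t v = 0;
    for (int k = 0; k < d[2]; ++k)
      for (int j = 0; j < d[1]; ++j)
        for (int i = 0; i < d[0]; ++i, ++v) {
          int pos = (ax == 0) ? i : (ax == 1 ? j : k);
          double acc = 0.0;
          for (int t = -r; t <= r; ++t) {
            int p = pos + t;
            if (p < 0) p = -p;                    // reflect
            if (p >= n_ax) p = 2 * n_ax - 2 - p;
            acc += w[t + r] * cur[v + (R_xlen_t)(p - pos) * step];
          }
          nxt[v] = acc;
        }
    cur = nxt;
  }
  return cur;
}
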