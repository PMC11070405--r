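#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
#include <algorithm>
#include <unordered_map>

using namespace Rcpp;

static inline int lin3(int i, int j, int k, const int* d) {
  return i + d[0] * (j + d[1] * k);
}

// Godunov upwind update at voxel (i,j,k): solve
//   sum_a ((T - a_d)^+ / h_d)^2 = 1
// using, per axis, the smaller accepted neighbour value.
static double godunov_update(const std::vector<double>& T,
                             const std::vector<char>& accepted,
                             int i, int j, int k, const int* d,
                             const double* h) {
  const double INF = std::numeric_limits<double>::infinity();
  double a[3];
  int pos[3][2][3] = {{{i - 1, j, k}, {i + 1, j, k}},
                      {{i, j - 1, k}, {i, j + 1, k}},
                      {{i, j, k - 1}, {i, j, k + 1}}};
  for (int ax = 0; ax < 3; ++ax) {
    a[ax] = INF;
    for (int s = 0; s < 2; ++s) {
      int ni = pos[ax][s][0], nj = pos[ax][s][1], nk = pos[ax][s][2];
      if (ni < 0 || nj < 0 || nk < 0 || ni >= d[0] || nj >= d[1] || nk >= d[2])
        continue;
      int w = lin3(ni, nj, nk, d);
      if (accepted[w] && T[w] < a[ax]) a[ax] = T[w];
    }
  }
  // sort (a, h) pairs by a ascending
  int ord[3] = {0, 1, 2};
  std::sort(ord, ord + 3, [&](int x, int y) { return a[x] < a[y]; });
  double best = INF;
  // try with 1, 2, 3 smallest terms; accept the largest consistent solution
  double s1 = 0.0, s2 = 0.0, s3 = 0.0; // sums of 1/h^2, a/h^2, a^2/h^2
  for (int m = 0; m < 3; ++m) {
    double av = a[ord[m]];
    if (av == INF) break;
    double w = 1.0 / (h[ord[m]] * h[ord[m]]);
    s1 += w; s2 += av * w; s3 += av * av * w;
    // solve s1 T^2 - 2 s2 T + s3 - 1 = 0
    double disc = s2 * s2 - s1 * (s3 - 1.0);
    if (disc < 0) continue;
    double t = (s2 + std::sqrt(disc)) / s1;
    // solution valid only if T >= all included a values
    if (t >= av) best = t;
  }
  return best;
}

// First-order fast marching for |grad T| = 1 inside a mask, anisotropic
// spacing h (mm).  seeds: 0-based (i,j,k) rows, T = 0 there.  Voxels within
// init_radius voxels (Chebyshev) of a seed are initialised with the exact
// Euclidean distance to the seed set, which removes most of the point-source
// discretisation error of the first-order scheme.
// [[Rcpp::export]]
NumericVector cpp_fast_march(LogicalVector mask, IntegerVector dim,
                             NumericVector spacing, IntegerMatrix seeds,
                             int init_radius) {
  const int d[3] = {dim[0], dim[1], dim[2]};
  const double h[3] = {spacing[0], spacing[1], spacing[2]};
  const double INF = std::numeric_limits<double>::infinity();
  const R_xlen_t n = mask.size();
  std::vector<double> T(n, INF);
  std::vector<char> accepted(n, 0);
  typedef std::pair<double, int> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > heap;

  // exact initialisation in a ball around each seed, restricted to voxels
  // with line-of-sight to the seed inside the mask (otherwise the straight
  // distance would undercut the geodesic across thin walls or gaps)
  const int R = std::max(0, init_radius);
  for (int s = 0; s < seeds.nrow(); ++s) {
    int si = seeds(s, 0), sj = seeds(s, 1), sk = seeds(s, 2);
    for (int dk = -R; dk <= R; ++dk)
      for (int dj = -R; dj <= R; ++dj)
        for (int di = -R; di <= R; ++di) {
          int i = si + di, j = sj + dj, k = sk + dk;
          if (i < 0 || j < 0 || k < 0 || i >= d[0] || j >= d[1] || k >= d[2])
            continue;
          int v = lin3(i, j, k, d);
          if (!mask[v]) continue;
          int cheb = std::max(std::abs(di), std::max(std::abs(dj),
                                                     std::abs(dk)));
          bool visible = true;
          int nstep = 2 * cheb;
          for (int t = 1; t < nstep && visible; ++t) {
            double f = (double) t / nstep;
            int xi = (int) std::lround(si + f * di);
            int yi = (int) std::lround(sj + f * dj);
            int zi = (int) std::lround(sk + f * dk);
            if (!mask[lin3(xi, yi, zi, d)]) visible = false;
          }
          if (!visible) continue;
          double dist = std::sqrt(di * h[0] * di * h[0] +
                                  dj * h[1] * dj * h[1] +
                                  dk * h[2] * dk * h[2]);
          if (dist < T[v]) { T[v] = dist; heap.push(QE(dist, v)); }
        }
  }
  const int face[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  while (!heap.empty()) {
    QE top = heap.top(); heap.pop();
    int u = top.second;
    if (accepted[u] || top.first > T[u]) continue;
    accepted[u] = 1;
    int uk = u / (d[0] * d[1]);
    int rem = u - uk * d[0] * d[1];
    int uj = rem / d[0];
    int ui = rem - uj * d[0];
    for (int m = 0; m < 6; ++m) {
      int ni = ui + face[m][0], nj = uj + face[m][1], nk = uk + face[m][2];
      if (ni < 0 || nj < 0 || nk < 0 || ni >= d[0] || nj >= d[1] || nk >= d[2])
        continue;
      int w = lin3(ni, nj, nk, d);
      if (!mask[w] || accepted[w]) continue;
      double t = godunov_update(T, accepted, ni, nj, nk, d, h);
      if (t < T[w]) { T[w] = t; heap.push(QE(t, w)); }
    }
  }
  NumericVector out(n, INF);
  for (R_xlen_t v = 0; v < n; ++v) if (mask[v]) out[v] = T[v];
  return out;
}

// Multi-source Dijkstra over the 26-connected graph of a voxel subset
// (skeleton), edge weight = Euclidean inter-voxel distance in mm.
// Returns geodesic distance from the given source subset to every subset
// voxel (Inf if unreachable).  idx: 0-based linear indices of the subset,
// sources: positions *within idx* (0-based).
// [[Rcpp::export]]
NumericVector cpp_skeleton_geodesic(IntegerVector idx, IntegerVector dim,
                                    NumericVector spacing,
                                    IntegerVector sources) {
  const int d[3] = {dim[0], dim[1], dim[2]};
  const double INF = std::numeric_limits<double>::infinity();
  const int m = idx.size();
  // map linear voxel index -> position in subset (hash via std::vector over
  // touched region would be large; use unordered_map)
  std::unordered_map<int, int> pos;
  pos.reserve(m * 2);
  for (int t = 0; t < m; ++t) pos[idx[t]] = t;
  std::vector<double> dist(m, INF);
  typedef std::pair<double, int> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > heap;
  for (int s = 0; s < sources.size(); ++s) {
    dist[sources[s]] = 0.0;
    heap.push(QE(0.0, sources[s]));
  }
  while (!heap.empty()) {
    QE top = heap.top(); heap.pop();
    int u = top.second;
    if (top.first > dist[u]) continue;
    int lu = idx[u];
    int uk = lu / (d[0] * d[1]);
    int rem = lu - uk * d[0] * d[1];
    int uj = rem / d[0];
    int ui = rem - uj * d[0];
    for (int dk = -1; dk <= 1; ++dk)
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di) {
          if (!di && !dj && !dk) continue;
          int ni = ui + di, nj = uj + dj, nk = uk + dk;
          if (ni < 0 || nj < 0 || nk < 0 || ni >= d[0] || nj >= d[1] || nk >= d[2])
            continue;
          auto it = pos.find(lin3(ni, nj, nk, d));
          if (it == pos.end()) continue;
          int w = it->second;
          double e = std::sqrt(di * spacing[0] * di * spacing[0] +
                               dj * spacing[1] * dj * spacing[1] +
                               dk * spacing[2] * dk * spacing[2]);
          if (dist[u] + e < dist[w]) {
            dist[w] = dist[u] + e;
            heap.push(QE(dist[w], w));
          }
        }
  }
  return NumericVector(dist.begin(), dist.end());
}
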