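#include <Rcpp.h>
#include <vector>
#include <array>

using namespace Rcpp;

// Sequential topology-preserving 3D thinning with directional subiterations.
// A border voxel is deleted when it is a simple point (deletion preserves the
// topology of both object and background) and not a curve endpoint, so
// tubular structures reduce to one-voxel-wide centerlines.  Simple-point
// characterisation (Malandain & Bertrand): exactly one 26-connected object
// component in the 26-neighbourhood AND exactly one 6-connected background
// component in the 18-neighbourhood that is 6-adjacent to the centre.

static inline int nb_index(int di, int dj, int dk) {
  return (di + 1) + 3 * ((dj + 1) + 3 * (dk + 1));
}

// occupancy of the 27-cell neighbourhood; centre cell ignored
static int count_object_neighbours(const bool* nb) {
  int c = 0;
  for (int t = 0; t < 27; ++t)
    if (t != 13 && nb[t]) ++c;
  return c;
}

static bool is_simple(const bool* nb) {
  // condition A: one 26-component of object among the 26 neighbours
  {
    int comp = 0;
    bool seen[27] = {false};
    for (int t0 = 0; t0 < 27; ++t0) {
      if (t0 == 13 || !nb[t0] || seen[t0]) continue;
      ++comp;
      if (comp > 1) return false;
      int stack[27], sp = 0;
      stack[sp++] = t0; seen[t0] = true;
      while (sp) {
        int u = stack[--sp];
        int ui = u % 3, uj = (u / 3) % 3, uk = u / 9;
        for (int dk = -1; dk <= 1; ++dk)
          for (int dj = -1; dj <= 1; ++dj)
            for (int di = -1; di <= 1; ++di) {
              int ni = ui + di, nj = uj + dj, nk = uk + dk;
              if (ni < 0 || nj < 0 || nk < 0 || ni > 2 || nj > 2 || nk > 2)
                continue;
              int w = ni + 3 * (nj + 3 * nk);
              if (w == 13 || w == u || seen[w] || !nb[w]) continue;
              seen[w] = true; stack[sp++] = w;
            }
      }
    }
    if (comp != 1) return false;
  }
  // condition B: 6-components of background restricted to the
  // 18-neighbourhood; count those touching a face neighbour of the centre
  {
    bool in18[27] = {false};
    for (int dk = -1; dk <= 1; ++dk)
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di) {
          int a = std::abs(di) + std::abs(dj) + std::abs(dk);
          if (a == 1 || a == 2) in18[nb_index(di, dj, dk)] = true;
        }
    const int faces[6] = {nb_index(1,0,0), nb_index(-1,0,0), nb_index(0,1,0),
                          nb_index(0,-1,0), nb_index(0,0,1), nb_index(0,0,-1)};
    bool seen[27] = {false};
    int comp_touching = 0;
    for (int f = 0; f < 6; ++f) {
      int t0 = faces[f];
      if (nb[t0] || seen[t0]) continue;
      ++comp_touching;
      if (comp_touching > 1) return false;
      int stack[27], sp = 0;
      stack[sp++] = t0; seen[t0] = true;
      while (sp) {
        int u = stack[--sp];
        int ui = u % 3, uj = (u / 3) % 3, uk = u / 9;
        const int step[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
        for (int m = 0; m < 6; ++m) {
          int ni = ui + step[m][0], nj = uj + step[m][1], nk = uk + step[m][2];
          if (ni < 0 || nj < 0 || nk < 0 || ni > 2 || nj > 2 || nk > 2)
            continue;
          int w = ni + 3 * (nj + 3 * nk);
          if (w == 13 || !in18[w] || nb[w] || seen[w]) continue;
          seen[w] = true; stack[sp++] = w;
        }
      }
    }
    if (comp_touching != 1) return false;
  }
  return true;
}

// [[Rcpp::export]]
LogicalVector cpp_thin3d(LogicalVector mask, IntegerVector dim) {
  const int d0 = dim[0], d1 = dim[1], d2 = dim[2];
  const R_xlen_t n = mask.size();
  std::vector<char> obj(n);
  for (R_xlen_t v = 0; v < n; ++v) obj[v] = mask[v] ? 1 : 0;
  auto at = [&](int i, int j, int k) -> char {
    if (i < 0 || j < 0 || k < 0 || i >= d0 || j >= d1 || k >= d2) return 0;
    return obj[i + (R_xlen_t) d0 * (j + (R_xlen_t) d1 * k)];
  };
  auto fill_nb = [&](int i, int j, int k, bool* nb) {
    for (int dk = -1; dk <= 1; ++dk)
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di)
          nb[nb_index(di, dj, dk)] = at(i + di, j + dj, k + dk) != 0;
  };
  const int dirs[6][3] = {{0,0,-1},{0,0,1},{0,-1,0},{0,1,0},{-1,0,0},{1,0,0}};
  bool nb[27];
  std::vector<R_xlen_t> cand;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int dir = 0; dir < 6; ++dir) {
      cand.clear();
      for (int k = 0; k < d2; ++k)
        for (int j = 0; j < d1; ++j)
          for (int i = 0; i < d0; ++i) {
            R_xlen_t v = i + (R_xlen_t) d0 * (j + (R_xlen_t) d1 * k);
            if (!obj[v]) continue;
            if (at(i + dirs[dir][0], j + dirs[dir][1], k + dirs[dir][2]))
              continue; // not a border voxel in this direction
            fill_nb(i, j, k, nb);
            if (count_object_neighbours(nb) <= 1) continue; // endpoint/isolated
            if (is_simple(nb)) cand.push_back(v);
          }
      // sequential re-check: deleting earlier candidates can make later ones
      // non-simple, so test each against the current object
      for (R_xlen_t c = 0; c < (R_xlen_t) cand.size(); ++c) {
        R_xlen_t v = cand[c];
        int k = (int) (v / ((R_xlen_t) d0 * d1));
        R_xlen_t rem = v - (R_xlen_t) k * d0 * d1;
        int j = (int) (rem / d0);
        int i = (int) (rem - (R_xlen_t) j * d0);
        fill_nb(i, j, k, nb);
        if (count_object_neighbours(nb) <= 1) continue;
        if (!is_simple(nb)) continue;
        obj[v] = 0;
        changed = true;
      }
    }
  }
  LogicalVector out(n);
  for (R_xlen_t v = 0; v < n; ++v) out[v] = obj[v] != 0;
  return out;
}
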