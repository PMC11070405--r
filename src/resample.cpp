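#include <Rcpp.h>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Resample a moving volume onto the fixed grid under a rigid map.  For each
// fixed-grid voxel with world position p (mm), the moving volume is sampled
// at  q = R (p - c) + c + t  by trilinear interpolation.  World coordinates
// are origin + index * spacing per volume.  Out-of-support samples get NA.
// [[Rcpp::export]]
NumericVector cpp_resample_rigid(NumericVector moving, IntegerVector mdim,
                                 NumericVector mspacing, NumericVector morigin,
                                 IntegerVector fdim, NumericVector fspacing,
                                 NumericVector forigin, NumericMatrix rot,
                                 NumericVector trans, NumericVector center) {
  const int md[3] = {mdim[0], mdim[1], mdim[2]};
  const int fd[3] = {fdim[0], fdim[1], fdim[2]};
  NumericVector out((R_xlen_t) fd[0] * fd[1] * fd[2], NA_REAL);
  R_xlen_t v = 0;
  for (int k = 0; k < fd[2]; ++k)
    for (int j = 0; j < fd[1]; ++j)
      for (int i = 0; i < fd[0]; ++i, ++v) {
        double p[3] = {forigin[0] + i * fspacing[0],
                       forigin[1] + j * fspacing[1],
                       forigin[2] + k * fspacing[2]};
        double q[3];
        for (int a = 0; a < 3; ++a)
          q[a] = rot(a, 0) * (p[0] - center[0]) +
                 rot(a, 1) * (p[1] - center[1]) +
                 rot(a, 2) * (p[2] - center[2]) + center[a] + trans[a];
        double x = (q[0] - morigin[0]) / mspacing[0];
        double y = (q[1] - morigin[1]) / mspacing[1];
        double z = (q[2] - morigin[2]) / mspacing[2];
        int x0 = (int) std::floor(x), y0 = (int) std::floor(y),
            z0 = (int) std::floor(z);
        if (x0 < 0 || y0 < 0 || z0 < 0 ||
            x0 + 1 >= md[0] || y0 + 1 >= md[1] || z0 + 1 >= md[2]) {
          // allow exact hits on the upper boundary
          if (x >= 0 && y >= 0 && z >= 0 &&
              x <= md[0] - 1 && y <= md[1] - 1 && z <= md[2] - 1) {
            x0 = std::min(x0, md[0] - 2); y0 = std::min(y0, md[1] - 2);
            z0 = std::min(z0, md[2] - 2);
            if (x0 < 0 || y0 < 0 || z0 < 0) continue;
          } else {
            continue;
          }
        }
        double fx = x - x0, fy = y - y0, fz = z - z0;
        double acc = 0.0;
        for (int dz = 0; dz <= 1; ++dz)
          for (int dy = 0; dy <= 1; ++dy)
            for (int dx = 0; dx <= 1; ++dx) {
              double w = (dx ? fx : 1 - fx) * (dy ? fy : 1 - fy) *
                         (dz ? fz : 1 - fz);
              if (w == 0) continue;
              acc += w * moving[(x0 + dx) +
                                (R_xlen_t) md[0] * ((y0 + dy) +
                                (R_xlen_t) md[1] * (z0 + dz))];
            }
        out[v] = acc;
      }
  return out;
}
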