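#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Overdamped displacement pass for spherical agents: linear spring on
// overlap (optional linear adhesion on the same pair set), forces summed
// from the pre-step configuration, displacement = clamp(F/zeta * dt).
// Internal cell list with cell edge >= the largest diameter, so every
// contacting pair lies in adjacent cells. Open space (no wrap).

// [[Rcpp::export]]
List cpp_mech_displacements(NumericMatrix pos, NumericVector radii,
                            double k, double adhesion, double zeta,
                            double dt, double max_disp) {
  const int n = pos.nrow();
  NumericMatrix disp(n, 3);
  int n_coincident = 0;
  if (n == 0) return List::create(_["disp"] = disp, _["n_coincident"] = 0);

  double lo[3], hi[3], maxd = 0;
  for (int j = 0; j < 3; ++j) { lo[j] = pos(0,j); hi[j] = pos(0,j); }
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < 3; ++j) {
      lo[j] = std::min(lo[j], pos(i,j));
      hi[j] = std::max(hi[j], pos(i,j));
    }
    maxd = std::max(maxd, 2.0 * radii[i]);
  }
  const double clen = std::max(maxd, 1e-12);
  int dims[3];
  for (int j = 0; j < 3; ++j)
    dims[j] = std::max(1, (int)std::floor((hi[j] - lo[j]) / clen) + 1);

  std::vector<std::vector<int>> cells((size_t)dims[0] * dims[1] * dims[2]);
  auto cellIdx = [&](int i, int out[3]) {
    for (int j = 0; j < 3; ++j) {
      int c = (int)((pos(i,j) - lo[j]) / clen);
      out[j] = std::min(std::max(c, 0), dims[j] - 1);
    }
  };
  int ci[3];
  for (int i = 0; i < n; ++i) {
    cellIdx(i, ci);
    cells[(ci[0] * (size_t)dims[1] + ci[1]) * dims[2] + ci[2]].push_back(i);
  }

  NumericMatrix force(n, 3);
  for (int i = 0; i < n; ++i) {
    cellIdx(i, ci);
    for (int dx = -1; dx <= 1; ++dx) {
      int ux = ci[0] + dx; if (ux < 0 || ux >= dims[0]) continue;
      for (int dy = -1; dy <= 1; ++dy) {
        int uy = ci[1] + dy; if (uy < 0 || uy >= dims[1]) continue;
        for (int dz = -1; dz <= 1; ++dz) {
          int uz = ci[2] + dz; if (uz < 0 || uz >= dims[2]) continue;
          const std::vector<int>& cell =
            cells[(ux * (size_t)dims[1] + uy) * dims[2] + uz];
          for (int j : cell) {
            if (j <= i) continue;  // each pair once; apply to both
            double ex = pos(i,0) - pos(j,0);
            double ey = pos(i,1) - pos(j,1);
            double ez = pos(i,2) - pos(j,2);
            double d = std::sqrt(ex*ex + ey*ey + ez*ez);
            double contact = radii[i] + radii[j];
            if (d >= contact) continue;
            double delta = contact - d;
            if (d < 1e-12) {
              // coincident centers: deterministic (seeded) random direction
              ++n_coincident;
              ex = norm_rand(); ey = norm_rand(); ez = norm_rand();
              d = std::sqrt(ex*ex + ey*ey + ez*ez);
              if (d < 1e-300) { ex = 1; ey = 0; ez = 0; d = 1; }
            }
            double mag = (k * delta - adhesion * delta) / d;
            force(i,0) += mag * ex; force(i,1) += mag * ey; force(i,2) += mag * ez;
            force(j,0) -= mag * ex; force(j,1) -= mag * ey; force(j,2) -= mag * ez;
          }
        }
      }
    }
  }

  for (int i = 0; i < n; ++i) {
    double mx = force(i,0) / zeta * dt;
    double my = force(i,1) / zeta * dt;
    double mz = force(i,2) / zeta * dt;
    double len = std::sqrt(mx*mx + my*my + mz*mz);
    if (len > max_disp) {
      double s = max_disp / len;
      mx *= s; my *= s; mz *= s;
    }
    disp(i,0) = mx; disp(i,1) = my; disp(i,2) = mz;
  }
  return List::create(_["disp"] = disp, _["n_coincident"] = n_coincident);
}
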