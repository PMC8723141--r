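#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Vectorized core of the spatial SIR model on a toroidal cube [0, L)^3.
// Per iteration, from the committed start-of-iteration state:
//   1. every susceptible with at least one infected agent within the
//      infection radius draws one Bernoulli(p_infection) (no draw otherwise);
//   2. every infected agent draws one Bernoulli(p_recovery);
//   3. every agent moves by a uniform random unit vector times a step length
//      drawn uniformly on [0, max_step], wrapped toroidally.
// State updates are computed from the snapshot and committed together, so a
// person infected at iteration i can neither transmit nor recover before
// iteration i + 1. Uses R's RNG, hence deterministic under set.seed().

namespace {

// floor-based wrap of a coordinate onto [0, L)
inline double wrap_coord(double v, double L) {
  v -= L * std::floor(v / L);
  if (v >= L) v = 0.0;  // guard against floating-point v/L rounding to L
  return v;
}

inline double torDist2(double ax, double ay, double az,
                       double bx, double by, double bz, double L) {
  double dx = std::fabs(ax - bx); if (dx > L - dx) dx = L - dx;
  double dy = std::fabs(ay - by); if (dy > L - dy) dy = L - dy;
  double dz = std::fabs(az - bz); if (dz > L - dz) dz = L - dz;
  return dx*dx + dy*dy + dz*dz;
}

} // namespace

// states: 0 = susceptible, 1 = infected, 2 = recovered
// [[Rcpp::export]]
List cpp_sir_run(NumericMatrix pos0, IntegerVector state0,
                 double p_infection, double p_recovery,
                 double radius, double max_step, double L,
                 int n_iter, bool early_stop) {
  const int n = pos0.nrow();
  std::vector<double> x(n), y(n), z(n);
  std::vector<int> st(n);
  for (int i = 0; i < n; ++i) {
    x[i] = pos0(i,0); y[i] = pos0(i,1); z[i] = pos0(i,2);
    st[i] = state0[i];
  }

  IntegerMatrix counts(n_iter + 1, 3);
  auto record = [&](int row) {
    int s = 0, inf = 0, r = 0;
    for (int i = 0; i < n; ++i) {
      if (st[i] == 0) ++s; else if (st[i] == 1) ++inf; else ++r;
    }
    counts(row,0) = s; counts(row,1) = inf; counts(row,2) = r;
  };
  record(0);

  const int ncell = std::max(1, (int)std::floor(L / radius));
  const double clen = L / ncell;
  const double r2 = radius * radius;
  std::vector<std::vector<int>> cells(ncell * (size_t)ncell * ncell);
  std::vector<int> newly_infected; newly_infected.reserve(64);
  std::vector<int> newly_recovered; newly_recovered.reserve(64);

  for (int it = 1; it <= n_iter; ++it) {
    if (early_stop && counts(it-1,1) == 0) {
      for (int row = it; row <= n_iter; ++row)
        for (int j = 0; j < 3; ++j) counts(row,j) = counts(it-1,j);
      break;
    }

    // cell list over infected agents only (cell edge >= radius)
    for (auto& c : cells) c.clear();
    for (int i = 0; i < n; ++i) {
      if (st[i] != 1) continue;
      int cx = std::min(ncell - 1, (int)(x[i] / clen));
      int cy = std::min(ncell - 1, (int)(y[i] / clen));
      int cz = std::min(ncell - 1, (int)(z[i] / clen));
      cells[(cx * (size_t)ncell + cy) * ncell + cz].push_back(i);
    }

    newly_infected.clear();
    newly_recovered.clear();
    for (int i = 0; i < n; ++i) {
      if (st[i] != 0) continue;
      int cx = std::min(ncell - 1, (int)(x[i] / clen));
      int cy = std::min(ncell - 1, (int)(y[i] / clen));
      int cz = std::min(ncell - 1, (int)(z[i] / clen));
      bool found = false;
      for (int dx = -1; dx <= 1 && !found; ++dx)
        for (int dy = -1; dy <= 1 && !found; ++dy)
          for (int dz = -1; dz <= 1 && !found; ++dz) {
            int ux = (cx + dx + ncell) % ncell;
            int uy = (cy + dy + ncell) % ncell;
            int uz = (cz + dz + ncell) % ncell;
            const std::vector<int>& cell = cells[(ux * (size_t)ncell + uy) * ncell + uz];
            for (int j : cell) {
              if (torDist2(x[i], y[i], z[i], x[j], y[j], z[j], L) <= r2) {
                found = true; break;
              }
            }
          }
      if (found && unif_rand() < p_infection) newly_infected.push_back(i);
    }

    for (int i = 0; i < n; ++i)
      if (st[i] == 1 && unif_rand() < p_recovery) newly_recovered.push_back(i);

    for (int i : newly_infected) st[i] = 1;
    for (int i : newly_recovered) st[i] = 2;

    for (int i = 0; i < n; ++i) {
      double ux = norm_rand(), uy = norm_rand(), uz = norm_rand();
      double nrm = std::sqrt(ux*ux + uy*uy + uz*uz);
      if (nrm < 1e-300) { ux = 1; uy = 0; uz = 0; nrm = 1; }
      double step = unif_rand() * max_step;
      x[i] = wrap_coord(x[i] + step * ux / nrm, L);
      y[i] = wrap_coord(y[i] + step * uy / nrm, L);
      z[i] = wrap_coord(z[i] + step * uz / nrm, L);
    }

    record(it);
  }

  NumericMatrix pos(n, 3);
  IntegerVector stateOut(n);
  for (int i = 0; i < n; ++i) {
    pos(i,0) = x[i]; pos(i,1) = y[i]; pos(i,2) = z[i];
    stateOut[i] = st[i];
  }
  return List::create(_["counts"] = counts, _["positions"] = pos,
                      _["state"] = stateOut);
}
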