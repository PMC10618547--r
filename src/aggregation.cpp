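// Off-lattice particle-cluster aggregation (diffusion-limited and ballistic)
// on a uniform cell grid.  Walkers are launched from a circle of radius
// L = r_max + delta; random-walk steps use the standard long-jump
// acceleration (an isotropic jump of length d_near - 1 is harmonic-measure
// preserving inside an empty disk), ballistic trajectories are ray-marched.
// Contact placement solves the quadratic for the step fraction at which the
// distance to the first contacted particle is exactly 1, so centers of
// touching disks sit at unit distance up to floating-point error.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

namespace {

inline int64_t cell_key(int ix, int iy) {
  return (static_cast<int64_t>(ix) << 32) ^
         static_cast<int64_t>(static_cast<uint32_t>(iy));
}

struct ParticleGrid {
  // cell size 1: a unit-contact query never needs more than a 3x3 block
  std::vector<double> x, y;
  std::unordered_map<int64_t, std::vector<int>> cells;
  double r_max = 0.0;
  double sum_r2 = 0.0;  // for the radius of gyration about the origin

  void add(double px, double py) {
    int id = static_cast<int>(x.size());
    x.push_back(px);
    y.push_back(py);
    cells[cell_key(static_cast<int>(std::floor(px)),
                   static_cast<int>(std::floor(py)))].push_back(id);
    double r2 = px * px + py * py;
    sum_r2 += r2;
    double r = std::sqrt(r2);
    if (r > r_max) r_max = r;
  }

  // exact euclidean distance to the nearest particle (expanding ring scan)
  double nearest(double px, double py) const {
    int cx = static_cast<int>(std::floor(px));
    int cy = static_cast<int>(std::floor(py));
    double best = R_PosInf;
    double span = std::sqrt(px * px + py * py) + r_max + 2.0;
    for (int k = 0;; ++k) {
      // any particle in a ring-k cell is at distance >= k - 1
      if (best < static_cast<double>(k - 1)) break;
      if (static_cast<double>(k) > span) break;
      for (int ix = cx - k; ix <= cx + k; ++ix) {
        for (int iy = cy - k; iy <= cy + k; ++iy) {
          if (std::max(std::abs(ix - cx), std::abs(iy - cy)) != k) continue;
          auto it = cells.find(cell_key(ix, iy));
          if (it == cells.end()) continue;
          for (int id : it->second) {
            double dx = x[id] - px, dy = y[id] - py;
            double d = std::sqrt(dx * dx + dy * dy);
            if (d < best) best = d;
          }
        }
      }
    }
    return best;
  }

  // earliest contact along p + t*(ux,uy), t in [0, s]; -1 if none.
  // Candidates live within s + 1 of the segment start.
  double first_contact(double px, double py, double ux, double uy,
                       double s) const {
    int cx = static_cast<int>(std::floor(px));
    int cy = static_cast<int>(std::floor(py));
    int kmax = static_cast<int>(std::ceil(s + 1.0)) + 1;
    double tbest = -1.0;
    for (int ix = cx - kmax; ix <= cx + kmax; ++ix) {
      for (int iy = cy - kmax; iy <= cy + kmax; ++iy) {
        auto it = cells.find(cell_key(ix, iy));
        if (it == cells.end()) continue;
        for (int id : it->second) {
          double vx = px - x[id], vy = py - y[id];
          double b = vx * ux + vy * uy;
          double c = vx * vx + vy * vy - 1.0;
          double disc = b * b - c;
          if (disc < 0.0) continue;
          double t = -b - std::sqrt(disc);
          if (t < 0.0 && c < 0.0) t = 0.0;  // defensive: started in contact
          if (t >= 0.0 && t <= s && (tbest < 0.0 || t < tbest)) tbest = t;
        }
      }
    }
    return tbest;
  }
};

}  // namespace

// model: 0 = diffusion-limited (random-walk), 1 = ballistic (straight-line)
// [[Rcpp::export]]
List grow_aggregate_cpp(int n, double delta, double kill_factor, double mfp,
                        int model, bool record_history,
                        double walker_step_budget, double global_step_budget) {
  if (n < 1) stop("n must be >= 1");
  RNGScope scope;
  ParticleGrid g;
  g.add(0.0, 0.0);

  std::vector<double> hist_n, hist_rg;
  auto record = [&](int N) {
    if (!record_history) return;
    if (N <= 1000 || N % 10 == 0 || N == n) {
      hist_n.push_back(static_cast<double>(N));
      hist_rg.push_back(std::sqrt(g.sum_r2 / N));
    }
  };
  record(1);

  double global_steps = 0.0;
  for (int i = 1; i < n; ++i) {
    double L = g.r_max + delta;
    double kill2 = (kill_factor * L) * (kill_factor * L);
    bool placed = false;
    while (!placed) {
      double a = 2.0 * M_PI * unif_rand();
      double px = L * std::cos(a), py = L * std::sin(a);
      double ux = 0.0, uy = 0.0;
      if (model == 1) {
        // aim at a uniform point of the disk of radius r_max + 1 so that
        // every chord intersecting the occupied region is reachable
        double rr = (g.r_max + 1.0) * std::sqrt(unif_rand());
        double b = 2.0 * M_PI * unif_rand();
        double dx = rr * std::cos(b) - px, dy = rr * std::sin(b) - py;
        double nrm = std::sqrt(dx * dx + dy * dy);
        ux = dx / nrm;
        uy = dy / nrm;
      }
      double steps = 0.0;
      while (true) {
        if (++steps > walker_step_budget) break;  // relaunch this walker
        if (++global_steps > global_step_budget)
          stop("aggregation exceeded its global step budget");
        double rpos = std::sqrt(px * px + py * py);
        double lb = rpos - g.r_max;  // lower bound, no grid scan needed
        double dn = (lb > 1.0 + mfp) ? lb : g.nearest(px, py);
        if (model == 0) {
          double t = 2.0 * M_PI * unif_rand();
          ux = std::cos(t);
          uy = std::sin(t);
        }
        if (dn > 1.0 + mfp) {
          double s = dn - 1.0;  // cannot make contact within this jump
          px += s * ux;
          py += s * uy;
        } else {
          double tc = g.first_contact(px, py, ux, uy, mfp);
          if (tc >= 0.0) {
            px += tc * ux;
            py += tc * uy;
            g.add(px, py);
            placed = true;
            break;
          }
          px += mfp * ux;
          py += mfp * uy;
        }
        double r2 = px * px + py * py;
        if (model == 0) {
          if (r2 > kill2) break;  // killed; relaunch
        } else {
          // ballistic walker receding beyond the occupied disk: a miss
          if (r2 > (g.r_max + 1.0) * (g.r_max + 1.0) &&
              px * ux + py * uy > 0.0)
            break;
        }
      }
    }
    record(i + 1);
  }

  NumericMatrix coords(n, 2);
  for (int i = 0; i < n; ++i) {
    coords(i, 0) = g.x[i];
    coords(i, 1) = g.y[i];
  }
  NumericMatrix hist(hist_n.size(), 2);
  for (size_t i = 0; i < hist_n.size(); ++i) {
    hist(i, 0) = hist_n[i];
    hist(i, 1) = hist_rg[i];
  }
  return List::create(_["coords"] = coords, _["history"] = hist);
}
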