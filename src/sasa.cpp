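#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

static inline std::int64_t skey(int ix, int iy, int iz) {
  const std::int64_t off = 1 << 20;
  return (((std::int64_t)(ix + off)) << 42) |
         (((std::int64_t)(iy + off)) << 21) |
          ((std::int64_t)(iz + off));
}

// Shrake-Rupley solvent-accessible surface area.
//
// Sample points come from the deterministic golden-section spiral, so
// results are reproducible across runs and platforms. A point on atom i's
// expanded sphere (radius r_i + probe) is buried when it falls strictly
// inside any other atom's expanded sphere. Per-atom area is the exposed
// point fraction times 4*pi*(r_i + probe)^2.
// [[Rcpp::export]]
NumericVector cpp_sasa(NumericMatrix xyz, NumericVector radii, double probe,
                       int n_points) {
  const int n = xyz.nrow();
  NumericVector area(n);
  if (n == 0) return area;

  // golden-section spiral directions
  std::vector<double> sx(n_points), sy(n_points), sz(n_points);
  const double ga = M_PI * (3.0 - std::sqrt(5.0));
  for (int k = 0; k < n_points; ++k) {
    double z = 1.0 - 2.0 * (k + 0.5) / n_points;
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    double phi = ga * k;
    sx[k] = r * std::cos(phi);
    sy[k] = r * std::sin(phi);
    sz[k] = z;
  }

  double rmax = 0.0;
  for (int i = 0; i < n; ++i) rmax = std::max(rmax, radii[i]);
  const double cell = 2.0 * (rmax + probe);

  std::unordered_map<std::int64_t, std::vector<int> > cm;
  for (int i = 0; i < n; ++i)
    cm[skey((int)std::floor(xyz(i, 0) / cell),
            (int)std::floor(xyz(i, 1) / cell),
            (int)std::floor(xyz(i, 2) / cell))].push_back(i);

  std::vector<int> nbr;
  for (int i = 0; i < n; ++i) {
    const double ri = radii[i] + probe;
    const double xi = xyz(i, 0), yi = xyz(i, 1), zi = xyz(i, 2);
    nbr.clear();
    int ix = (int)std::floor(xi / cell);
    int iy = (int)std::floor(yi / cell);
    int iz = (int)std::floor(zi / cell);
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          std::unordered_map<std::int64_t, std::vector<int> >::const_iterator
            it = cm.find(skey(ix + dx, iy + dy, iz + dz));
          if (it == cm.end()) continue;
          for (size_t k = 0; k < it->second.size(); ++k) {
            int j = it->second[k];
            if (j == i) continue;
            double rj = radii[j] + probe;
            double ddx = xi - xyz(j, 0), ddy = yi - xyz(j, 1),
                   ddz = zi - xyz(j, 2);
            double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
            double lim = ri + rj;
            if (d2 < lim * lim) nbr.push_back(j);
          }
        }

    int exposed = 0;
    for (int k = 0; k < n_points; ++k) {
      double px = xi + ri * sx[k], py = yi + ri * sy[k], pz = zi + ri * sz[k];
      bool buried = false;
      for (size_t m = 0; m < nbr.size(); ++m) {
        int j = nbr[m];
        double rj = radii[j] + probe;
        double ddx = px - xyz(j, 0), ddy = py - xyz(j, 1),
               ddz = pz - xyz(j, 2);
        if (ddx * ddx + ddy * ddy + ddz * ddz < rj * rj) {
          buried = true;
          break;
        }
      }
      if (!buried) ++exposed;
    }
    area[i] = (double)exposed / n_points * 4.0 * M_PI * ri * ri;
  }
  return area;
}
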