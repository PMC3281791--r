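#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>

using namespace Rcpp;

// Shared grid marking. Cell centers sit at integer multiples of `spacing`
// in the global frame (origin snapped to the lattice), so translating a
// body by a lattice vector leaves the occupied-cell count exactly
// invariant. A cell is solid when its center lies within the expanded
// radius rexp[i] of any atom.
struct Grid {
  int nx, ny, nz;
  int ix0, iy0, iz0; // index of first cell (center = index * spacing)
  double spacing;
  std::vector<unsigned char> solid;
  inline size_t idx(int i, int j, int k) const {
    return ((size_t)k * ny + j) * nx + i;
  }
};

static Grid mark_grid(const NumericMatrix &xyz, const NumericVector &rexp,
                      double spacing, int margin) {
  Grid g;
  g.spacing = spacing;
  const int n = xyz.nrow();
  double rmax = 0.0;
  for (int i = 0; i < n; ++i) rmax = std::max(rmax, (double)rexp[i]);
  double xmin = R_PosInf, ymin = R_PosInf, zmin = R_PosInf;
  double xmax = R_NegInf, ymax = R_NegInf, zmax = R_NegInf;
  for (int i = 0; i < n; ++i) {
    xmin = std::min(xmin, xyz(i, 0)); xmax = std::max(xmax, xyz(i, 0));
    ymin = std::min(ymin, xyz(i, 1)); ymax = std::max(ymax, xyz(i, 1));
    zmin = std::min(zmin, xyz(i, 2)); zmax = std::max(zmax, xyz(i, 2));
  }
  g.ix0 = (int)std::floor((xmin - rmax) / spacing) - margin;
  g.iy0 = (int)std::floor((ymin - rmax) / spacing) - margin;
  g.iz0 = (int)std::floor((zmin - rmax) / spacing) - margin;
  g.nx = (int)std::ceil((xmax + rmax) / spacing) + margin - g.ix0 + 1;
  g.ny = (int)std::ceil((ymax + rmax) / spacing) + margin - g.iy0 + 1;
  g.nz = (int)std::ceil((zmax + rmax) / spacing) + margin - g.iz0 + 1;
  g.solid.assign((size_t)g.nx * g.ny * g.nz, 0);

  for (int a = 0; a < n; ++a) {
    const double r = rexp[a];
    if (r <= 0) continue;
    const double r2 = r * r;
    const double x = xyz(a, 0), y = xyz(a, 1), z = xyz(a, 2);
    int ilo = (int)std::ceil((x - r) / spacing), ihi = (int)std::floor((x + r) / spacing);
    int jlo = (int)std::ceil((y - r) / spacing), jhi = (int)std::floor((y + r) / spacing);
    int klo = (int)std::ceil((z - r) / spacing), khi = (int)std::floor((z + r) / spacing);
    for (int k = klo; k <= khi; ++k) {
      double dz = k * spacing - z;
      for (int j = jlo; j <= jhi; ++j) {
        double dy = j * spacing - y;
        double dyz = dy * dy + dz * dz;
        if (dyz > r2) continue;
        for (int i = ilo; i <= ihi; ++i) {
          double dx = i * spacing - x;
          if (dx * dx + dyz <= r2)
            g.solid[g.idx(i - g.ix0, j - g.iy0, k - g.iz0)] = 1;
        }
      }
    }
  }
  return g;
}

// [[Rcpp::export]]
List cpp_grid_volume(NumericMatrix xyz, NumericVector rexp, double spacing) {
  Grid g = mark_grid(xyz, rexp, spacing, 0);
  size_t occ = 0;
  for (size_t i = 0; i < g.solid.size(); ++i) occ += g.solid[i];
  return List::create(_["occupied_cells"] = (double)occ,
                      _["volume"] = occ * spacing * spacing * spacing);
}

// Flood-fill cavity detection: solvent cells reachable from the bounding
// box boundary (6-connectivity) are exterior; remaining empty components
// are interior cavities.
// [[Rcpp::export]]
List cpp_cavities(NumericMatrix xyz, NumericVector rexp, double spacing) {
  Grid g = mark_grid(xyz, rexp, spacing, 2);
  const int nx = g.nx, ny = g.ny, nz = g.nz;
  std::vector<int> label((size_t)nx * ny * nz, 0); // 0 empty, -1 exterior

  std::queue<size_t> q;
  // seed flood fill from all boundary cells
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        if (i > 0 && i < nx - 1 && j > 0 && j < ny - 1 && k > 0 && k < nz - 1)
          continue;
        size_t id = g.idx(i, j, k);
        if (!g.solid[id] && label[id] == 0) {
          label[id] = -1;
          q.push(id);
        }
      }
  const int di[6] = {1, -1, 0, 0, 0, 0};
  const int dj[6] = {0, 0, 1, -1, 0, 0};
  const int dk[6] = {0, 0, 0, 0, 1, -1};
  while (!q.empty()) {
    size_t id = q.front(); q.pop();
    int i = (int)(id % nx), j = (int)((id / nx) % ny), k = (int)(id / ((size_t)nx * ny));
    for (int m = 0; m < 6; ++m) {
      int ii = i + di[m], jj = j + dj[m], kk = k + dk[m];
      if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
        continue;
      size_t jd = g.idx(ii, jj, kk);
      if (!g.solid[jd] && label[jd] == 0) {
        label[jd] = -1;
        q.push(jd);
      }
    }
  }

  // remaining empty cells -> connected components (cavities)
  std::vector<double> counts, cx, cy, cz;
  int ncav = 0;
  for (int k0 = 0; k0 < nz; ++k0)
    for (int j0 = 0; j0 < ny; ++j0)
      for (int i0 = 0; i0 < nx; ++i0) {
        size_t s = g.idx(i0, j0, k0);
        if (g.solid[s] || label[s] != 0) continue;
        ++ncav;
        double cnt = 0, sx = 0, sy = 0, sz = 0;
        label[s] = ncav;
        q.push(s);
        while (!q.empty()) {
          size_t id = q.front(); q.pop();
          int i = (int)(id % nx), j = (int)((id / nx) % ny),
              k = (int)(id / ((size_t)nx * ny));
          cnt += 1.0;
          sx += (i + g.ix0) * spacing;
          sy += (j + g.iy0) * spacing;
          sz += (k + g.iz0) * spacing;
          for (int m = 0; m < 6; ++m) {
            int ii = i + di[m], jj = j + dj[m], kk = k + dk[m];
            if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
              continue;
            size_t jd = g.idx(ii, jj, kk);
            if (!g.solid[jd] && label[jd] == 0) {
              label[jd] = ncav;
              q.push(jd);
            }
          }
        }
        counts.push_back(cnt);
        cx.push_back(sx / cnt);
        cy.push_back(sy / cnt);
        cz.push_back(sz / cnt);
      }
  return List::create(_["cell_count"] = wrap(counts), _["cx"] = wrap(cx),
                      _["cy"] = wrap(cy), _["cz"] = wrap(cz));
}
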