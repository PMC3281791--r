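#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Spatial hash key for an integer cell coordinate. Coordinates are offset
// so they stay positive for any realistic structure extent.
static inline std::int64_t cell_key(int ix, int iy, int iz) {
  const std::int64_t off = 1 << 20;
  return (((std::int64_t)(ix + off)) << 42) |
         (((std::int64_t)(iy + off)) << 21) |
          ((std::int64_t)(iz + off));
}

typedef std::unordered_map<std::int64_t, std::vector<int> > CellMap;

static CellMap build_cells(const NumericMatrix &xyz, double cell) {
  CellMap cm;
  for (int i = 0; i < xyz.nrow(); ++i) {
    int ix = (int)std::floor(xyz(i, 0) / cell);
    int iy = (int)std::floor(xyz(i, 1) / cell);
    int iz = (int)std::floor(xyz(i, 2) / cell);
    cm[cell_key(ix, iy, iz)].push_back(i);
  }
  return cm;
}

// All pairs (i in a, j in b) with Euclidean distance strictly below cutoff.
// Exact: cell size >= cutoff guarantees candidate completeness over the
// 27 neighbouring cells.
// [[Rcpp::export]]
List cpp_neighbor_pairs(NumericMatrix a, NumericMatrix b, double cutoff) {
  std::vector<int> ri, rj;
  std::vector<double> rd;
  if (a.nrow() > 0 && b.nrow() > 0) {
    const double cell = cutoff;
    CellMap cm = build_cells(b, cell);
    const double cut2 = cutoff * cutoff;
    for (int i = 0; i < a.nrow(); ++i) {
      double x = a(i, 0), y = a(i, 1), z = a(i, 2);
      int ix = (int)std::floor(x / cell);
      int iy = (int)std::floor(y / cell);
      int iz = (int)std::floor(z / cell);
      for (int dx = -1; dx <= 1; ++dx)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dz = -1; dz <= 1; ++dz) {
            CellMap::const_iterator it =
              cm.find(cell_key(ix + dx, iy + dy, iz + dz));
            if (it == cm.end()) continue;
            const std::vector<int> &v = it->second;
            for (size_t k = 0; k < v.size(); ++k) {
              int j = v[k];
              double ddx = x - b(j, 0), ddy = y - b(j, 1), ddz = z - b(j, 2);
              double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
              if (d2 < cut2) {
                ri.push_back(i + 1);
                rj.push_back(j + 1);
                rd.push_back(std::sqrt(d2));
              }
            }
          }
    }
  }
  return List::create(_["i"] = wrap(ri), _["j"] = wrap(rj),
                      _["dist"] = wrap(rd));
}
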