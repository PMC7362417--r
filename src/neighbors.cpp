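#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Cell-list accelerated pair searches between two coordinate sets (n x 3, Å).
// Atoms of B are binned into cubic cells of edge = cutoff; each atom of A is
// tested only against the 27 cells around its own. Distances use the strict
// inequality d < cutoff, matching the contact definition.

namespace {

inline long long cell_key(int ix, int iy, int iz) {
  // pack three 21-bit signed cell indices into one key
  const long long off = 1LL << 20;
  return (((long long)(ix + off)) << 42) |
         (((long long)(iy + off)) << 21) |
         ((long long)(iz + off));
}

typedef std::unordered_map<long long, std::vector<int> > CellMap;

CellMap build_cells(const NumericMatrix& B, double inv_cell) {
  CellMap cells;
  cells.reserve(B.nrow());
  for (int j = 0; j < B.nrow(); ++j) {
    int ix = (int)std::floor(B(j, 0) * inv_cell);
    int iy = (int)std::floor(B(j, 1) * inv_cell);
    int iz = (int)std::floor(B(j, 2) * inv_cell);
    cells[cell_key(ix, iy, iz)].push_back(j);
  }
  return cells;
}

} // namespace

// [[Rcpp::export]]
double cpp_min_dist(NumericMatrix A, NumericMatrix B) {
  if (A.nrow() == 0 || B.nrow() == 0)
    stop("empty coordinate set");
  double best = R_PosInf;
  for (int i = 0; i < A.nrow(); ++i) {
    const double ax = A(i, 0), ay = A(i, 1), az = A(i, 2);
    for (int j = 0; j < B.nrow(); ++j) {
      const double dx = ax - B(j, 0), dy = ay - B(j, 1), dz = az - B(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
  }
  return std::sqrt(best);
}

// [[Rcpp::export]]
int cpp_count_within(NumericMatrix A, NumericMatrix B, double cutoff) {
  if (cutoff <= 0.0) return 0;
  const double cut2 = cutoff * cutoff;
  const double inv_cell = 1.0 / cutoff;
  CellMap cells = build_cells(B, inv_cell);
  int count = 0;
  for (int i = 0; i < A.nrow(); ++i) {
    const double ax = A(i, 0), ay = A(i, 1), az = A(i, 2);
    const int cx = (int)std::floor(ax * inv_cell);
    const int cy = (int)std::floor(ay * inv_cell);
    const int cz = (int)std::floor(az * inv_cell);
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          CellMap::const_iterator it =
              cells.find(cell_key(cx + dx, cy + dy, cz + dz));
          if (it == cells.end()) continue;
          const std::vector<int>& bucket = it->second;
          for (size_t k = 0; k < bucket.size(); ++k) {
            const int j = bucket[k];
            const double ux = ax - B(j, 0), uy = ay - B(j, 1),
                         uz = az - B(j, 2);
            if (ux * ux + uy * uy + uz * uz < cut2) ++count;
          }
        }
  }
  return count;
}

// [[Rcpp::export]]
List cpp_pairs_within(NumericMatrix A, NumericMatrix B, double cutoff) {
  std::vector<int> ii, jj;
  if (cutoff > 0.0) {
    const double cut2 = cutoff * cutoff;
    const double inv_cell = 1.0 / cutoff;
    CellMap cells = build_cells(B, inv_cell);
    for (int i = 0; i < A.nrow(); ++i) {
      const double ax = A(i, 0), ay = A(i, 1), az = A(i, 2);
      const int cx = (int)std::floor(ax * inv_cell);
      const int cy = (int)std::floor(ay * inv_cell);
      const int cz = (int)std::floor(az * inv_cell);
      for (int dx = -1; dx <= 1; ++dx)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dz = -1; dz <= 1; ++dz) {
            CellMap::const_iterator it =
                cells.find(cell_key(cx + dx, cy + dy, cz + dz));
            if (it == cells.end()) continue;
            const std::vector<int>& bucket = it->second;
            for (size_t k = 0; k < bucket.size(); ++k) {
              const int j = bucket[k];
              const double ux = ax - B(j, 0), uy = ay - B(j, 1),
                           uz = az - B(j, 2);
              if (ux * ux + uy * uy + uz * uz < cut2) {
                ii.push_back(i + 1);
                jj.push_back(j + 1);
              }
            }
          }
    }
  }
  return List::create(_["i"] = wrap(ii), _["j"] = wrap(jj));
}
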