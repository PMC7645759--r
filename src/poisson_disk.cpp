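#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Greedy dart throwing on an integer grid. Candidates are visited in the
// given order (0-based cell ids, column-major over ny x nz) and accepted when
// no previously accepted sample lies within Euclidean distance < r. Bucketed
// neighbor search keeps this linear in the number of candidates.
// [[Rcpp::export]]
IntegerVector pd_greedy(IntegerVector order, int ny, int nz, double r) {
  const double r2 = r * r;
  const double cell = std::max(r / std::sqrt(2.0), 1e-9);
  const int by = (int)std::ceil(ny / cell) + 1;
  const int bz = (int)std::ceil(nz / cell) + 1;
  const int reach = (int)std::ceil(r / cell);
  std::vector< std::vector<int> > bucket((size_t)by * bz);
  std::vector<int> accepted;
  accepted.reserve(order.size());
  for (int idx = 0; idx < order.size(); ++idx) {
    const int id = order[idx];
    const int iy = id % ny;
    const int iz = id / ny;
    const int cy = (int)(iy / cell);
    const int cz = (int)(iz / cell);
    bool ok = true;
    for (int dy = -reach; dy <= reach && ok; ++dy) {
      const int qy = cy + dy;
      if (qy < 0 || qy >= by) continue;
      for (int dz = -reach; dz <= reach && ok; ++dz) {
        const int qz = cz + dz;
        if (qz < 0 || qz >= bz) continue;
        const std::vector<int>& b = bucket[(size_t)qy + (size_t)by * qz];
        for (size_t j = 0; j < b.size(); ++j) {
          const int oy = b[j] % ny, oz = b[j] / ny;
          const double ddy = oy - iy, ddz = oz - iz;
          if (ddy * ddy + ddz * ddz < r2) { ok = false; break; }
        }
      }
    }
    if (ok) {
      bucket[(size_t)cy + (size_t)by * cz].push_back(id);
      accepted.push_back(id);
    }
  }
  return wrap(accepted);
}
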