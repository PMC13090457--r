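#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// 3D connected-component labeling by breadth-first flood fill.
// connectivity: 6 (faces), 18 (faces+edges) or 26 (faces+edges+corners).
// [[Rcpp::export(name = ".label_components_cpp")]]
List label_components_cpp(LogicalVector mask, IntegerVector dims,
                          int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;

  std::vector<int> dx, dy, dz;
  for (int cz = -1; cz <= 1; ++cz)
    for (int cy = -1; cy <= 1; ++cy)
      for (int cx = -1; cx <= 1; ++cx) {
        int m = std::abs(cx) + std::abs(cy) + std::abs(cz);
        if (m == 0) continue;
        if ((connectivity == 6 && m > 1) || (connectivity == 18 && m > 2))
          continue;
        dx.push_back(cx); dy.push_back(cy); dz.push_back(cz);
      }
  const int nb = (int)dx.size();

  IntegerVector labels(n);  // zero-initialized
  int *L = INTEGER(labels);
  const int *M = LOGICAL(mask);
  int count = 0;
  std::vector<R_xlen_t> queue;
  queue.reserve(1024);
  const R_xlen_t sxy = (R_xlen_t)nx * ny;

  for (R_xlen_t seed = 0; seed < n; ++seed) {
    if (!M[seed] || L[seed] != 0) continue;
    ++count;
    L[seed] = count;
    queue.clear();
    queue.push_back(seed);
    while (!queue.empty()) {
      R_xlen_t cur = queue.back();
      queue.pop_back();
      int cx = (int)(cur % nx);
      int cy = (int)((cur / nx) % ny);
      int cz = (int)(cur / sxy);
      for (int k = 0; k < nb; ++k) {
        int px = cx + dx[k], py = cy + dy[k], pz = cz + dz[k];
        if (px < 0 || px >= nx || py < 0 || py >= ny || pz < 0 || pz >= nz)
          continue;
        R_xlen_t q = (R_xlen_t)pz * sxy + (R_xlen_t)py * nx + px;
        if (M[q] && L[q] == 0) {
          L[q] = count;
          queue.push_back(q);
        }
      }
    }
  }
  labels.attr("dim") = dims;
  return List::create(_["labels"] = labels, _["count"] = count);
}
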