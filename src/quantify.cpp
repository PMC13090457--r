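#include <Rcpp.h>

using namespace Rcpp;

// One-pass tally used by quantify_kidney: for each stratification depth d,
// the cortical-shell voxel count (kidney & dist <= d) and the embolic
// intersection count (vessel & kidney & dist <= d), plus the kidney total.
// Results are identical to composing stratify + count_intersection_voxels;
// this avoids materializing per-depth masks on multi-million-voxel grids.
// [[Rcpp::export(name = ".region_stats_cpp")]]
List region_stats_cpp(LogicalVector vessel, LogicalVector kidney,
                      NumericVector dist, NumericVector depths) {
  const int nd = depths.size();
  std::vector<double> shell(nd, 0.0), inter(nd, 0.0);
  double kid_total = 0.0;
  const R_xlen_t n = kidney.size();
  const int *K = LOGICAL(kidney);
  const int *V = LOGICAL(vessel);
  const double *D = REAL(dist);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!K[i]) continue;
    kid_total += 1.0;
    const double dv = D[i];
    for (int j = 0; j < nd; ++j) {
      if (dv <= depths[j]) {
        shell[j] += 1.0;
        if (V[i]) inter[j] += 1.0;
      }
    }
  }
  return List::create(_["shell_voxels"] = shell,
                      _["intersect_voxels"] = inter,
                      _["kidney_voxels"] = kid_total);
}
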