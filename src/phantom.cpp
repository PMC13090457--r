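#include <Rcpp.h>

using namespace Rcpp;

// Ellipsoid indicator on voxel centers: ((c - center)/a)^2 summed <= 1.
// center_vox and semi_vox are in voxel units (voxel i has center i - 0.5).
// [[Rcpp::export(name = ".ellipsoid_mask_cpp")]]
LogicalVector ellipsoid_mask_cpp(IntegerVector dims, NumericVector center_vox,
                                 NumericVector semi_vox) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  LogicalVector out((R_xlen_t)nx * ny * nz);
  int *o = LOGICAL(out);
  std::vector<double> ux(nx), uy(ny), uz(nz);
  for (int i = 0; i < nx; ++i) {
    double t = (i + 0.5 - center_vox[0]) / semi_vox[0]; ux[i] = t * t;
  }
  for (int j = 0; j < ny; ++j) {
    double t = (j + 0.5 - center_vox[1]) / semi_vox[1]; uy[j] = t * t;
  }
  for (int k = 0; k < nz; ++k) {
    double t = (k + 0.5 - center_vox[2]) / semi_vox[2]; uz[k] = t * t;
  }
  R_xlen_t p = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      double ujk = uy[j] + uz[k];
      for (int i = 0; i < nx; ++i, ++p) o[p] = (ux[i] + ujk <= 1.0);
    }
  out.attr("dim") = dims;
  return out;
}

// Zero-clamped additive Gaussian noise drawing from R's RNG stream, so
// set.seed() reproducibility is identical to a stats::rnorm implementation.
// [[Rcpp::export(name = ".add_noise_cpp")]]
NumericVector add_noise_cpp(NumericVector vol, double sigma) {
  R_xlen_t n = vol.size();
  NumericVector out(n);
  RNGScope scope;
  for (R_xlen_t i = 0; i < n; ++i) {
    double v = vol[i] + norm_rand() * sigma;
    out[i] = v < 0 ? 0 : v;
  }
  out.attr("dim") = vol.attr("dim");
  return out;
}
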