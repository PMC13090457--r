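#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

// Felzenszwalb & Huttenlocher separable 1D squared distance transform.
// f: sampled function along one line (squared distances so far), d: output.
// Foreground cells are seeded with a large finite constant instead of
// infinity so envelope intersections of two seeded parabolas stay finite
// (inf - inf would poison the hull bookkeeping).
static const double DT_BIG = 1e20;

static void dt1d(const double *f, double *d, int n,
                 std::vector<int> &v, std::vector<double> &z) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) {
        --k;
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact Euclidean distance (voxel units) from each foreground voxel center
// to the nearest background voxel center; background voxels get 0.
// [[Rcpp::export(name = ".edt_cpp")]]
NumericVector edt_cpp(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  double *D = REAL(out);
  for (R_xlen_t i = 0; i < n; ++i) D[i] = mask[i] ? DT_BIG : 0.0;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x (stride 1)
  for (int zz = 0; zz < nz; ++zz)
    for (int yy = 0; yy < ny; ++yy) {
      double *line = D + (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx;
      dt1d(line, f.data(), nx, v, z);
      for (int xx = 0; xx < nx; ++xx) line[xx] = f[xx];
    }
  // pass along y (stride nx)
  for (int zz = 0; zz < nz; ++zz)
    for (int xx = 0; xx < nx; ++xx) {
      double *base = D + (R_xlen_t)zz * nx * ny + xx;
      for (int yy = 0; yy < ny; ++yy) f[yy] = base[(R_xlen_t)yy * nx];
      dt1d(f.data(), d.data(), ny, v, z);
      for (int yy = 0; yy < ny; ++yy) base[(R_xlen_t)yy * nx] = d[yy];
    }
  // pass along z (stride nx*ny)
  const R_xlen_t sxy = (R_xlen_t)nx * ny;
  for (int yy = 0; yy < ny; ++yy)
    for (int xx = 0; xx < nx; ++xx) {
      double *base = D + (R_xlen_t)yy * nx + xx;
      for (int zz = 0; zz < nz; ++zz) f[zz] = base[(R_xlen_t)zz * sxy];
      dt1d(f.data(), d.data(), nz, v, z);
      for (int zz = 0; zz < nz; ++zz) base[(R_xlen_t)zz * sxy] = d[zz];
    }

  for (R_xlen_t i = 0; i < n; ++i) D[i] = std::sqrt(D[i]);
  return out;
}
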