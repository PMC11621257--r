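#include <Rcpp.h>
#include <vector>
#include <limits>
#include <algorithm>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// 1-D lower-envelope squared distance transform (Felzenszwalb & Huttenlocher)
// on samples at physical positions x_i = i*h. f holds squared distances from
// previous passes (INF where no feature reachable); d receives the result.
static void dt1d(const double* f, double* d, int n, double h,
                 std::vector<int>& v, std::vector<double>& z) {
  int k = -1;
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue;
    double xq = q * h;
    while (k >= 0) {
      double xv = v[k] * h;
      double s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * (xq - xv));
      if (s <= z[k]) {
        --k;
      } else {
        break;
      }
    }
    if (k < 0) {
      k = 0;
      v[0] = q;
      z[0] = -INF;
      z[1] = INF;
    } else {
      double xv = v[k] * h;
      double s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * (xq - xv));
      ++k;
      v[k] = q;
      z[k] = s;
      z[k + 1] = INF;
    }
  }
  if (k < 0) {  // no finite sample on this line
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  int j = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * h;
    while (z[j + 1] < xq) ++j;
    double dx = xq - v[j] * h;
    d[q] = dx * dx + f[v[j]];
  }
}

// Exact squared Euclidean distance (mm^2) from every voxel centre to the
// nearest feature-voxel centre, honouring anisotropic spacing. Column-major
// (R) layout, dims = (nx, ny, nz).
// [[Rcpp::export]]
NumericVector cpp_edt_squared(LogicalVector feature, IntegerVector dim,
                              NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (feature.size() != n)
    stop("feature length does not match dim");
  NumericVector D(n);
  for (R_xlen_t i = 0; i < n; ++i) D[i] = feature[i] ? 0.0 : INF;

  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  const R_xlen_t sxy = (R_xlen_t)nx * ny;

  // pass along x
  for (int zz = 0; zz < nz; ++zz) {
    for (int y = 0; y < ny; ++y) {
      const R_xlen_t base = (R_xlen_t)zz * sxy + (R_xlen_t)y * nx;
      for (int x = 0; x < nx; ++x) f[x] = D[base + x];
      dt1d(f.data(), d.data(), nx, spacing[0], v, z);
      for (int x = 0; x < nx; ++x) D[base + x] = d[x];
    }
  }
  // pass along y
  for (int zz = 0; zz < nz; ++zz) {
    for (int x = 0; x < nx; ++x) {
      const R_xlen_t base = (R_xlen_t)zz * sxy + x;
      for (int y = 0; y < ny; ++y) f[y] = D[base + (R_xlen_t)y * nx];
      dt1d(f.data(), d.data(), ny, spacing[1], v, z);
      for (int y = 0; y < ny; ++y) D[base + (R_xlen_t)y * nx] = d[y];
    }
  }
  // pass along z
  for (int y = 0; y < ny; ++y) {
    for (int x = 0; x < nx; ++x) {
      const R_xlen_t base = (R_xlen_t)y * nx + x;
      for (int zz = 0; zz < nz; ++zz) f[zz] = D[base + (R_xlen_t)zz * sxy];
      dt1d(f.data(), d.data(), nz, spacing[2], v, z);
      for (int zz = 0; zz < nz; ++zz) D[base + (R_xlen_t)zz * sxy] = d[zz];
    }
  }
  return D;
}
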