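#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Exact squared Euclidean distance transform, Felzenszwalb & Huttenlocher
// (2012) separable lower-envelope algorithm. Distances are in voxel units;
// voxels where mask == FALSE are sources (distance 0), mask == TRUE voxels
// receive the squared distance to the nearest source voxel centre.

static const double DT_INF = 1e30;

static void dt1d(std::vector<double> &f, std::vector<double> &d, int n,
                 std::vector<int> &v, std::vector<double> &z) {
  int k = 0;
  v[0] = 0;
  z[0] = -DT_INF;
  z[1] = DT_INF;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = DT_INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = (double)q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? DT_INF : 0.0;
  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x
  if (nx > 1) {
    for (int zz = 0; zz < nz; ++zz) {
      for (int y = 0; y < ny; ++y) {
        R_xlen_t base = (R_xlen_t)nx * (y + (R_xlen_t)ny * zz);
        bool any = false;
        for (int x = 0; x < nx; ++x) { f[x] = out[base + x]; if (f[x] > 0) any = true; }
        if (!any) continue;
        dt1d(f, d, nx, v, z);
        for (int x = 0; x < nx; ++x) out[base + x] = d[x];
      }
    }
  }
  // pass along y
  if (ny > 1) {
    for (int zz = 0; zz < nz; ++zz) {
      for (int x = 0; x < nx; ++x) {
        R_xlen_t base = x + (R_xlen_t)nx * ny * zz;
        for (int y = 0; y < ny; ++y) f[y] = out[base + (R_xlen_t)nx * y];
        dt1d(f, d, ny, v, z);
        for (int y = 0; y < ny; ++y) out[base + (R_xlen_t)nx * y] = d[y];
      }
    }
  }
  // pass along z
  if (nz > 1) {
    const R_xlen_t nxy = (R_xlen_t)nx * ny;
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        R_xlen_t base = x + (R_xlen_t)nx * y;
        for (int zz = 0; zz < nz; ++zz) f[zz] = out[base + nxy * zz];
        dt1d(f, d, nz, v, z);
        for (int zz = 0; zz < nz; ++zz) out[base + nxy * zz] = d[zz];
      }
    }
  }
  return out;
}
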