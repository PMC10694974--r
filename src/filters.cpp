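#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Per-slice (z-planes of the passed array) image filters. Callers permute
// the volume so that the slicing axis is the third dimension.

// Non-local means, slice by slice. Patch radius pr, search radius sr,
// filtering strength h (same scale as the grey values). Patch distances
// use mean squared difference; edge patches are cropped symmetrically.
// [[Rcpp::export]]
NumericVector cpp_nlm_slices(NumericVector img, IntegerVector dim,
                             double h, int pr, int sr) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  NumericVector out((R_xlen_t)nxy * nz);
  const double h2 = std::max(h * h, 1e-12);
  for (int zz = 0; zz < nz; ++zz) {
    const double *sl = &img[nxy * zz];
    double *ot = &out[nxy * zz];
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        double wsum = 0.0, vsum = 0.0;
        for (int by = std::max(0, y - sr); by <= std::min(ny - 1, y + sr); ++by) {
          for (int bx = std::max(0, x - sr); bx <= std::min(nx - 1, x + sr); ++bx) {
            // symmetric crop of the patch so both centres stay in bounds
            int rx0 = -pr, rx1 = pr, ry0 = -pr, ry1 = pr;
            if (x + rx0 < 0) rx0 = -x;       if (bx + rx0 < 0) rx0 = -bx;
            if (x + rx1 >= nx) rx1 = nx - 1 - x; if (bx + rx1 >= nx) rx1 = nx - 1 - bx;
            if (y + ry0 < 0) ry0 = -y;       if (by + ry0 < 0) ry0 = -by;
            if (y + ry1 >= ny) ry1 = ny - 1 - y; if (by + ry1 >= ny) ry1 = ny - 1 - by;
            double d2 = 0.0; int np = 0;
            for (int ry = ry0; ry <= ry1; ++ry) {
              const double *pa = sl + (R_xlen_t)nx * (y + ry);
              const double *pb = sl + (R_xlen_t)nx * (by + ry);
              for (int rx = rx0; rx <= rx1; ++rx) {
                double df = pa[x + rx] - pb[bx + rx];
                d2 += df * df; ++np;
              }
            }
            double w = std::exp(-(d2 / np) / h2);
            wsum += w;
            vsum += w * sl[(R_xlen_t)nx * by + bx];
          }
        }
        ot[(R_xlen_t)nx * y + x] = vsum / wsum;
      }
    }
  }
  return out;
}

// Local box mean per slice (half-width wr), via integral images;
// windows are cropped at slice borders and normalised by actual size.
// [[Rcpp::export]]
NumericVector cpp_boxmean_slices(NumericVector img, IntegerVector dim, int wr) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  NumericVector out((R_xlen_t)nxy * nz);
  std::vector<double> ii((R_xlen_t)(nx + 1) * (ny + 1));
  for (int zz = 0; zz < nz; ++zz) {
    const double *sl = &img[nxy * zz];
    for (int y = 0; y <= ny; ++y) ii[(R_xlen_t)(nx + 1) * y] = 0.0;
    for (int x = 0; x <= nx; ++x) ii[x] = 0.0;
    for (int y = 1; y <= ny; ++y) {
      double rowsum = 0.0;
      for (int x = 1; x <= nx; ++x) {
        rowsum += sl[(R_xlen_t)nx * (y - 1) + (x - 1)];
        ii[(R_xlen_t)(nx + 1) * y + x] = ii[(R_xlen_t)(nx + 1) * (y - 1) + x] + rowsum;
      }
    }
    double *ot = &out[nxy * zz];
    for (int y = 0; y < ny; ++y) {
      int y0 = std::max(0, y - wr), y1 = std::min(ny - 1, y + wr);
      for (int x = 0; x < nx; ++x) {
        int x0 = std::max(0, x - wr), x1 = std::min(nx - 1, x + wr);
        double s = ii[(R_xlen_t)(nx + 1) * (y1 + 1) + (x1 + 1)]
                 - ii[(R_xlen_t)(nx + 1) * (y0) + (x1 + 1)]
                 - ii[(R_xlen_t)(nx + 1) * (y1 + 1) + (x0)]
                 + ii[(R_xlen_t)(nx + 1) * (y0) + (x0)];
        ot[(R_xlen_t)nx * y + x] = s / ((double)(y1 - y0 + 1) * (x1 - x0 + 1));
      }
    }
  }
  return out;
}

// Fill enclosed background holes slice by slice: background connected
// (4-connectivity) to the slice border stays background, the rest is
// turned into foreground.
// [[Rcpp::export]]
LogicalVector cpp_fill_holes_slices(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  LogicalVector out((R_xlen_t)nxy * nz);
  std::vector<char> reach((size_t)nxy);
  std::vector<int> stack;
  for (int zz = 0; zz < nz; ++zz) {
    const R_xlen_t base = nxy * zz;
    std::fill(reach.begin(), reach.end(), 0);
    stack.clear();
    for (int x = 0; x < nx; ++x) {
      int tops[2] = {x, nx * (ny - 1) + x};
      for (int t = 0; t < 2; ++t)
        if (!mask[base + tops[t]] && !reach[tops[t]]) { reach[tops[t]] = 1; stack.push_back(tops[t]); }
    }
    for (int y = 0; y < ny; ++y) {
      int sides[2] = {nx * y, nx * y + nx - 1};
      for (int t = 0; t < 2; ++t)
        if (!mask[base + sides[t]] && !reach[sides[t]]) { reach[sides[t]] = 1; stack.push_back(sides[t]); }
    }
    while (!stack.empty()) {
      int p = stack.back(); stack.pop_back();
      int x = p % nx, y = p / nx;
      const int nb[4][2] = {{x - 1, y}, {x + 1, y}, {x, y - 1}, {x, y + 1}};
      for (int k = 0; k < 4; ++k) {
        int xx = nb[k][0], yy = nb[k][1];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny) continue;
        int q = nx * yy + xx;
        if (!mask[base + q] && !reach[q]) { reach[q] = 1; stack.push_back(q); }
      }
    }
    for (R_xlen_t q = 0; q < nxy; ++q)
      out[base + q] = mask[base + q] || !reach[q];
  }
  return out;
}
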