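#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labeling of a 3D binary mask under 6/18/26
// connectivity via iterative BFS. Labels are 1..k in scan order.

static void make_offsets(int connectivity, int nx, R_xlen_t nxy,
                         std::vector<R_xlen_t> &off,
                         std::vector<int> &dx, std::vector<int> &dy,
                         std::vector<int> &dz) {
  for (int c = -1; c <= 1; ++c)
    for (int b = -1; b <= 1; ++b)
      for (int a = -1; a <= 1; ++a) {
        if (a == 0 && b == 0 && c == 0) continue;
        int man = std::abs(a) + std::abs(b) + std::abs(c);
        if (connectivity == 6 && man > 1) continue;
        if (connectivity == 18 && man > 2) continue;
        off.push_back((R_xlen_t)a + (R_xlen_t)nx * b + nxy * c);
        dx.push_back(a); dy.push_back(b); dz.push_back(c);
      }
}

// [[Rcpp::export]]
IntegerVector cpp_label(LogicalVector mask, IntegerVector dim, int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nxy = (R_xlen_t)nx * ny, n = nxy * nz;
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> off; std::vector<int> dx, dy, dz;
  make_offsets(connectivity, nx, nxy, off, dx, dy, dz);
  const int m = (int)off.size();
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t p = stack.back(); stack.pop_back();
      int x = (int)(p % nx), y = (int)((p / nx) % ny), zz = (int)(p / nxy);
      for (int k = 0; k < m; ++k) {
        int xx = x + dx[k], yy = y + dy[k], zc = zz + dz[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zc < 0 || zc >= nz)
          continue;
        R_xlen_t q = p + off[k];
        if (mask[q] && lab[q] == 0) { lab[q] = next; stack.push_back(q); }
      }
    }
  }
  return lab;
}

// Number of TRUE voxels among the 26 neighbours of every voxel
// (used for skeleton degree classification).
// [[Rcpp::export]]
IntegerVector cpp_neighbor_count26(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nxy = (R_xlen_t)nx * ny, n = nxy * nz;
  IntegerVector cnt(n, 0);
  std::vector<R_xlen_t> off; std::vector<int> dx, dy, dz;
  make_offsets(26, nx, nxy, off, dx, dy, dz);
  for (R_xlen_t p = 0; p < n; ++p) {
    if (!mask[p]) continue;
    int x = (int)(p % nx), y = (int)((p / nx) % ny), zz = (int)(p / nxy);
    int c = 0;
    for (int k = 0; k < 26; ++k) {
      int xx = x + dx[k], yy = y + dy[k], zc = zz + dz[k];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zc < 0 || zc >= nz)
        continue;
      if (mask[p + off[k]]) ++c;
    }
    cnt[p] = c;
  }
  return cnt;
}
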