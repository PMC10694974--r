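#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// Distance-ordered homotopic thinning of a 3D binary object down to a
// curve skeleton. Object voxels are visited in order of increasing
// Euclidean distance to the background and deleted sequentially when the
// deletion preserves topology (simple point in the (26,6) adjacency pair,
// characterised by the Bertrand/Malandain numbers T26 == 1 and T6 == 1)
// and the voxel is not a curve endpoint (<= 1 object neighbour).
// Sequential deletion keeps the process homotopic; the distance ordering
// keeps the surviving curve close to the medial axis.

namespace {

int coord_dx[26], coord_dy[26], coord_dz[26];        // 26-neighbour offsets
bool adj26[26][26];                                  // 26-adjacency between neighbour slots
bool adj6[26][26];                                   // 6-adjacency between neighbour slots
bool is_face[26];                                    // slot is a face (6-) neighbour
bool in_n18[26];                                     // slot belongs to the 18-neighbourhood
bool tables_ready = false;

void init_tables() {
  if (tables_ready) return;
  int idx = 0;
  for (int c = -1; c <= 1; ++c)
    for (int b = -1; b <= 1; ++b)
      for (int a = -1; a <= 1; ++a) {
        if (a == 0 && b == 0 && c == 0) continue;
        coord_dx[idx] = a; coord_dy[idx] = b; coord_dz[idx] = c;
        int man = std::abs(a) + std::abs(b) + std::abs(c);
        is_face[idx] = (man == 1);
        in_n18[idx] = (man <= 2);
        ++idx;
      }
  for (int i = 0; i < 26; ++i)
    for (int j = 0; j < 26; ++j) {
      int ddx = std::abs(coord_dx[i] - coord_dx[j]);
      int ddy = std::abs(coord_dy[i] - coord_dy[j]);
      int ddz = std::abs(coord_dz[i] - coord_dz[j]);
      int cheb = std::max(ddx, std::max(ddy, ddz));
      int man = ddx + ddy + ddz;
      adj26[i][j] = (i != j) && (cheb <= 1);
      adj6[i][j] = (man == 1);
    }
  tables_ready = true;
}

// T26: number of 26-connected components of object voxels in N26*(p).
// T6: number of 6-connected components of background voxels of N18*(p)
// that are 6-adjacent to p (contain a face neighbour), with connectivity
// evaluated inside the 18-neighbourhood.
bool is_simple(const bool nb[26]) {
  // T26
  int comp = 0;
  int seen[26]; std::fill(seen, seen + 26, 0);
  int stack[26], top;
  for (int i = 0; i < 26; ++i) {
    if (!nb[i] || seen[i]) continue;
    ++comp;
    if (comp > 1) return false;
    top = 0; stack[top++] = i; seen[i] = 1;
    while (top) {
      int u = stack[--top];
      for (int j = 0; j < 26; ++j)
        if (nb[j] && !seen[j] && adj26[u][j]) { seen[j] = 1; stack[top++] = j; }
    }
  }
  if (comp != 1) return false;
  // T6
  std::fill(seen, seen + 26, 0);
  int comp6 = 0;
  for (int i = 0; i < 26; ++i) {
    if (!is_face[i] || nb[i] || seen[i]) continue;
    ++comp6;
    if (comp6 > 1) return false;
    top = 0; stack[top++] = i; seen[i] = 1;
    while (top) {
      int u = stack[--top];
      for (int j = 0; j < 26; ++j)
        if (in_n18[j] && !nb[j] && !seen[j] && adj6[u][j]) { seen[j] = 1; stack[top++] = j; }
    }
  }
  return comp6 == 1;
}

} // namespace

// [[Rcpp::export]]
LogicalVector cpp_thin3d(LogicalVector mask, IntegerVector dim,
                         NumericVector priority) {
  init_tables();
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nxy = (R_xlen_t)nx * ny, n = nxy * nz;
  std::vector<uint8_t> obj((size_t)n);
  std::vector<R_xlen_t> order;
  for (R_xlen_t i = 0; i < n; ++i) {
    obj[i] = mask[i] ? 1 : 0;
    if (obj[i]) order.push_back(i);
  }
  std::stable_sort(order.begin(), order.end(),
                   [&](R_xlen_t a, R_xlen_t b) { return priority[a] < priority[b]; });

  bool nb[26];
  bool changed = true;
  while (changed) {
    changed = false;
    for (size_t s = 0; s < order.size(); ++s) {
      R_xlen_t p = order[s];
      if (!obj[p]) continue;
      int x = (int)(p % nx), y = (int)((p / nx) % ny), zz = (int)(p / nxy);
      int deg = 0;
      bool border = false;
      for (int k = 0; k < 26; ++k) {
        int xx = x + coord_dx[k], yy = y + coord_dy[k], zc = zz + coord_dz[k];
        bool inside = (xx >= 0 && xx < nx && yy >= 0 && yy < ny && zc >= 0 && zc < nz);
        bool v = inside && obj[p + coord_dx[k] + (R_xlen_t)nx * coord_dy[k] + nxy * coord_dz[k]];
        nb[k] = v;
        if (v) ++deg;
        if (is_face[k] && !v) border = true;
      }
      if (!border || deg <= 1) continue;
      if (is_simple(nb)) {
        obj[p] = 0;
        changed = true;
      }
    }
  }
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = obj[i] != 0;
  return out;
}
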