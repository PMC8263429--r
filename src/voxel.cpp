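#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Neighbour offsets for a given 3D connectivity (6 = faces, 18 = faces+edges,
// 26 = faces+edges+corners). Offsets are (dx, dy, dz) with each in {-1, 0, 1}.
static std::vector<std::array<int, 3>> neighbour_offsets(int connectivity) {
  std::vector<std::array<int, 3>> off;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int order = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (order == 0) continue;
        if (connectivity == 6 && order > 1) continue;
        if (connectivity == 18 && order > 2) continue;
        off.push_back({dx, dy, dz});
      }
  return off;
}

// Connected-component labelling of a 3D logical array (column-major, R layout).
// Labels are assigned in ascending column-major scan order of each component's
// first voxel, so the labelling is deterministic. Returns an integer vector of
// the same length: 0 outside the mask, 1..k inside.
// [[Rcpp::export]]
IntegerVector cc_label(LogicalVector mask, IntegerVector dims, int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  std::vector<std::array<int, 3>> off = neighbour_offsets(connectivity);
  IntegerVector lab(n, 0);
  int next = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    q.push(i);
    while (!q.empty()) {
      R_xlen_t cur = q.front();
      q.pop();
      int x = (int)(cur % nx);
      int y = (int)((cur / nx) % ny);
      int z = (int)(cur / ((R_xlen_t)nx * ny));
      for (size_t k = 0; k < off.size(); ++k) {
        int xx = x + off[k][0], yy = y + off[k][1], zz = z + off[k][2];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        R_xlen_t j = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
        if (mask[j] && lab[j] == 0) {
          lab[j] = next;
          q.push(j);
        }
      }
    }
  }
  return lab;
}

// Morphological inner boundary: in-mask voxels with at least one of their six
// face neighbours out-of-mask; neighbours beyond the grid count as out-of-mask,
// so in-mask voxels on the grid edge are boundary.
// [[Rcpp::export]]
LogicalVector inner_boundary(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  LogicalVector out(n, false);
  static const int face[6][3] = {{-1, 0, 0}, {1, 0, 0}, {0, -1, 0},
                                 {0, 1, 0},  {0, 0, -1}, {0, 0, 1}};
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i]) continue;
    int x = (int)(i % nx);
    int y = (int)((i / nx) % ny);
    int z = (int)(i / ((R_xlen_t)nx * ny));
    bool bnd = false;
    for (int k = 0; k < 6 && !bnd; ++k) {
      int xx = x + face[k][0], yy = y + face[k][1], zz = z + face[k][2];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) {
        bnd = true;
      } else {
        R_xlen_t j = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
        if (!mask[j]) bnd = true;
      }
    }
    out[i] = bnd;
  }
  return out;
}

// For every row of src (physical mm coordinates), the minimum Euclidean
// distance to any row of ref. Boundary point sets are small (surfaces, not
// volumes), so the exhaustive scan is adequate and exact.
// [[Rcpp::export]]
NumericVector min_pair_dists(NumericMatrix src, NumericMatrix ref) {
  const int n = src.nrow(), m = ref.nrow();
  if (m == 0) stop("reference point set is empty");
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double sx = src(i, 0), sy = src(i, 1), sz = src(i, 2);
    double best = R_PosInf;
    for (int j = 0; j < m; ++j) {
      double dx = sx - ref(j, 0), dy = sy - ref(j, 1), dz = sz - ref(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
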