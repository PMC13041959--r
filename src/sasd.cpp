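#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Voxel grid machinery for solvent-accessible surface distance (SASD).
// Grids are column-major flat arrays: index = ix + nx*(iy + ny*iz), 0-based.

// [[Rcpp::export]]
LogicalVector build_block_mask_cpp(NumericMatrix coords, NumericVector radii,
                                   NumericVector origin, IntegerVector dims,
                                   double spacing, double probe) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  LogicalVector blocked((R_xlen_t)nx * ny * nz, false);
  for (int a = 0; a < coords.nrow(); ++a) {
    const double r = radii[a] + probe;
    const double r2 = r * r;
    const double cx = coords(a, 0), cy = coords(a, 1), cz = coords(a, 2);
    int ix0 = (int)std::floor((cx - r - origin[0]) / spacing);
    int ix1 = (int)std::ceil((cx + r - origin[0]) / spacing);
    int iy0 = (int)std::floor((cy - r - origin[1]) / spacing);
    int iy1 = (int)std::ceil((cy + r - origin[1]) / spacing);
    int iz0 = (int)std::floor((cz - r - origin[2]) / spacing);
    int iz1 = (int)std::ceil((cz + r - origin[2]) / spacing);
    if (ix0 < 0) ix0 = 0; if (iy0 < 0) iy0 = 0; if (iz0 < 0) iz0 = 0;
    if (ix1 >= nx) ix1 = nx - 1;
    if (iy1 >= ny) iy1 = ny - 1;
    if (iz1 >= nz) iz1 = nz - 1;
    for (int iz = iz0; iz <= iz1; ++iz) {
      const double dz = origin[2] + iz * spacing - cz;
      for (int iy = iy0; iy <= iy1; ++iy) {
        const double dy = origin[1] + iy * spacing - cy;
        const double dyz2 = dy * dy + dz * dz;
        if (dyz2 > r2) continue;
        for (int ix = ix0; ix <= ix1; ++ix) {
          const double dx = origin[0] + ix * spacing - cx;
          if (dx * dx + dyz2 <= r2)
            blocked[(R_xlen_t)ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz)] = true;
        }
      }
    }
  }
  return blocked;
}

// Dijkstra over accessible voxels with 26-connected moves and Euclidean
// step costs (spacing * {1, sqrt2, sqrt3}); stops at the target or when the
// best remaining distance exceeds `budget` (then the target is unreachable
// within the path-length budget and +Inf is returned).
// src/dst are 0-based (ix, iy, iz) triplets.

// [[Rcpp::export]]
double grid_dijkstra_cpp(LogicalVector blocked, IntegerVector dims,
                         IntegerVector src, IntegerVector dst,
                         double spacing, double budget) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  auto idx = [&](int ix, int iy, int iz) {
    return (R_xlen_t)ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz);
  };
  const R_xlen_t s = idx(src[0], src[1], src[2]);
  const R_xlen_t t = idx(dst[0], dst[1], dst[2]);
  if (blocked[s] || blocked[t]) return R_PosInf;
  if (s == t) return 0.0;

  // 26-neighbour offsets with weights
  std::vector<int> ox, oy, oz;
  std::vector<double> ow;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        ox.push_back(dx); oy.push_back(dy); oz.push_back(dz);
        ow.push_back(spacing * std::sqrt((double)(dx*dx + dy*dy + dz*dz)));
      }

  std::vector<double> dist(n, R_PosInf);
  typedef std::pair<double, R_xlen_t> Node;
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;
  dist[s] = 0.0;
  pq.push(Node(0.0, s));
  while (!pq.empty()) {
    const Node top = pq.top(); pq.pop();
    const double d = top.first;
    const R_xlen_t u = top.second;
    if (u == t) return d;
    if (d > dist[u]) continue;
    if (d > budget) return R_PosInf;
    const int iz = (int)(u / ((R_xlen_t)nx * ny));
    const int iy = (int)((u / nx) % ny);
    const int ix = (int)(u % nx);
    for (size_t k = 0; k < ox.size(); ++k) {
      const int jx = ix + ox[k], jy = iy + oy[k], jz = iz + oz[k];
      if (jx < 0 || jy < 0 || jz < 0 || jx >= nx || jy >= ny || jz >= nz)
        continue;
      const R_xlen_t v = idx(jx, jy, jz);
      if (blocked[v]) continue;
      const double nd = d + ow[k];
      if (nd < dist[v] && nd <= budget) {
        dist[v] = nd;
        pq.push(Node(nd, v));
      }
    }
  }
  return R_PosInf;
}
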