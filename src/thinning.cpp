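#include "voxgrid.h"
using namespace Rcpp;

// Sequential topology-preserving 3-D thinning with 26-connected foreground
// and 6-connected background. A border voxel is deletable when it is a
// simple point (deletion preserves topology) and not a curve endpoint.
// Simple-point characterization (Bertrand & Malandain):
//   (a) the foreground voxels of the 26-neighborhood form exactly one
//       26-connected component, and
//   (b) the background voxels of the 18-neighborhood form exactly one
//       6-connected component that touches a face neighbor of the center.
// Six directional subiterations (U, D, N, S, E, W) with sequential deletion
// (each deletion re-checked against the current image) keep the result
// topologically faithful and reasonably centered.

namespace {

// offsets of the 3x3x3 cube positions, index p = (dz+1) + 3*(dy+1) + 9*(dx+1)
inline int cubeIndex(int dz, int dy, int dx) {
  return (dz + 1) + 3 * (dy + 1) + 9 * (dx + 1);
}

bool isSimple(const LogicalVector &mask, const Grid &g, int z, int y, int x) {
  bool cube[27];
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int zz = z + dz, yy = y + dy, xx = x + dx;
        cube[cubeIndex(dz, dy, dx)] =
          g.inside(zz, yy, xx) ? (bool)mask[g.idx(zz, yy, xx)] : false;
      }

  // (a) one 26-component of foreground in the punctured neighborhood
  bool fg[27];
  for (int p = 0; p < 27; ++p) fg[p] = cube[p];
  fg[cubeIndex(0, 0, 0)] = false;
  int nfg = 0;
  for (int p = 0; p < 27; ++p) if (fg[p]) ++nfg;
  if (nfg == 0) return false; // isolated voxel: never simple
  {
    int comp = 0;
    bool seen[27] = {false};
    for (int p0 = 0; p0 < 27; ++p0) {
      if (!fg[p0] || seen[p0]) continue;
      ++comp;
      if (comp > 1) return false;
      int stack[27], top = 0;
      stack[top++] = p0; seen[p0] = true;
      while (top) {
        int p = stack[--top];
        int dz = p % 3 - 1, dy = (p / 3) % 3 - 1, dx = p / 9 - 1;
        for (int ez = -1; ez <= 1; ++ez)
          for (int ey = -1; ey <= 1; ++ey)
            for (int ex = -1; ex <= 1; ++ex) {
              int nz2 = dz + ez, ny2 = dy + ey, nx2 = dx + ex;
              if (nz2 < -1 || nz2 > 1 || ny2 < -1 || ny2 > 1 ||
                  nx2 < -1 || nx2 > 1) continue;
              int q = cubeIndex(nz2, ny2, nx2);
              if (fg[q] && !seen[q]) { seen[q] = true; stack[top++] = q; }
            }
      }
    }
    if (comp != 1) return false;
  }

  // (b) one 6-component of background within the 18-neighborhood touching a
  //     face neighbor of the center
  {
    bool bg[27] = {false};
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          int m = std::abs(dz) + std::abs(dy) + std::abs(dx);
          if (m == 0 || m == 3) continue; // skip center and corners
          int p = cubeIndex(dz, dy, dx);
          bg[p] = !cube[p];
        }
    static const int faces[6] = {
      cubeIndex(-1, 0, 0), cubeIndex(1, 0, 0), cubeIndex(0, -1, 0),
      cubeIndex(0, 1, 0), cubeIndex(0, 0, -1), cubeIndex(0, 0, 1)};
    int comp = 0;
    bool seen[27] = {false};
    for (int s = 0; s < 6; ++s) {
      int p0 = faces[s];
      if (!bg[p0] || seen[p0]) continue;
      ++comp;
      if (comp > 1) return false;
      int stack[27], top = 0;
      stack[top++] = p0; seen[p0] = true;
      while (top) {
        int p = stack[--top];
        int dz = p % 3 - 1, dy = (p / 3) % 3 - 1, dx = p / 9 - 1;
        static const int e6[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
        for (int e = 0; e < 6; ++e) {
          int nz2 = dz + e6[e][0], ny2 = dy + e6[e][1], nx2 = dx + e6[e][2];
          if (nz2 < -1 || nz2 > 1 || ny2 < -1 || ny2 > 1 ||
              nx2 < -1 || nx2 > 1) continue;
          int q = cubeIndex(nz2, ny2, nx2);
          if (bg[q] && !seen[q]) { seen[q] = true; stack[top++] = q; }
        }
      }
    }
    if (comp != 1) return false;
  }
  return true;
}

int fgNeighborCount26(const LogicalVector &mask, const Grid &g,
                      int z, int y, int x) {
  int n = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (!dz && !dy && !dx) continue;
        int zz = z + dz, yy = y + dy, xx = x + dx;
        if (g.inside(zz, yy, xx) && mask[g.idx(zz, yy, xx)]) ++n;
      }
  return n;
}

} // namespace

// [[Rcpp::export(name = ".thin3d")]]
LogicalVector thin3d(LogicalVector mask) {
  Grid g(mask);
  LogicalVector cur = clone(mask);
  // border directions: a voxel is a d-border voxel when its neighbor in
  // direction d is background
  static const int dirs[6][3] = {
    {-1, 0, 0}, {1, 0, 0}, {0, -1, 0}, {0, 1, 0}, {0, 0, -1}, {0, 0, 1}};

  std::vector<R_xlen_t> cand;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      cand.clear();
      for (R_xlen_t i = 0; i < g.n(); ++i) {
        if (!cur[i]) continue;
        int z, y, x; g.coords(i, z, y, x);
        int zz = z + dirs[d][0], yy = y + dirs[d][1], xx = x + dirs[d][2];
        bool border = !g.inside(zz, yy, xx) || !cur[g.idx(zz, yy, xx)];
        if (!border) continue;
        int nn = fgNeighborCount26(cur, g, z, y, x);
        if (nn <= 1) continue; // endpoint or isolated: keep
        if (isSimple(cur, g, z, y, x)) cand.push_back(i);
      }
      // sequential deletion: re-check simplicity in the evolving image
      for (R_xlen_t i : cand) {
        int z, y, x; g.coords(i, z, y, x);
        if (fgNeighborCount26(cur, g, z, y, x) <= 1) continue;
        if (isSimple(cur, g, z, y, x)) { cur[i] = false; changed = true; }
      }
    }
  }
  cur.attr("dim") = mask.attr("dim");
  return cur;
}

// 26-neighbor counts for skeleton voxels (used for graph node detection)
// [[Rcpp::export(name = ".neighbor_count26")]]
IntegerVector neighbor_count26(LogicalVector mask) {
  Grid g(mask);
  IntegerVector out(g.n(), 0);
  for (R_xlen_t i = 0; i < g.n(); ++i) {
    if (!mask[i]) continue;
    int z, y, x; g.coords(i, z, y, x);
    out[i] = fgNeighborCount26(mask, g, z, y, x);
  }
  out.attr("dim") = mask.attr("dim");
  return out;
}
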