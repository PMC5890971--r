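#ifndef PULMOLOBE_VOXGRID_H
#define PULMOLOBE_VOXGRID_H

#include <Rcpp.h>
#include <vector>

// All volumes are R arrays with dim = (nz, ny, nx); the first index (z) is
// the fastest-varying one.  Linear index (0-based): z + nz*(y + ny*x).

struct Grid {
  int nz, ny, nx;
  Grid(const Rcpp::RObject &v) {
    Rcpp::IntegerVector d = v.attr("dim");
    if (d.size() != 3) Rcpp::stop("expected a 3-D array");
    nz = d[0]; ny = d[1]; nx = d[2];
  }
  inline R_xlen_t n() const { return (R_xlen_t)nz * ny * nx; }
  inline R_xlen_t idx(int z, int y, int x) const {
    return (R_xlen_t)z + (R_xlen_t)nz * ((R_xlen_t)y + (R_xlen_t)ny * x);
  }
  inline bool inside(int z, int y, int x) const {
    return z >= 0 && z < nz && y >= 0 && y < ny && x >= 0 && x < nx;
  }
  inline void coords(R_xlen_t i, int &z, int &y, int &x) const {
    z = (int)(i % nz);
    R_xlen_t r = i / nz;
    y = (int)(r % ny);
    x = (int)(r / ny);
  }
};

// neighbor offset tables (dz, dy, dx)
inline const std::vector<std::array<int,3>> &offsets6() {
  static const std::vector<std::array<int,3>> o = {
    {{-1,0,0}}, {{1,0,0}}, {{0,-1,0}}, {{0,1,0}}, {{0,0,-1}}, {{0,0,1}}
  };
  return o;
}

inline std::vector<std::array<int,3>> make_offsets(int conn) {
  std::vector<std::array<int,3>> o;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dz == 0 && dy == 0 && dx == 0) continue;
        int m = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (conn == 6 && m > 1) continue;
        if (conn == 18 && m > 2) continue;
        o.push_back({{dz, dy, dx}});
      }
  return o;
}

#endif
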