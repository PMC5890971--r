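#include "voxgrid.h"
#include <set>
#include <tuple>
#include <cmath>
using namespace Rcpp;

// Voxelization of the 3-D convex hull of a set of voxel-coordinate points
// (rows of `pts`, 0-based (z, y, x)). Facet half-spaces are enumerated by
// brute force over point triples (the point sets here are small bronchial
// centerlines), with explicit handling of degenerate rank-0/1/2 sets:
// single voxel, rasterized segment, and planar polygon of half-voxel
// thickness. A voxel belongs to the hull when its center satisfies every
// facet half-space (within a small tolerance).

namespace {

struct V3 { double z, y, x; };
inline V3 sub(const V3 &a, const V3 &b) { return {a.z - b.z, a.y - b.y, a.x - b.x}; }
inline double dot(const V3 &a, const V3 &b) { return a.z * b.z + a.y * b.y + a.x * b.x; }
inline V3 cross(const V3 &a, const V3 &b) {
  return {a.y * b.x - a.x * b.y, a.x * b.z - a.z * b.x, a.z * b.y - a.y * b.z};
}
inline double nrm(const V3 &a) { return std::sqrt(dot(a, a)); }
inline V3 scale(const V3 &a, double s) { return {a.z * s, a.y * s, a.x * s}; }

} // namespace

// [[Rcpp::export(name = ".hull_voxelize")]]
LogicalVector hull_voxelize(NumericMatrix pts, IntegerVector dims) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  R_xlen_t ntot = (R_xlen_t)nz * ny * nx;
  LogicalVector out(ntot, false);
  out.attr("dim") = dims;
  int n0 = pts.nrow();
  if (n0 == 0) return out;

  // deduplicate
  std::set<std::tuple<long long, long long, long long>> seen;
  std::vector<V3> p;
  for (int i = 0; i < n0; ++i) {
    long long a = llround(pts(i, 0) * 1e6), b = llround(pts(i, 1) * 1e6),
              c = llround(pts(i, 2) * 1e6);
    if (seen.insert(std::make_tuple(a, b, c)).second)
      p.push_back({pts(i, 0), pts(i, 1), pts(i, 2)});
  }
  int n = (int)p.size();

  // bounding box (clipped to grid)
  double mnz = p[0].z, mxz = p[0].z, mny = p[0].y, mxy = p[0].y,
         mnx = p[0].x, mxx = p[0].x;
  for (int i = 1; i < n; ++i) {
    mnz = std::min(mnz, p[i].z); mxz = std::max(mxz, p[i].z);
    mny = std::min(mny, p[i].y); mxy = std::max(mxy, p[i].y);
    mnx = std::min(mnx, p[i].x); mxx = std::max(mxx, p[i].x);
  }
  int z0 = std::max(0, (int)std::floor(mnz) - 1), z1 = std::min(nz - 1, (int)std::ceil(mxz) + 1);
  int y0 = std::max(0, (int)std::floor(mny) - 1), y1 = std::min(ny - 1, (int)std::ceil(mxy) + 1);
  int x0 = std::max(0, (int)std::floor(mnx) - 1), x1 = std::min(nx - 1, (int)std::ceil(mxx) + 1);
  Grid g(out);

  // affine rank via Gram-Schmidt over point differences
  const double rtol = 1e-7;
  std::vector<V3> basis;
  for (int i = 1; i < n && (int)basis.size() < 3; ++i) {
    V3 d = sub(p[i], p[0]);
    for (const V3 &b : basis) d = sub(d, scale(b, dot(d, b)));
    double l = nrm(d);
    if (l > rtol) basis.push_back(scale(d, 1.0 / l));
  }
  int rank = (int)basis.size();

  if (rank == 0) {
    int z = (int)llround(p[0].z), y = (int)llround(p[0].y), x = (int)llround(p[0].x);
    if (g.inside(z, y, x)) out[g.idx(z, y, x)] = true;
    return out;
  }

  if (rank == 1) {
    // segment between extreme projections; voxels within half a voxel
    V3 u = basis[0];
    double tmin = 0, tmax = 0;
    for (int i = 0; i < n; ++i) {
      double t = dot(sub(p[i], p[0]), u);
      tmin = std::min(tmin, t); tmax = std::max(tmax, t);
    }
    for (int x = x0; x <= x1; ++x)
      for (int y = y0; y <= y1; ++y)
        for (int z = z0; z <= z1; ++z) {
          V3 q = {(double)z, (double)y, (double)x};
          double t = dot(sub(q, p[0]), u);
          double tc = std::min(std::max(t, tmin), tmax);
          V3 proj = {p[0].z + tc * u.z, p[0].y + tc * u.y, p[0].x + tc * u.x};
          if (nrm(sub(q, proj)) <= 0.5 + 1e-9) out[g.idx(z, y, x)] = true;
        }
    return out;
  }

  if (rank == 2) {
    // planar: 2-D hull (monotone chain) in the (u, v) plane, half-voxel slab
    V3 u = basis[0], v = basis[1];
    V3 w = cross(u, v); w = scale(w, 1.0 / nrm(w));
    std::vector<std::pair<double, double>> q2(n);
    for (int i = 0; i < n; ++i) {
      V3 d = sub(p[i], p[0]);
      q2[i] = {dot(d, u), dot(d, v)};
    }
    std::sort(q2.begin(), q2.end());
    q2.erase(std::unique(q2.begin(), q2.end()), q2.end());
    int m = (int)q2.size();
    std::vector<std::pair<double, double>> hull(2 * m);
    int k = 0;
    auto cr = [](const std::pair<double, double> &o, const std::pair<double, double> &a,
                 const std::pair<double, double> &b) {
      return (a.first - o.first) * (b.second - o.second) -
             (a.second - o.second) * (b.first - o.first);
    };
    for (int i = 0; i < m; ++i) {
      while (k >= 2 && cr(hull[k - 2], hull[k - 1], q2[i]) <= 0) --k;
      hull[k++] = q2[i];
    }
    int lower = k + 1;
    for (int i = m - 2; i >= 0; --i) {
      while (k >= lower && cr(hull[k - 2], hull[k - 1], q2[i]) <= 0) --k;
      hull[k++] = q2[i];
    }
    hull.resize(k > 1 ? k - 1 : k);
    for (int x = x0; x <= x1; ++x)
      for (int y = y0; y <= y1; ++y)
        for (int z = z0; z <= z1; ++z) {
          V3 q = {(double)z, (double)y, (double)x};
          V3 d = sub(q, p[0]);
          if (std::fabs(dot(d, w)) > 0.5 + 1e-9) continue;
          double a = dot(d, u), b = dot(d, v);
          bool in = true;
          int h = (int)hull.size();
          for (int i = 0; i < h && in; ++i) {
            const auto &A = hull[i];
            const auto &B = hull[(i + 1) % h];
            double c = (B.first - A.first) * (b - A.second) -
                       (B.second - A.second) * (a - A.first);
            if (c < -1e-7) in = false; // monotone chain yields a CCW polygon
          }
          if (in) out[g.idx(z, y, x)] = true;
        }
    return out;
  }

  // full rank: facet half-spaces by brute force over triples
  std::vector<std::array<double, 4>> hs; // unit normal (z,y,x) and offset d
  std::set<std::tuple<long long, long long, long long, long long>> hseen;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      for (int k2 = j + 1; k2 < n; ++k2) {
        V3 nrml = cross(sub(p[j], p[i]), sub(p[k2], p[i]));
        double l = nrm(nrml);
        if (l < 1e-9) continue;
        nrml = scale(nrml, 1.0 / l);
        double d0 = dot(nrml, p[i]);
        double smin = 0, smax = 0;
        for (int t = 0; t < n; ++t) {
          double s = dot(nrml, p[t]) - d0;
          smin = std::min(smin, s); smax = std::max(smax, s);
        }
        double sgn;
        if (smax <= 1e-7) sgn = 1.0;        // all points on or below: keep n
        else if (smin >= -1e-7) sgn = -1.0; // all on or above: flip
        else continue;
        V3 nn = scale(nrml, sgn);
        double dd = d0 * sgn;
        auto key = std::make_tuple(llround(nn.z * 1e6), llround(nn.y * 1e6),
                                   llround(nn.x * 1e6), llround(dd * 1e6));
        if (hseen.insert(key).second)
          hs.push_back({{nn.z, nn.y, nn.x, dd}});
      }

  for (int x = x0; x <= x1; ++x)
    for (int y = y0; y <= y1; ++y)
      for (int z = z0; z <= z1; ++z) {
        bool in = true;
        for (const auto &h : hs) {
          if (h[0] * z + h[1] * y + h[2] * x - h[3] > 1e-7) { in = false; break; }
        }
        if (in) out[g.idx(z, y, x)] = true;
      }
  return out;
}
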