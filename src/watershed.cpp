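#include "voxgrid.h"
#include <queue>
#include <tuple>
using namespace Rcpp;

// Marker-based watershed on a scalar topography (high values act as
// barriers), restricted to a mask. Ordered flood with lexicographic
// priority (flood level, distance to the claiming marker voxel, linear
// index), where the flood level of a voxel is the maximum topography value
// along the path that reached it and the distance is the physical Euclidean
// distance to the marker voxel the flood started from. With a flat
// topography this reduces to the nearest-marker (Euclidean distance)
// partition; the index tie-break makes the result fully deterministic.
// Marker voxels keep their labels. Flooding uses 26-connectivity.
// [[Rcpp::export(name = ".watershed3d")]]
IntegerVector watershed3d(NumericVector topo, IntegerVector markers,
                          LogicalVector mask, NumericVector spacing) {
  Grid g(topo);
  auto off = make_offsets(26);
  IntegerVector out(g.n(), 0);
  out.attr("dim") = topo.attr("dim");
  struct Item {
    double level, dist;
    R_xlen_t idx, src;
    int label;
    bool operator>(const Item &o) const {
      if (level != o.level) return level > o.level;
      if (dist != o.dist) return dist > o.dist;
      return idx > o.idx;
    }
  };
  std::priority_queue<Item, std::vector<Item>, std::greater<Item>> pq;
  std::vector<char> expanded(g.n(), 0);

  for (R_xlen_t i = 0; i < g.n(); ++i) {
    if (mask[i] && markers[i] > 0) {
      out[i] = markers[i];
      pq.push({topo[i], 0.0, i, i, markers[i]});
    }
  }
  while (!pq.empty()) {
    Item it = pq.top();
    pq.pop();
    R_xlen_t v = it.idx;
    if (expanded[v]) continue; // stale offer: a better claim already expanded
    expanded[v] = 1;
    if (out[v] == 0) out[v] = it.label; // markers keep their own labels
    int z, y, x; g.coords(v, z, y, x);
    int sz, sy, sx; g.coords(it.src, sz, sy, sx);
    for (const auto &o : off) {
      int zz = z + o[0], yy = y + o[1], xx = x + o[2];
      if (!g.inside(zz, yy, xx)) continue;
      R_xlen_t j = g.idx(zz, yy, xx);
      if (!mask[j] || expanded[j] || out[j] != 0) continue;
      double dz = (zz - sz) * spacing[0], dy = (yy - sy) * spacing[1],
             dx = (xx - sx) * spacing[2];
      double dist = std::sqrt(dz * dz + dy * dy + dx * dx);
      double level = std::max(it.level, topo[j]);
      pq.push({level, dist, j, it.src, it.label});
    }
  }
  return out;
}
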