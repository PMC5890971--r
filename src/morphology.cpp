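#include "voxgrid.h"
#include <limits>
using namespace Rcpp;

// Connected-component labeling. Components are numbered 1..K in order of
// their first voxel in array scan order, which makes labels deterministic.
// [[Rcpp::export(name = ".cc_label")]]
IntegerVector cc_label(LogicalVector mask, int connectivity) {
  Grid g(mask);
  auto off = make_offsets(connectivity);
  IntegerVector lab(g.n(), 0);
  lab.attr("dim") = mask.attr("dim");
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t i = 0; i < g.n(); ++i) {
    if (!mask[i] || lab[i]) continue;
    ++next;
    lab[i] = next;
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t v = stack.back(); stack.pop_back();
      int z, y, x; g.coords(v, z, y, x);
      for (const auto &o : off) {
        int zz = z + o[0], yy = y + o[1], xx = x + o[2];
        if (!g.inside(zz, yy, xx)) continue;
        R_xlen_t j = g.idx(zz, yy, xx);
        if (mask[j] && !lab[j]) { lab[j] = next; stack.push_back(j); }
      }
    }
  }
  lab.attr("ncomp") = next;
  return lab;
}

// 26-connected flood fill of {v : hu[v] <= thr} from a seed voxel.
// [[Rcpp::export(name = ".flood_leq")]]
LogicalVector flood_leq(NumericVector hu, int seed, double thr) {
  Grid g(hu);
  auto off = make_offsets(26);
  LogicalVector out(g.n(), false);
  out.attr("dim") = hu.attr("dim");
  if (seed < 0 || seed >= g.n()) stop("seed out of range");
  if (!(hu[seed] <= thr)) return out;
  std::vector<R_xlen_t> stack;
  out[seed] = true;
  stack.push_back(seed);
  while (!stack.empty()) {
    R_xlen_t v = stack.back(); stack.pop_back();
    int z, y, x; g.coords(v, z, y, x);
    for (const auto &o : off) {
      int zz = z + o[0], yy = y + o[1], xx = x + o[2];
      if (!g.inside(zz, yy, xx)) continue;
      R_xlen_t j = g.idx(zz, yy, xx);
      if (!out[j] && hu[j] <= thr) { out[j] = true; stack.push_back(j); }
    }
  }
  return out;
}

// Binary erosion; voxels outside the grid count as background.
// [[Rcpp::export(name = ".bin_erode")]]
LogicalVector bin_erode(LogicalVector mask, int connectivity, int iterations) {
  Grid g(mask);
  auto off = make_offsets(connectivity);
  LogicalVector cur = clone(mask);
  for (int it = 0; it < iterations; ++it) {
    LogicalVector nxt = clone(cur);
    for (R_xlen_t i = 0; i < g.n(); ++i) {
      if (!cur[i]) continue;
      int z, y, x; g.coords(i, z, y, x);
      for (const auto &o : off) {
        int zz = z + o[0], yy = y + o[1], xx = x + o[2];
        if (!g.inside(zz, yy, xx) || !cur[g.idx(zz, yy, xx)]) {
          nxt[i] = false; break;
        }
      }
    }
    cur = nxt;
  }
  cur.attr("dim") = mask.attr("dim");
  return cur;
}

// [[Rcpp::export(name = ".bin_dilate")]]
LogicalVector bin_dilate(LogicalVector mask, int connectivity, int iterations) {
  Grid g(mask);
  auto off = make_offsets(connectivity);
  LogicalVector cur = clone(mask);
  for (int it = 0; it < iterations; ++it) {
    LogicalVector nxt = clone(cur);
    for (R_xlen_t i = 0; i < g.n(); ++i) {
      if (!cur[i]) continue;
      int z, y, x; g.coords(i, z, y, x);
      for (const auto &o : off) {
        int zz = z + o[0], yy = y + o[1], xx = x + o[2];
        if (g.inside(zz, yy, xx)) nxt[g.idx(zz, yy, xx)] = true;
      }
    }
    cur = nxt;
  }
  cur.attr("dim") = mask.attr("dim");
  return cur;
}

// Exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher,
// separable lower-envelope passes), anisotropic spacing in mm per axis
// (spacing order matches dim order: z, y, x). Distance TO the feature set.
static void dt1d(std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &zb, double w2) {
  const double INF = std::numeric_limits<double>::infinity();
  int n = (int)f.size();
  int k = -1; // index of rightmost parabola in the lower envelope
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue;
    if (k < 0) {
      k = 0; v[0] = q; zb[0] = -INF; zb[1] = INF;
      continue;
    }
    double s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) /
               (2.0 * w2 * (q - v[k]));
    while (s <= zb[k]) {
      --k;
      if (k < 0) break;
      s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) /
          (2.0 * w2 * (q - v[k]));
    }
    if (k < 0) { k = 0; v[0] = q; zb[0] = -INF; }
    else       { ++k;  v[k] = q; zb[k] = s;    }
    zb[k + 1] = INF;
  }
  if (k < 0) { for (int q = 0; q < n; ++q) d[q] = INF; return; }
  int j = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[j + 1] < q) ++j;
    double dq = (double)q - v[j];
    d[q] = w2 * dq * dq + f[v[j]];
  }
}

// [[Rcpp::export(name = ".edt_sq")]]
NumericVector edt_sq(LogicalVector feature, NumericVector spacing) {
  Grid g(feature);
  const double INF = std::numeric_limits<double>::infinity();
  NumericVector d(g.n());
  for (R_xlen_t i = 0; i < g.n(); ++i) d[i] = feature[i] ? 0.0 : INF;

  int dims[3] = {g.nz, g.ny, g.nx};
  for (int axis = 0; axis < 3; ++axis) {
    int n = dims[axis];
    double w2 = spacing[axis] * spacing[axis];
    std::vector<double> f(n), dd(n), zb(n + 1);
    std::vector<int> v(n);
    int n1 = dims[(axis + 1) % 3], n2 = dims[(axis + 2) % 3];
    for (int a = 0; a < n1; ++a) {
      for (int b = 0; b < n2; ++b) {
        // build the line of voxels along `axis` at cross position (a, b)
        bool any = false;
        for (int q = 0; q < n; ++q) {
          int c[3]; c[axis] = q; c[(axis + 1) % 3] = a; c[(axis + 2) % 3] = b;
          f[q] = d[g.idx(c[0], c[1], c[2])];
          if (f[q] < INF) any = true;
        }
        if (!any) continue;
        dt1d(f, dd, v, zb, w2);
        for (int q = 0; q < n; ++q) {
          int c[3]; c[axis] = q; c[(axis + 1) % 3] = a; c[(axis + 2) % 3] = b;
          d[g.idx(c[0], c[1], c[2])] = dd[q];
        }
      }
    }
  }
  d.attr("dim") = feature.attr("dim");
  return d;
}

// Minimum over a voxel subset of a volume, by component id: for each voxel i
// with comp[i] = k > 0, accumulate min of val[i] into out[k].
// [[Rcpp::export(name = ".min_by_component")]]
NumericVector min_by_component(NumericVector val, IntegerVector comp, int ncomp) {
  NumericVector out(ncomp, std::numeric_limits<double>::infinity());
  for (R_xlen_t i = 0; i < val.size(); ++i) {
    int k = comp[i];
    if (k > 0 && val[i] < out[k - 1]) out[k - 1] = val[i];
  }
  return out;
}
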