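#include "voxgrid.h"
#include <cmath>
using namespace Rcpp;

// Separable 1-D convolution along one axis (0 = z, 1 = y, 2 = x) with a
// centered odd-length kernel; borders are replicated.
// [[Rcpp::export(name = ".convolve_axis")]]
NumericVector convolve_axis(NumericVector vol, NumericVector kernel, int axis) {
  Grid g(vol);
  int kl = kernel.size();
  if (kl % 2 == 0) stop("kernel length must be odd");
  int kr = kl / 2;
  NumericVector out(g.n());
  out.attr("dim") = vol.attr("dim");
  int dims[3] = {g.nz, g.ny, g.nx};
  int n = dims[axis];
  int n1 = dims[(axis + 1) % 3], n2 = dims[(axis + 2) % 3];
  std::vector<double> line(n);
  for (int a = 0; a < n1; ++a) {
    for (int b = 0; b < n2; ++b) {
      for (int q = 0; q < n; ++q) {
        int c[3]; c[axis] = q; c[(axis + 1) % 3] = a; c[(axis + 2) % 3] = b;
        line[q] = vol[g.idx(c[0], c[1], c[2])];
      }
      for (int q = 0; q < n; ++q) {
        double acc = 0;
        for (int t = -kr; t <= kr; ++t) {
          int s = q + t;
          if (s < 0) s = 0;
          if (s >= n) s = n - 1;
          acc += line[s] * kernel[t + kr];
        }
        int c[3]; c[axis] = q; c[(axis + 1) % 3] = a; c[(axis + 2) % 3] = b;
        out[g.idx(c[0], c[1], c[2])] = acc;
      }
    }
  }
  return out;
}

// Plate-likeness from the six unique Hessian components (hzz, hyy, hxx,
// hzy, hzx, hyx), evaluated at masked voxels. Eigenvalues are ordered by
// decreasing magnitude |l1| >= |l2| >= |l3|; a bright plate (ridge of high
// HU across a thin sheet) has a strongly negative l1, so the score
//   (|l1| - |l2|) / (|l1| + |l2| + eps)
// is gated to zero unless l1 < 0 and weighted by a structureness term
// 1 - exp(-S^2 / (2 c^2)) with S the Frobenius norm of the Hessian, so
// weak noise plates do not score like true fissures. The caller passes
// c (struct_c); struct_c <= 0 disables the weighting.
// [[Rcpp::export(name = ".plate_score")]]
NumericVector plate_score(NumericVector hzz, NumericVector hyy,
                          NumericVector hxx, NumericVector hzy,
                          NumericVector hzx, NumericVector hyx,
                          LogicalVector mask, double struct_c) {
  R_xlen_t n = hzz.size();
  NumericVector out(n, 0.0);
  out.attr("dim") = hzz.attr("dim");
  const double eps = 1e-10;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i]) continue;
    double a = hzz[i], b = hyy[i], c = hxx[i];
    double d = hzy[i], e = hzx[i], f = hyx[i];
    // analytic eigenvalues of a symmetric 3x3 matrix
    double p1 = d * d + e * e + f * f;
    double l1, l2, l3;
    if (p1 < 1e-30) {
      l1 = a; l2 = b; l3 = c;
    } else {
      double q = (a + b + c) / 3.0;
      double p2 = (a - q) * (a - q) + (b - q) * (b - q) + (c - q) * (c - q) +
                  2.0 * p1;
      double p = std::sqrt(p2 / 6.0);
      // B = (A - q I) / p ; r = det(B) / 2 in [-1, 1]
      double b11 = (a - q) / p, b22 = (b - q) / p, b33 = (c - q) / p;
      double b12 = d / p, b13 = e / p, b23 = f / p;
      double r = (b11 * (b22 * b33 - b23 * b23) -
                  b12 * (b12 * b33 - b23 * b13) +
                  b13 * (b12 * b23 - b22 * b13)) / 2.0;
      if (r < -1.0) r = -1.0;
      if (r > 1.0) r = 1.0;
      double phi = std::acos(r) / 3.0;
      l1 = q + 2.0 * p * std::cos(phi);
      l3 = q + 2.0 * p * std::cos(phi + 2.0 * M_PI / 3.0);
      l2 = 3.0 * q - l1 - l3;
    }
    // sort by |.| descending
    double v[3] = {l1, l2, l3};
    for (int s = 0; s < 2; ++s)
      for (int t = 0; t < 2 - s; ++t)
        if (std::fabs(v[t]) < std::fabs(v[t + 1])) std::swap(v[t], v[t + 1]);
    if (v[0] >= 0) continue; // dark plate / blob: not a fissure candidate
    double sc = (std::fabs(v[0]) - std::fabs(v[1])) /
                (std::fabs(v[0]) + std::fabs(v[1]) + eps);
    if (struct_c > 0) {
      double s2 = v[0] * v[0] + v[1] * v[1] + v[2] * v[2];
      sc *= 1.0 - std::exp(-s2 / (2.0 * struct_c * struct_c));
    }
    out[i] = sc;
  }
  return out;
}
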