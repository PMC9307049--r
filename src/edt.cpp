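// Exact squared Euclidean distance transform, separable lower-envelope
// algorithm (one parabola pass per dimension). Distances are measured to
// foreground voxel centres on an isotropic grid. Lines may contain +Inf
// (no source yet); such parabolas never enter the envelope.
#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

static inline double intersect(const std::vector<double>& f, int q, int p,
                               double sp2) {
  return ((f[q] + (double)q * q * sp2) - (f[p] + (double)p * p * sp2)) /
         (2.0 * sp2 * (q - p));
}

static void dt1d(std::vector<double>& f, std::vector<double>& d, int n,
                 double sp2, std::vector<int>& v, std::vector<double>& z) {
  int k = -1;
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue;
    if (k < 0) {
      k = 0; v[0] = q; z[0] = -INF; z[1] = INF;
      continue;
    }
    double s = intersect(f, q, v[k], sp2);
    while (k >= 0 && s <= z[k]) {
      --k;
      if (k >= 0) s = intersect(f, q, v[k], sp2);
    }
    if (k < 0) {
      k = 0; v[0] = q; z[0] = -INF; z[1] = INF;
    } else {
      ++k; v[k] = q; z[k] = s; z[k + 1] = INF;
    }
  }
  if (k < 0) {                        // no finite source on this line
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  int j = 0;
  for (int q = 0; q < n; ++q) {
    while (z[j + 1] < (double)q) ++j;
    d[q] = sp2 * (double)(q - v[j]) * (q - v[j]) + f[v[j]];
  }
}

// [[Rcpp::export(name = ".edt3d_sq")]]
NumericVector edt3d_sq(LogicalVector mask, IntegerVector dims, double spacing) {
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  R_xlen_t total = (R_xlen_t)n1 * n2 * n3;
  NumericVector out(total);
  for (R_xlen_t i = 0; i < total; ++i) out[i] = mask[i] ? 0.0 : INF;
  double sp2 = spacing * spacing;
  int nmax = std::max(n1, std::max(n2, n3));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  for (int k3 = 0; k3 < n3; ++k3)       // pass along dim 1
    for (int k2 = 0; k2 < n2; ++k2) {
      R_xlen_t base = (R_xlen_t)k3 * n1 * n2 + (R_xlen_t)k2 * n1;
      for (int i = 0; i < n1; ++i) f[i] = out[base + i];
      dt1d(f, d, n1, sp2, v, z);
      for (int i = 0; i < n1; ++i) out[base + i] = d[i];
    }
  for (int k3 = 0; k3 < n3; ++k3)       // pass along dim 2
    for (int k1 = 0; k1 < n1; ++k1) {
      R_xlen_t base = (R_xlen_t)k3 * n1 * n2 + k1;
      for (int i = 0; i < n2; ++i) f[i] = out[base + (R_xlen_t)i * n1];
      dt1d(f, d, n2, sp2, v, z);
      for (int i = 0; i < n2; ++i) out[base + (R_xlen_t)i * n1] = d[i];
    }
  R_xlen_t plane = (R_xlen_t)n1 * n2;
  for (int k2 = 0; k2 < n2; ++k2)       // pass along dim 3
    for (int k1 = 0; k1 < n1; ++k1) {
      R_xlen_t base = (R_xlen_t)k2 * n1 + k1;
      for (int i = 0; i < n3; ++i) f[i] = out[base + (R_xlen_t)i * plane];
      dt1d(f, d, n3, sp2, v, z);
      for (int i = 0; i < n3; ++i) out[base + (R_xlen_t)i * plane] = d[i];
    }
  out.attr("dim") = dims;
  return out;
}
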