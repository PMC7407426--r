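#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Felzenszwalb & Huttenlocher exact squared Euclidean distance transform,
// one 1D lower-envelope pass per axis. Distances in voxel units.
static const double INF = std::numeric_limits<double>::infinity();

static void dt1d(std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &z, int n) {
  int k = -1; // index of rightmost parabola in the lower envelope
  for (int q = 0; q < n; q++) {
    if (f[q] == INF) continue; // an infinite parabola never enters the envelope
    if (k < 0) {
      k = 0; v[0] = q; z[0] = -INF; z[1] = INF;
      continue;
    }
    double s = 0.0;
    while (true) {
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) {
        k--;
        if (k < 0) break;
      } else break;
    }
    if (k < 0) {
      k = 0; v[0] = q; z[0] = -INF;
    } else {
      k++; v[k] = q; z[k] = s;
    }
    z[k + 1] = INF;
  }
  if (k < 0) { // whole row infinite
    for (int q = 0; q < n; q++) d[q] = INF;
    return;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    double dq = (double)q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector edt_sq_cpp(LogicalVector mask, IntegerVector dims) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t ntot = (R_xlen_t)n1 * n2 * n3;
  NumericVector out(ntot);
  for (R_xlen_t i = 0; i < ntot; i++) out[i] = mask[i] ? 0.0 : INF;

  int nmax = std::max(n1, std::max(n2, n3));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // axis 1 (fastest varying)
  for (int k = 0; k < n3; k++)
    for (int j = 0; j < n2; j++) {
      R_xlen_t base = (R_xlen_t)n1 * (j + (R_xlen_t)n2 * k);
      for (int i = 0; i < n1; i++) f[i] = out[base + i];
      dt1d(f, d, v, z, n1);
      for (int i = 0; i < n1; i++) out[base + i] = d[i];
    }
  // axis 2
  for (int k = 0; k < n3; k++)
    for (int i = 0; i < n1; i++) {
      R_xlen_t base = i + (R_xlen_t)n1 * n2 * k;
      for (int j = 0; j < n2; j++) f[j] = out[base + (R_xlen_t)n1 * j];
      dt1d(f, d, v, z, n2);
      for (int j = 0; j < n2; j++) out[base + (R_xlen_t)n1 * j] = d[j];
    }
  // axis 3
  for (int j = 0; j < n2; j++)
    for (int i = 0; i < n1; i++) {
      R_xlen_t base = i + (R_xlen_t)n1 * j;
      R_xlen_t step = (R_xlen_t)n1 * n2;
      for (int k = 0; k < n3; k++) f[k] = out[base + step * k];
      dt1d(f, d, v, z, n3);
      for (int k = 0; k < n3; k++) out[base + step * k] = d[k];
    }
  return out;
}
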