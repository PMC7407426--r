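#include <Rcpp.h>
using namespace Rcpp;

// Trilinear interpolation on voxel-center grids. Voxel (i,j,k) (1-based in R)
// has its center at ((i-0.5)*h, (j-0.5)*h, (k-0.5)*h) in mm.

static inline void locate(double x, double h, int n, bool clamp,
                          int &i0, double &u, bool &ok) {
  double t = x / h - 0.5; // continuous 0-based index
  if (clamp) {
    if (t < 0.0) t = 0.0;
    if (t > n - 1.0) t = n - 1.0;
  } else if (t < -0.5 || t > n - 0.5) {
    // outside the physical grid extent: no extrapolation
    ok = false;
    return;
  } else {
    // within the outermost half-voxel: nearest-edge extension
    if (t < 0.0) t = 0.0;
    if (t > n - 1.0) t = n - 1.0;
  }
  i0 = (int)std::floor(t);
  if (i0 > n - 2) i0 = n - 2;
  if (i0 < 0) i0 = 0;
  u = t - i0;
  ok = true;
}

// [[Rcpp::export]]
NumericVector interp_trilinear_cpp(NumericVector vol, IntegerVector dims,
                                   NumericMatrix pts, double spacing,
                                   bool clamp = false) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t npt = pts.nrow();
  NumericVector out(npt);
  for (R_xlen_t p = 0; p < npt; p++) {
    int i0, j0, k0; double u, v, w; bool ok = true;
    locate(pts(p, 0), spacing, n1, clamp, i0, u, ok);
    if (ok) locate(pts(p, 1), spacing, n2, clamp, j0, v, ok);
    if (ok) locate(pts(p, 2), spacing, n3, clamp, k0, w, ok);
    if (!ok) stop("point %d is outside the grid (no extrapolation)", (int)(p + 1));
    double acc = 0.0;
    for (int dk = 0; dk < 2; dk++)
      for (int dj = 0; dj < 2; dj++)
        for (int di = 0; di < 2; di++) {
          double wt = (di ? u : 1 - u) * (dj ? v : 1 - v) * (dk ? w : 1 - w);
          R_xlen_t idx = (R_xlen_t)(i0 + di) +
                         (R_xlen_t)n1 * ((j0 + dj) + (R_xlen_t)n2 * (k0 + dk));
          acc += wt * vol[idx];
        }
    out[p] = acc;
  }
  return out;
}

// Sample a dense 3-component displacement field (4D array, dims x 3) at
// arbitrary mm points; errors on out-of-bounds points.
// [[Rcpp::export]]
NumericMatrix interp_field_cpp(NumericVector field, IntegerVector dims,
                               NumericMatrix pts, double spacing) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t ncomp = (R_xlen_t)n1 * n2 * n3;
  const R_xlen_t npt = pts.nrow();
  NumericMatrix out(npt, 3);
  for (R_xlen_t p = 0; p < npt; p++) {
    int i0, j0, k0; double u, v, w; bool ok = true;
    locate(pts(p, 0), spacing, n1, false, i0, u, ok);
    if (ok) locate(pts(p, 1), spacing, n2, false, j0, v, ok);
    if (ok) locate(pts(p, 2), spacing, n3, false, k0, w, ok);
    if (!ok) stop("point %d is outside the displacement grid", (int)(p + 1));
    double acc[3] = {0.0, 0.0, 0.0};
    for (int dk = 0; dk < 2; dk++)
      for (int dj = 0; dj < 2; dj++)
        for (int di = 0; di < 2; di++) {
          double wt = (di ? u : 1 - u) * (dj ? v : 1 - v) * (dk ? w : 1 - w);
          R_xlen_t idx = (R_xlen_t)(i0 + di) +
                         (R_xlen_t)n1 * ((j0 + dj) + (R_xlen_t)n2 * (k0 + dk));
          acc[0] += wt * field[idx];
          acc[1] += wt * field[idx + ncomp];
          acc[2] += wt * field[idx + 2 * ncomp];
        }
    out(p, 0) = acc[0];
    out(p, 1) = acc[1];
    out(p, 2) = acc[2];
  }
  return out;
}
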