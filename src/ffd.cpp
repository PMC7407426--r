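#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Cubic B-spline free-form deformation. Control node l (0-based) of an axis
// sits at (l-1)*s mm, so every x >= 0 in the image domain has full 4-node
// support; an axis with extent E needs floor(E/s) + 4 nodes.

static inline void bspline_w(double u, double *w) {
  double u2 = u * u, u3 = u2 * u;
  w[0] = (1.0 - 3.0 * u + 3.0 * u2 - u3) / 6.0;
  w[1] = (3.0 * u3 - 6.0 * u2 + 4.0) / 6.0;
  w[2] = (-3.0 * u3 + 3.0 * u2 + 3.0 * u + 1.0) / 6.0;
  w[3] = u3 / 6.0;
}

static inline void locate_ctrl(double x, double s, int nc, int &i0, double *w) {
  double t = x / s;
  int i = (int)std::floor(t);
  if (i < 0) i = 0;
  if (i > nc - 4) i = nc - 4;
  bspline_w(t - i, w);
  i0 = i;
}

// Evaluate the FFD at arbitrary mm points.
// [[Rcpp::export]]
NumericMatrix bspline_sample_cpp(NumericVector phi, IntegerVector nc, double s,
                                 NumericMatrix pts) {
  const int ncx = nc[0], ncy = nc[1], ncz = nc[2];
  const R_xlen_t nctot = (R_xlen_t)ncx * ncy * ncz;
  const R_xlen_t npt = pts.nrow();
  NumericMatrix out(npt, 3);
  for (R_xlen_t p = 0; p < npt; p++) {
    int ix, iy, iz;
    double wx[4], wy[4], wz[4];
    locate_ctrl(pts(p, 0), s, ncx, ix, wx);
    locate_ctrl(pts(p, 1), s, ncy, iy, wy);
    locate_ctrl(pts(p, 2), s, ncz, iz, wz);
    double acc[3] = {0, 0, 0};
    for (int c = 0; c < 3; c++) {
      double a = 0.0;
      for (int mz = 0; mz < 4; mz++)
        for (int my = 0; my < 4; my++) {
          double wyz = wy[my] * wz[mz];
          R_xlen_t base = (R_xlen_t)ix + (R_xlen_t)ncx * ((iy + my) + (R_xlen_t)ncy * (iz + mz)) + c * nctot;
          for (int mx = 0; mx < 4; mx++) a += wx[mx] * wyz * phi[base + mx];
        }
      acc[c] = a;
    }
    out(p, 0) = acc[0];
    out(p, 1) = acc[1];
    out(p, 2) = acc[2];
  }
  return out;
}

// Dense displacement on a voxel-center grid (centers at (i-0.5)*h).
// [[Rcpp::export]]
NumericVector ffd_dense_field_cpp(NumericVector phi, IntegerVector nc, double s,
                                  IntegerVector dims, double spacing) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const int ncx = nc[0], ncy = nc[1], ncz = nc[2];
  const R_xlen_t nctot = (R_xlen_t)ncx * ncy * ncz;
  const R_xlen_t nvox = (R_xlen_t)n1 * n2 * n3;
  NumericVector out(nvox * 3);

  std::vector<int> ix(n1), iy(n2), iz(n3);
  std::vector<double> wx(4 * n1), wy(4 * n2), wz(4 * n3);
  for (int i = 0; i < n1; i++) locate_ctrl((i + 0.5) * spacing, s, ncx, ix[i], &wx[4 * i]);
  for (int j = 0; j < n2; j++) locate_ctrl((j + 0.5) * spacing, s, ncy, iy[j], &wy[4 * j]);
  for (int k = 0; k < n3; k++) locate_ctrl((k + 0.5) * spacing, s, ncz, iz[k], &wz[4 * k]);

  std::vector<double> phi_yz(ncx);
  for (int c = 0; c < 3; c++) {
    const double *ph = &phi[c * nctot];
    double *op = &out[c * nvox];
    for (int k = 0; k < n3; k++)
      for (int j = 0; j < n2; j++) {
        // collapse the y and z sums once per (j,k) row:
        // phi_yz[l] = sum_{my,mz} wy*wz*phi[l, iy+my, iz+mz], so the x loop
        // reduces to a 4-tap filter.
        for (int l = 0; l < ncx; l++) phi_yz[l] = 0.0;
        for (int mz = 0; mz < 4; mz++)
          for (int my = 0; my < 4; my++) {
            double wyz = wy[4 * j + my] * wz[4 * k + mz];
            const double *row = ph + (R_xlen_t)ncx * ((iy[j] + my) + (R_xlen_t)ncy * (iz[k] + mz));
            for (int l = 0; l < ncx; l++) phi_yz[l] += wyz * row[l];
          }
        R_xlen_t base = (R_xlen_t)n1 * (j + (R_xlen_t)n2 * k);
        for (int i = 0; i < n1; i++) {
          const double *w = &wx[4 * i];
          const double *pl = &phi_yz[ix[i]];
          op[base + i] = w[0] * pl[0] + w[1] * pl[1] + w[2] * pl[2] + w[3] * pl[3];
        }
      }
  }
  return out;
}

static inline double clamp_locate(double x, double h, int n, int &i0) {
  double t = x / h - 0.5;
  if (t < 0.0) t = 0.0;
  if (t > n - 1.0) t = n - 1.0;
  int i = (int)std::floor(t);
  if (i > n - 2) i = n - 2;
  i0 = i;
  return t - i;
}

// SSD-on-SDT cost and analytic gradient w.r.t. control displacements, plus a
// bending-energy penalty on the control lattice (second differences).
// pts: band voxel centers (mm) on the fixed grid; fvals: fixed SDT there.
// mov / mg[xyz]: moving SDT and its precomputed central-difference gradient.
// [[Rcpp::export]]
List ffd_cost_grad_cpp(NumericVector phi, IntegerVector nc, double s,
                       NumericMatrix pts, NumericVector fvals,
                       NumericVector mov, NumericVector mgx, NumericVector mgy,
                       NumericVector mgz, IntegerVector mdims, double mspacing,
                       double lambda) {
  const int ncx = nc[0], ncy = nc[1], ncz = nc[2];
  const R_xlen_t nctot = (R_xlen_t)ncx * ncy * ncz;
  const int n1 = mdims[0], n2 = mdims[1], n3 = mdims[2];
  const R_xlen_t npt = pts.nrow();
  NumericVector grad(nctot * 3);
  double cost = 0.0;

  for (R_xlen_t p = 0; p < npt; p++) {
    int ix, iy, iz;
    double wx[4], wy[4], wz[4];
    locate_ctrl(pts(p, 0), s, ncx, ix, wx);
    locate_ctrl(pts(p, 1), s, ncy, iy, wy);
    locate_ctrl(pts(p, 2), s, ncz, iz, wz);
    double u[3] = {0, 0, 0};
    for (int c = 0; c < 3; c++) {
      const double *ph = &phi[c * nctot];
      double a = 0.0;
      for (int mz = 0; mz < 4; mz++)
        for (int my = 0; my < 4; my++) {
          double wyz = wy[my] * wz[mz];
          const double *row = ph + (R_xlen_t)ix + (R_xlen_t)ncx * ((iy + my) + (R_xlen_t)ncy * (iz + mz));
          a += wyz * (wx[0] * row[0] + wx[1] * row[1] + wx[2] * row[2] + wx[3] * row[3]);
        }
      u[c] = a;
    }
    double y0 = pts(p, 0) + u[0], y1 = pts(p, 1) + u[1], y2 = pts(p, 2) + u[2];
    int i0, j0, k0;
    double a0 = clamp_locate(y0, mspacing, n1, i0);
    double a1 = clamp_locate(y1, mspacing, n2, j0);
    double a2 = clamp_locate(y2, mspacing, n3, k0);
    double m = 0, g0 = 0, g1 = 0, g2 = 0;
    for (int dk = 0; dk < 2; dk++)
      for (int dj = 0; dj < 2; dj++)
        for (int di = 0; di < 2; di++) {
          double wt = (di ? a0 : 1 - a0) * (dj ? a1 : 1 - a1) * (dk ? a2 : 1 - a2);
          R_xlen_t idx = (R_xlen_t)(i0 + di) + (R_xlen_t)n1 * ((j0 + dj) + (R_xlen_t)n2 * (k0 + dk));
          m += wt * mov[idx];
          g0 += wt * mgx[idx];
          g1 += wt * mgy[idx];
          g2 += wt * mgz[idx];
        }
    double r = m - fvals[p];
    cost += r * r;
    double f0 = 2.0 * r * g0, f1 = 2.0 * r * g1, f2 = 2.0 * r * g2;
    for (int mz = 0; mz < 4; mz++)
      for (int my = 0; my < 4; my++) {
        double wyz = wy[my] * wz[mz];
        R_xlen_t base = (R_xlen_t)ix + (R_xlen_t)ncx * ((iy + my) + (R_xlen_t)ncy * (iz + mz));
        for (int mx = 0; mx < 4; mx++) {
          double w = wx[mx] * wyz;
          grad[base + mx] += f0 * w;
          grad[base + mx + nctot] += f1 * w;
          grad[base + mx + 2 * nctot] += f2 * w;
        }
      }
  }
  double invn = 1.0 / (double)npt;
  cost *= invn;
  for (R_xlen_t i = 0; i < nctot * 3; i++) grad[i] *= invn;

  // bending energy on the lattice
  if (lambda > 0) {
    double s2 = 1.0 / (s * s);
    double invm = 1.0 / (double)nctot;
    double bend = 0.0;
    const int strd[3] = {1, ncx, ncx * ncy};
    for (int c = 0; c < 3; c++) {
      double *ph = &phi[c * nctot];
      double *gr = &grad[c * nctot];
      for (int k = 1; k < ncz - 1; k++)
        for (int j = 1; j < ncy - 1; j++)
          for (int i = 1; i < ncx - 1; i++) {
            R_xlen_t q = (R_xlen_t)i + (R_xlen_t)ncx * (j + (R_xlen_t)ncy * k);
            // pure second differences
            for (int d = 0; d < 3; d++) {
              double D = (ph[q - strd[d]] - 2.0 * ph[q] + ph[q + strd[d]]) * s2;
              bend += D * D;
              double f = lambda * invm * 2.0 * D * s2;
              gr[q - strd[d]] += f;
              gr[q] += -2.0 * f;
              gr[q + strd[d]] += f;
            }
            // mixed second differences (weight 2)
            for (int d1 = 0; d1 < 3; d1++)
              for (int d2 = d1 + 1; d2 < 3; d2++) {
                double D = (ph[q + strd[d1] + strd[d2]] - ph[q + strd[d1] - strd[d2]] -
                            ph[q - strd[d1] + strd[d2]] + ph[q - strd[d1] - strd[d2]]) *
                           0.25 * s2;
                bend += 2.0 * D * D;
                double f = lambda * invm * 4.0 * D * 0.25 * s2;
                gr[q + strd[d1] + strd[d2]] += f;
                gr[q + strd[d1] - strd[d2]] -= f;
                gr[q - strd[d1] + strd[d2]] -= f;
                gr[q - strd[d1] - strd[d2]] += f;
              }
          }
    }
    cost += lambda * invm * bend;
  }
  return List::create(_["cost"] = cost, _["grad"] = grad);
}

// Exact subdivision of a cubic B-spline lattice when the control spacing is
// halved: aligned nodes get (1,6,1)/8 taps, midpoints (1,1)/2 taps.
// [[Rcpp::export]]
NumericVector bspline_refine_cpp(NumericVector phi, IntegerVector nc,
                                 IntegerVector nc_new) {
  const int ox = nc[0], oy = nc[1], oz = nc[2];
  const int nx = nc_new[0], ny = nc_new[1], nz = nc_new[2];
  const R_xlen_t otot = (R_xlen_t)ox * oy * oz;
  const R_xlen_t ntot = (R_xlen_t)nx * ny * nz;
  NumericVector out(ntot * 3);

  auto taps = [](int m, int on, int idx[3], double w[3]) -> int {
    auto cl = [on](int l) { return l < 0 ? 0 : (l >= on ? on - 1 : l); };
    if (m % 2 == 1) { // aligned with old node l = (m+1)/2
      int l = (m + 1) / 2;
      idx[0] = cl(l - 1); idx[1] = cl(l); idx[2] = cl(l + 1);
      w[0] = 0.125; w[1] = 0.75; w[2] = 0.125;
      return 3;
    } else { // midpoint between old nodes l and l+1, l = m/2
      int l = m / 2;
      idx[0] = cl(l); idx[1] = cl(l + 1);
      w[0] = 0.5; w[1] = 0.5;
      return 2;
    }
  };

  for (int c = 0; c < 3; c++) {
    const double *ph = &phi[c * otot];
    double *op = &out[c * ntot];
    for (int k = 0; k < nz; k++) {
      int kz[3]; double wz[3]; int ntz = taps(k, oz, kz, wz);
      for (int j = 0; j < ny; j++) {
        int jy[3]; double wy[3]; int nty = taps(j, oy, jy, wy);
        for (int i = 0; i < nx; i++) {
          int ixk[3]; double wxk[3]; int ntx = taps(i, ox, ixk, wxk);
          double a = 0.0;
          for (int mz = 0; mz < ntz; mz++)
            for (int my = 0; my < nty; my++)
              for (int mx = 0; mx < ntx; mx++)
                a += wz[mz] * wy[my] * wxk[mx] *
                     ph[(R_xlen_t)ixk[mx] + (R_xlen_t)ox * (jy[my] + (R_xlen_t)oy * kz[mz])];
          op[(R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = a;
        }
      }
    }
  }
  return out;
}
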