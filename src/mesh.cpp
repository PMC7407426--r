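#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Kuhn/Freudenthal decomposition: each voxel cube is split into 6 tetrahedra
// along the main diagonal (0,0,0)-(1,1,1); the same diagonal in every voxel
// makes the decomposition conform across shared faces. Tets are reordered to
// positive orientation (signed volume > 0).

struct TetTemplate { int c[4]; }; // corner offsets encoded as dx + 2*dy + 4*dz

static std::vector<TetTemplate> kuhn_templates() {
  int perms[6][3] = {{0, 1, 2}, {0, 2, 1}, {1, 0, 2}, {1, 2, 0}, {2, 0, 1}, {2, 1, 0}};
  std::vector<TetTemplate> out;
  for (int p = 0; p < 6; p++) {
    int v[4][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}, {1, 1, 1}};
    v[1][perms[p][0]] = 1;
    v[2][perms[p][0]] = 1;
    v[2][perms[p][1]] = 1;
    // signed volume of (v0,v1,v2,v3)
    double a[3][3];
    for (int c = 0; c < 3; c++) {
      a[0][c] = v[1][c] - v[0][c];
      a[1][c] = v[2][c] - v[0][c];
      a[2][c] = v[3][c] - v[0][c];
    }
    double det = a[0][0] * (a[1][1] * a[2][2] - a[1][2] * a[2][1]) -
                 a[0][1] * (a[1][0] * a[2][2] - a[1][2] * a[2][0]) +
                 a[0][2] * (a[1][0] * a[2][1] - a[1][1] * a[2][0]);
    TetTemplate t;
    int order[4] = {0, 1, 2, 3};
    if (det < 0) { order[1] = 2; order[2] = 1; }
    for (int q = 0; q < 4; q++) {
      int *vv = v[order[q]];
      t.c[q] = vv[0] + 2 * vv[1] + 4 * vv[2];
    }
    out.push_back(t);
  }
  return out;
}

// [[Rcpp::export]]
List tetrahedralize_mask_cpp(LogicalVector mask, IntegerVector dims, double spacing) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t c1 = n1 + 1, c2 = n2 + 1, c3 = n3 + 1;
  std::vector<int> nodeid(c1 * c2 * c3, -1);
  std::vector<TetTemplate> tmpl = kuhn_templates();

  // first pass: count voxels, mark corner usage
  R_xlen_t nvox = 0;
  for (int k = 0; k < n3; k++)
    for (int j = 0; j < n2; j++)
      for (int i = 0; i < n1; i++) {
        R_xlen_t vidx = i + (R_xlen_t)n1 * (j + (R_xlen_t)n2 * k);
        if (!mask[vidx]) continue;
        nvox++;
        for (int dz = 0; dz < 2; dz++)
          for (int dy = 0; dy < 2; dy++)
            for (int dx = 0; dx < 2; dx++) {
              R_xlen_t cidx = (i + dx) + c1 * ((j + dy) + c2 * (k + dz));
              nodeid[cidx] = 0;
            }
      }
  if (nvox == 0) stop("mask is empty: cannot build a tetrahedral mesh");

  R_xlen_t nnode = 0;
  for (R_xlen_t c = 0; c < (R_xlen_t)(c1 * c2 * c3); c++)
    if (nodeid[c] == 0) nodeid[c] = (int)(nnode++);

  NumericMatrix nodes(nnode, 3);
  for (int k = 0; k < (int)c3; k++)
    for (int j = 0; j < (int)c2; j++)
      for (int i = 0; i < (int)c1; i++) {
        int id = nodeid[i + c1 * (j + c2 * k)];
        if (id < 0) continue;
        nodes(id, 0) = i * spacing;
        nodes(id, 1) = j * spacing;
        nodes(id, 2) = k * spacing;
      }

  IntegerMatrix tets(6 * nvox, 4);
  IntegerVector owner(6 * nvox);
  R_xlen_t t = 0;
  for (int k = 0; k < n3; k++)
    for (int j = 0; j < n2; j++)
      for (int i = 0; i < n1; i++) {
        R_xlen_t vidx = i + (R_xlen_t)n1 * (j + (R_xlen_t)n2 * k);
        if (!mask[vidx]) continue;
        int corner[8];
        for (int dz = 0; dz < 2; dz++)
          for (int dy = 0; dy < 2; dy++)
            for (int dx = 0; dx < 2; dx++)
              corner[dx + 2 * dy + 4 * dz] =
                  nodeid[(i + dx) + c1 * ((j + dy) + c2 * (k + dz))];
        for (int q = 0; q < 6; q++) {
          for (int w = 0; w < 4; w++) tets(t, w) = corner[tmpl[q].c[w]] + 1; // 1-based
          owner[t] = (int)(vidx + 1);
          t++;
        }
      }

  return List::create(_["nodes"] = nodes, _["tets"] = tets, _["owner"] = owner);
}

static inline double det3(const double a[3][3]) {
  return a[0][0] * (a[1][1] * a[2][2] - a[1][2] * a[2][1]) -
         a[0][1] * (a[1][0] * a[2][2] - a[1][2] * a[2][0]) +
         a[0][2] * (a[1][0] * a[2][1] - a[1][1] * a[2][0]);
}

// Per-tet geometry in the current (EI) and reference (EE) configurations.
// J is computed two ways: as the volume ratio V_cur/V_ref and as det(F) with
// F = E_cur * E_ref^{-1} assembled explicitly (cross-check of the identity).
// [[Rcpp::export]]
List tet_metrics_cpp(NumericMatrix nodes_cur, NumericMatrix nodes_ref,
                     IntegerMatrix tets) {
  const R_xlen_t nt = tets.nrow();
  NumericVector v_cur(nt), v_ref(nt), j_ratio(nt), j_det(nt);
  NumericMatrix centroid(nt, 3);
  for (R_xlen_t t = 0; t < nt; t++) {
    int n0 = tets(t, 0) - 1, n1 = tets(t, 1) - 1, n2 = tets(t, 2) - 1,
        n3 = tets(t, 3) - 1;
    double ec[3][3], er[3][3];
    for (int c = 0; c < 3; c++) {
      ec[c][0] = nodes_cur(n1, c) - nodes_cur(n0, c);
      ec[c][1] = nodes_cur(n2, c) - nodes_cur(n0, c);
      ec[c][2] = nodes_cur(n3, c) - nodes_cur(n0, c);
      er[c][0] = nodes_ref(n1, c) - nodes_ref(n0, c);
      er[c][1] = nodes_ref(n2, c) - nodes_ref(n0, c);
      er[c][2] = nodes_ref(n3, c) - nodes_ref(n0, c);
      centroid(t, c) = 0.25 * (nodes_cur(n0, c) + nodes_cur(n1, c) +
                               nodes_cur(n2, c) + nodes_cur(n3, c));
    }
    double dc = det3(ec), dr = det3(er);
    v_cur[t] = dc / 6.0;
    v_ref[t] = dr / 6.0;
    j_ratio[t] = (dr != 0.0) ? dc / dr : R_PosInf;
    // explicit F = E_cur * E_ref^{-1}
    if (dr != 0.0) {
      double inv[3][3];
      inv[0][0] = (er[1][1] * er[2][2] - er[1][2] * er[2][1]) / dr;
      inv[0][1] = (er[0][2] * er[2][1] - er[0][1] * er[2][2]) / dr;
      inv[0][2] = (er[0][1] * er[1][2] - er[0][2] * er[1][1]) / dr;
      inv[1][0] = (er[1][2] * er[2][0] - er[1][0] * er[2][2]) / dr;
      inv[1][1] = (er[0][0] * er[2][2] - er[0][2] * er[2][0]) / dr;
      inv[1][2] = (er[0][2] * er[1][0] - er[0][0] * er[1][2]) / dr;
      inv[2][0] = (er[1][0] * er[2][1] - er[1][1] * er[2][0]) / dr;
      inv[2][1] = (er[0][1] * er[2][0] - er[0][0] * er[2][1]) / dr;
      inv[2][2] = (er[0][0] * er[1][1] - er[0][1] * er[1][0]) / dr;
      double F[3][3];
      for (int r = 0; r < 3; r++)
        for (int c = 0; c < 3; c++)
          F[r][c] = ec[r][0] * inv[0][c] + ec[r][1] * inv[1][c] + ec[r][2] * inv[2][c];
      j_det[t] = det3(F);
    } else {
      j_det[t] = R_PosInf;
    }
  }
  return List::create(_["v_cur"] = v_cur, _["v_ref"] = v_ref,
                      _["j_ratio"] = j_ratio, _["j_det"] = j_det,
                      _["centroid"] = centroid);
}
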