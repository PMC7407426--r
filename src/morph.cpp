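#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// 3x3x3 majority filter: a voxel becomes TRUE when >= 14 of the 27 voxels in
// its neighbourhood (outside the grid counts as FALSE) are TRUE. Removes
// salt-and-pepper speckle from threshold classification before distance
// transforms are taken.
// [[Rcpp::export]]
LogicalVector majority_filter_cpp(LogicalVector mask, IntegerVector dims, int iterations = 1) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t ntot = (R_xlen_t)n1 * n2 * n3;
  std::vector<char> cur(ntot), nxt(ntot);
  for (R_xlen_t i = 0; i < ntot; i++) cur[i] = mask[i] ? 1 : 0;
  for (int it = 0; it < iterations; it++) {
    for (int k = 0; k < n3; k++)
      for (int j = 0; j < n2; j++)
        for (int i = 0; i < n1; i++) {
          int cnt = 0;
          for (int dk = -1; dk <= 1; dk++)
            for (int dj = -1; dj <= 1; dj++)
              for (int di = -1; di <= 1; di++) {
                int ii = i + di, jj = j + dj, kk = k + dk;
                if (ii < 0 || jj < 0 || kk < 0 || ii >= n1 || jj >= n2 || kk >= n3) continue;
                cnt += cur[ii + (R_xlen_t)n1 * (jj + (R_xlen_t)n2 * kk)];
              }
          nxt[i + (R_xlen_t)n1 * (j + (R_xlen_t)n2 * k)] = cnt >= 14;
        }
    cur.swap(nxt);
  }
  LogicalVector out(ntot);
  for (R_xlen_t i = 0; i < ntot; i++) out[i] = cur[i] != 0;
  return out;
}

// Largest 6-connected component of a binary mask.
// [[Rcpp::export]]
LogicalVector largest_component_cpp(LogicalVector mask, IntegerVector dims) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t ntot = (R_xlen_t)n1 * n2 * n3;
  std::vector<int> label(ntot, 0);
  int nlab = 0;
  R_xlen_t best_size = 0;
  int best_lab = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t start = 0; start < ntot; start++) {
    if (!mask[start] || label[start]) continue;
    nlab++;
    R_xlen_t size = 0;
    stack.clear();
    stack.push_back(start);
    label[start] = nlab;
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      size++;
      int i = (int)(v % n1), j = (int)((v / n1) % n2), k = (int)(v / ((R_xlen_t)n1 * n2));
      const int di[6] = {-1, 1, 0, 0, 0, 0};
      const int dj[6] = {0, 0, -1, 1, 0, 0};
      const int dk[6] = {0, 0, 0, 0, -1, 1};
      for (int d = 0; d < 6; d++) {
        int ii = i + di[d], jj = j + dj[d], kk = k + dk[d];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= n1 || jj >= n2 || kk >= n3) continue;
        R_xlen_t w = ii + (R_xlen_t)n1 * (jj + (R_xlen_t)n2 * kk);
        if (mask[w] && !label[w]) {
          label[w] = nlab;
          stack.push_back(w);
        }
      }
    }
    if (size > best_size) { best_size = size; best_lab = nlab; }
  }
  LogicalVector out(ntot);
  for (R_xlen_t i = 0; i < ntot; i++) out[i] = label[i] == best_lab && best_lab > 0;
  return out;
}
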