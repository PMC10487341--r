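#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Offsets for 6/18/26 neighborhoods: Chebyshev-1 shell filtered by the
// number of nonzero components (1 -> face, <=2 -> face+edge, <=3 -> all).
static void neighbor_offsets(int connectivity, std::vector<int>& dx,
                             std::vector<int>& dy, std::vector<int>& dz) {
  int maxnz = (connectivity == 6) ? 1 : (connectivity == 18 ? 2 : 3);
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        int nzc = (a != 0) + (b != 0) + (c != 0);
        if (nzc == 0 || nzc > maxnz) continue;
        dx.push_back(a); dy.push_back(b); dz.push_back(c);
      }
}

// Connected-component labelling of a 3D logical array.
// Labels are assigned in column-major scan order (x fastest), so
// component 1 contains the scan-order-first foreground voxel.
// [[Rcpp::export(name = ".cc_label")]]
IntegerVector cc_label(LogicalVector mask, IntegerVector dim,
                       int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<int> dx, dy, dz;
  neighbor_offsets(connectivity, dx, dy, dz);
  const int nn = (int)dx.size();
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int k = (int)(v / ((R_xlen_t)nx * ny));
      int rem = (int)(v % ((R_xlen_t)nx * ny));
      int j = rem / nx;
      int i = rem % nx;
      for (int t = 0; t < nn; ++t) {
        int ii = i + dx[t], jj = j + dy[t], kk = k + dz[t];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
          continue;
        R_xlen_t w = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
        if (mask[w] && !lab[w]) {
          lab[w] = next;
          stack.push_back(w);
        }
      }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}
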