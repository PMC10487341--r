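#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Topology-preserving 3D thinning for (26,6) digital topology, in the
// classic parallel-directional style: each pass visits the six border
// directions in turn, collects border voxels that are deletable, and
// deletes them sequentially with a re-check (so topology is preserved
// exactly). A voxel is *simple* (deletable) iff
//  (A) its foreground 26-neighbors form exactly one 26-connected
//      component, and
//  (B) the background voxels of its 18-neighborhood contain exactly one
//      6-connected component touching a face neighbor of the voxel
// (Malandain & Bertrand characterization). Line ends (voxels with a
// single foreground neighbor) are never deleted, so the result is a
// centered curve skeleton; medial sheets of flattened objects collapse
// to curves because erosion proceeds symmetrically from opposite faces.

// 3x3x3 neighborhood cells indexed (a+1) + 3*(b+1) + 9*(c+1), center 13.
static int adj26[27][27]; static int n26[27];
static int adj6in18[27][27]; static int n6[27];
static bool in18[27]; static bool isface[27];
static bool tables_ready = false;

static void build_tables() {
  if (tables_ready) return;
  for (int p = 0; p < 27; ++p) {
    int pa = p % 3 - 1, pb = (p / 3) % 3 - 1, pc = p / 9 - 1;
    int nzp = (pa != 0) + (pb != 0) + (pc != 0);
    in18[p] = (p != 13) && nzp <= 2;
    isface[p] = nzp == 1;
    n26[p] = 0; n6[p] = 0;
    for (int q = 0; q < 27; ++q) {
      if (q == p || q == 13 || p == 13) continue;
      int qa = q % 3 - 1, qb = (q / 3) % 3 - 1, qc = q / 9 - 1;
      int da = std::abs(pa - qa), db = std::abs(pb - qb),
          dc = std::abs(pc - qc);
      if (da <= 1 && db <= 1 && dc <= 1)
        adj26[p][n26[p]++] = q;
      if (da + db + dc == 1)
        adj6in18[p][n6[p]++] = q;
    }
  }
  tables_ready = true;
}

static int fg_count(const bool* nb) {
  int c = 0;
  for (int p = 0; p < 27; ++p)
    if (p != 13 && nb[p]) ++c;
  return c;
}

static int fg_components(const bool* nb) {
  bool vis[27] = {false};
  int stack[27], top;
  int ncomp = 0;
  for (int s = 0; s < 27; ++s) {
    if (s == 13 || !nb[s] || vis[s]) continue;
    ++ncomp;
    top = 0;
    stack[top++] = s; vis[s] = true;
    while (top) {
      int p = stack[--top];
      for (int t = 0; t < n26[p]; ++t) {
        int q = adj26[p][t];
        if (nb[q] && !vis[q]) { vis[q] = true; stack[top++] = q; }
      }
    }
  }
  return ncomp;
}

static bool background_ok(const bool* nb) {
  bool bvis[27] = {false};
  int stack[27], top;
  int ncomp = 0;
  for (int s = 0; s < 27; ++s) {
    if (!in18[s] || nb[s] || bvis[s] || !isface[s]) continue;
    ++ncomp;
    if (ncomp > 1) return false;
    top = 0;
    stack[top++] = s; bvis[s] = true;
    while (top) {
      int p = stack[--top];
      for (int t = 0; t < n6[p]; ++t) {
        int q = adj6in18[p][t];
        if (in18[q] && !nb[q] && !bvis[q]) { bvis[q] = true; stack[top++] = q; }
      }
    }
  }
  return ncomp == 1;
}

// [[Rcpp::export(name = ".thin_parallel")]]
LogicalVector thin_parallel(LogicalVector mask, IntegerVector dim) {
  build_tables();
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<char> fg(n);
  for (R_xlen_t i = 0; i < n; ++i) fg[i] = mask[i] ? 1 : 0;

  auto at = [&](int i, int j, int k) -> bool {
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz)
      return false;
    return fg[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] != 0;
  };
  auto gather = [&](int i, int j, int k, bool* nb) {
    for (int c = -1; c <= 1; ++c)
      for (int b = -1; b <= 1; ++b)
        for (int a = -1; a <= 1; ++a)
          nb[(a + 1) + 3 * (b + 1) + 9 * (c + 1)] = at(i + a, j + b, k + c);
  };
  auto deletable = [&](int i, int j, int k) -> bool {
    bool nb[27];
    gather(i, j, k, nb);
    int cnt = fg_count(nb);
    if (cnt <= 1) return false;          // line end or isolated: keep
    if (fg_components(nb) != 1) return false;
    return background_ok(nb);
  };

  // six border directions: -x, +x, -y, +y, -z, +z (skip the z pair on
  // single-slice inputs so 2D shapes erode symmetrically in-plane)
  const int DX[6] = {-1, 1, 0, 0, 0, 0};
  const int DY[6] = {0, 0, -1, 1, 0, 0};
  const int DZ[6] = {0, 0, 0, 0, -1, 1};
  const int ndir = (nz == 1) ? 4 : 6;

  std::vector<R_xlen_t> cand;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < ndir; ++d) {
      cand.clear();
      for (int k = 0; k < nz; ++k)
        for (int j = 0; j < ny; ++j)
          for (int i = 0; i < nx; ++i) {
            R_xlen_t v = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
            if (!fg[v]) continue;
            if (at(i + DX[d], j + DY[d], k + DZ[d])) continue;  // not a border in d
            if (deletable(i, j, k)) cand.push_back(v);
          }
      for (size_t t = 0; t < cand.size(); ++t) {
        R_xlen_t v = cand[t];
        int k = (int)(v / ((R_xlen_t)nx * ny));
        int rem = (int)(v % ((R_xlen_t)nx * ny));
        int j = rem / nx;
        int i = rem % nx;
        if (deletable(i, j, k)) {        // re-check: neighbors may be gone
          fg[v] = 0;
          changed = true;
        }
      }
    }
  }

  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = fg[i] != 0;
  return out;
}
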