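#include <Rcpp.h>
#include <vector>
#include <cstring>
using namespace Rcpp;

// 3x3x3 neighborhood positions indexed p = (dz+1)*9 + (dy+1)*3 + (dx+1),
// center p = 13. Topological numbers after Bertrand & Malandain: the number
// of connected components of X restricted to the geodesic neighborhood
// (N18 for 6-connectivity, N26 for 18/26) that are adjacent to the center.

namespace {

struct TopoTables {
  // adjacency between the 27 positions, per connectivity
  int adj[3][27][27]; // [c][p][k] neighbor list, -1 terminated; c: 0=6,1=18,2=26
  bool domain[3][27]; // admissible positions for each connectivity
  bool cadj[3][27];   // position adjacent to the center under that connectivity
  TopoTables() {
    int dx[27], dy[27], dz[27];
    for (int p = 0; p < 27; p++) {
      dx[p] = p % 3 - 1; dy[p] = (p / 3) % 3 - 1; dz[p] = p / 9 - 1;
    }
    auto cheb = [&](int p, int q) {
      int a = std::abs(dx[p] - dx[q]), b = std::abs(dy[p] - dy[q]),
          c = std::abs(dz[p] - dz[q]);
      return std::max(a, std::max(b, c));
    };
    auto city = [&](int p, int q) {
      return std::abs(dx[p] - dx[q]) + std::abs(dy[p] - dy[q]) +
             std::abs(dz[p] - dz[q]);
    };
    for (int c = 0; c < 3; c++)
      for (int p = 0; p < 27; p++) {
        int city0 = std::abs(dx[p]) + std::abs(dy[p]) + std::abs(dz[p]);
        bool inN18 = p != 13 && city0 <= 2;
        bool inN26 = p != 13;
        domain[c][p] = (c == 0) ? inN18 : inN26;
        if (c == 0) cadj[c][p] = (city0 == 1);
        else if (c == 1) cadj[c][p] = inN18;
        else cadj[c][p] = inN26;
        int k = 0;
        for (int q = 0; q < 27; q++) {
          if (q == p || q == 13) continue;
          bool a;
          if (c == 0) a = (city(p, q) == 1);
          else if (c == 1) a = (cheb(p, q) == 1 && city(p, q) <= 2);
          else a = (cheb(p, q) == 1);
          if (a) adj[c][p][k++] = q;
        }
        adj[c][p][k] = -1;
      }
  }
};

const TopoTables TT;

inline int conn_index(int conn) {
  if (conn == 6) return 0;
  if (conn == 18) return 1;
  if (conn == 26) return 2;
  stop("connectivity must be 6, 18 or 26");
  return -1;
}

// topological number of the set given by occ[27] (center ignored)
int topo_number(const bool *occ, int conn) {
  int c = conn_index(conn);
  bool seen[27] = {false};
  int ncomp = 0;
  int stack[27];
  for (int p = 0; p < 27; p++) {
    if (!TT.domain[c][p] || !occ[p] || seen[p]) continue;
    // flood this component, note center adjacency
    bool touches = false;
    int top = 0;
    stack[top++] = p; seen[p] = true;
    while (top > 0) {
      int q = stack[--top];
      if (TT.cadj[c][q]) touches = true;
      for (int k = 0; TT.adj[c][q][k] >= 0; k++) {
        int r = TT.adj[c][q][k];
        if (TT.domain[c][r] && occ[r] && !seen[r]) {
          seen[r] = true; stack[top++] = r;
        }
      }
    }
    if (touches) ncomp++;
  }
  return ncomp;
}

inline bool simple_from_occ(const bool *fg, int fg_conn, int bg_conn) {
  bool bg[27];
  for (int p = 0; p < 27; p++) bg[p] = !fg[p];
  return topo_number(fg, fg_conn) == 1 && topo_number(bg, bg_conn) == 1;
}

// gather the 27-neighborhood of voxel (x,y,z) for predicate labels==lab;
// out-of-volume treated as background
void gather(const int *labels, int nx, int ny, int nz, int x, int y, int z,
            int lab, bool *occ) {
  int p = 0;
  for (int dz = -1; dz <= 1; dz++)
    for (int dy = -1; dy <= 1; dy++)
      for (int dx = -1; dx <= 1; dx++, p++) {
        int xx = x + dx, yy = y + dy, zz = z + dz;
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
          occ[p] = false;
        else
          occ[p] = labels[(R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx] == lab;
      }
}

} // namespace

// [[Rcpp::export]]
LogicalVector cpp_is_simple_batch(IntegerMatrix nbhd, int fg_conn, int bg_conn) {
  int n = nbhd.nrow();
  if (nbhd.ncol() != 27) stop("neighborhood matrix must have 27 columns");
  LogicalVector out(n);
  bool occ[27];
  for (int i = 0; i < n; i++) {
    for (int p = 0; p < 27; p++) occ[p] = nbhd(i, p) != 0;
    out[i] = simple_from_occ(occ, fg_conn, bg_conn);
  }
  return out;
}

// Sequentially attempt label flips cand[i] -> to[i] on a label volume,
// accepting a flip only when the voxel is a simple point for every region
// whose membership changes. In binary mode the single classical test
// (foreground under fg_conn, background under bg_conn) is applied with
// foreground = (labels == 1). In multi-label mode both the losing and the
// gaining region must remain topologically unchanged (each region checked as
// foreground under fg_conn against its complement under bg_conn).
// `labels` is modified in place; callers must pass a copy they own.
// [[Rcpp::export]]
LogicalVector cpp_topo_flips(IntegerVector labels, IntegerVector dim,
                             IntegerVector cand, IntegerVector to,
                             int fg_conn, int bg_conn, bool binary) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n = cand.size();
  LogicalVector acc(n);
  int *lab = INTEGER(labels);
  bool occ[27];
  for (int i = 0; i < n; i++) {
    R_xlen_t idx = cand[i];
    int x = idx % nx, y = (idx / nx) % ny, z = idx / ((R_xlen_t)nx * ny);
    int from = lab[idx], tol = to[i];
    if (from == tol) { acc[i] = true; continue; }
    bool ok;
    if (binary) {
      gather(lab, nx, ny, nz, x, y, z, 1, occ);
      ok = simple_from_occ(occ, fg_conn, bg_conn);
    } else {
      gather(lab, nx, ny, nz, x, y, z, from, occ);
      ok = simple_from_occ(occ, fg_conn, bg_conn);
      if (ok) {
        gather(lab, nx, ny, nz, x, y, z, tol, occ);
        ok = simple_from_occ(occ, fg_conn, bg_conn);
      }
    }
    if (ok) lab[idx] = tol;
    acc[i] = ok;
  }
  return acc;
}

// Connected-component labeling of a binary volume (0 background), BFS.
// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector mask, IntegerVector dim,
                                   int connectivity) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  IntegerVector out(nvox, 0);
  const int *m = INTEGER(mask);
  int *lab = INTEGER(out);
  // neighbor offsets
  std::vector<int> ox, oy, oz;
  for (int dz = -1; dz <= 1; dz++)
    for (int dy = -1; dy <= 1; dy++)
      for (int dx = -1; dx <= 1; dx++) {
        int city = std::abs(dx) + std::abs(dy) + std::abs(dz);
        int cheb = std::max(std::abs(dx), std::max(std::abs(dy), std::abs(dz)));
        if (city == 0) continue;
        bool keep = (connectivity == 6)    ? city == 1
                    : (connectivity == 18) ? (cheb == 1 && city <= 2)
                                           : cheb == 1;
        if (keep) { ox.push_back(dx); oy.push_back(dy); oz.push_back(dz); }
      }
  int noff = ox.size();
  std::vector<R_xlen_t> queue;
  queue.reserve(1024);
  int cur = 0;
  for (R_xlen_t s = 0; s < nvox; s++) {
    if (!m[s] || lab[s]) continue;
    cur++;
    queue.clear();
    queue.push_back(s);
    lab[s] = cur;
    size_t head = 0;
    while (head < queue.size()) {
      R_xlen_t q = queue[head++];
      int x = q % nx, y = (q / nx) % ny, z = q / ((R_xlen_t)nx * ny);
      for (int k = 0; k < noff; k++) {
        int xx = x + ox[k], yy = y + oy[k], zz = z + oz[k];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
          continue;
        R_xlen_t r = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
        if (m[r] && !lab[r]) { lab[r] = cur; queue.push_back(r); }
      }
    }
  }
  return out;
}
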