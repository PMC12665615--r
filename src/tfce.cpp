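#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

// Neighborhood stencil on a 3-D grid; connectivity 6, 18 or 26.
struct Grid {
  int nx, ny, nz;
  std::vector<int> off, dx, dy, dz;
  Grid(const IntegerVector& dims, int connectivity) {
    nx = dims[0]; ny = dims[1]; nz = dims[2];
    for (int c = -1; c <= 1; ++c)
      for (int b = -1; b <= 1; ++b)
        for (int a = -1; a <= 1; ++a) {
          int m = std::abs(a) + std::abs(b) + std::abs(c);
          if (m == 0) continue;
          if (connectivity == 6 && m > 1) continue;
          if (connectivity == 18 && m > 2) continue;
          dx.push_back(a); dy.push_back(b); dz.push_back(c);
          off.push_back(a + nx * (b + ny * c));
        }
  }
};

inline int find_root(std::vector<int>& parent, int v) {
  int r = v;
  while (parent[r] != r) r = parent[r];
  while (parent[v] != r) { int nxt = parent[v]; parent[v] = r; v = nxt; }
  return r;
}

} // namespace

// Connected-component labeling of a binary volume (components 1..K, background 0).
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims, int connectivity) {
  Grid g(dims, connectivity);
  const int V = g.nx * g.ny * g.nz;
  IntegerVector lab(V);
  std::vector<int> stack;
  int cur = 0;
  for (int v0 = 0; v0 < V; ++v0) {
    if (mask[v0] != TRUE || lab[v0]) continue;
    lab[v0] = ++cur;
    stack.push_back(v0);
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      int x = v % g.nx, y = (v / g.nx) % g.ny, z = v / (g.nx * g.ny);
      for (size_t k = 0; k < g.off.size(); ++k) {
        int xx = x + g.dx[k], yy = y + g.dy[k], zz = z + g.dz[k];
        if (xx < 0 || xx >= g.nx || yy < 0 || yy >= g.ny || zz < 0 || zz >= g.nz) continue;
        int w = v + g.off[k];
        if (mask[w] == TRUE && !lab[w]) { lab[w] = cur; stack.push_back(w); }
      }
    }
  }
  return lab;
}

// Threshold-free cluster enhancement of the positive part of a statistic volume:
// TFCE(v) = sum_h e_h(v)^E * h^H * dh over h = dh, 2*dh, ..., where e_h(v) is the
// extent of the connected component containing v among voxels with stat >= h.
// Thresholds are processed in descending order with an incremental union-find, so
// component structure is built once.
// [[Rcpp::export]]
NumericVector tfce_cpp(NumericVector stat, IntegerVector dims, double E, double H,
                       double dh, int connectivity) {
  Grid g(dims, connectivity);
  const int V = g.nx * g.ny * g.nz;
  NumericVector out(V);
  if (dh <= 0) stop("dh must be positive");
  std::vector<int> pos;
  double mx = 0.0;
  for (int v = 0; v < V; ++v) {
    double s = stat[v];
    if (ISNAN(s)) continue;
    if (s > 0) { pos.push_back(v); if (s > mx) mx = s; }
  }
  if (pos.empty()) return out;
  std::sort(pos.begin(), pos.end(),
            [&](int a, int b) { return stat[a] > stat[b]; });
  const int nsteps = (int) std::floor(mx / dh + 1e-7);
  if (nsteps < 1) return out;
  std::vector<int> parent(V, -1), csize(V, 0);
  const double tol = dh * 1e-6; // guard against h = k*dh landing a hair above a voxel value
  size_t ptr = 0;
  for (int t = nsteps; t >= 1; --t) {
    const double h = t * dh;
    while (ptr < pos.size() && stat[pos[ptr]] >= h - tol) {
      int v = pos[ptr++];
      parent[v] = v; csize[v] = 1;
      int x = v % g.nx, y = (v / g.nx) % g.ny, z = v / (g.nx * g.ny);
      for (size_t k = 0; k < g.off.size(); ++k) {
        int xx = x + g.dx[k], yy = y + g.dy[k], zz = z + g.dz[k];
        if (xx < 0 || xx >= g.nx || yy < 0 || yy >= g.ny || zz < 0 || zz >= g.nz) continue;
        int w = v + g.off[k];
        if (parent[w] >= 0) {
          int rv = find_root(parent, v), rw = find_root(parent, w);
          if (rv != rw) {
            if (csize[rv] < csize[rw]) std::swap(rv, rw);
            parent[rw] = rv;
            csize[rv] += csize[rw];
          }
        }
      }
    }
    const double hh = std::pow(h, H) * dh;
    for (size_t i = 0; i < ptr; ++i) {
      int v = pos[i];
      out[v] += std::pow((double) csize[find_root(parent, v)], E) * hh;
    }
  }
  return out;
}
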