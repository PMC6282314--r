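// Voxel-grid utilities: 3D hole filling, connected-component labelling, and
// the alpha-filtration component sweep used by alpha curves.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
LogicalVector cpp_fill_holes_3d(LogicalVector grid, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t N = (size_t)nx * ny * nz;
  std::vector<char> reach(N, 0);
  std::vector<int> stack;
  stack.reserve(N / 8 + 64);

  // seed from every background voxel on the grid boundary; singleton axes
  // (a 2D slice passed as an nz = 1 grid) contribute no boundary faces, so
  // the fill then behaves as the 2D edge flood fill
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        bool bx = nx > 1 && (x == 0 || x == nx - 1);
        bool by = ny > 1 && (y == 0 || y == ny - 1);
        bool bz = nz > 1 && (z == 0 || z == nz - 1);
        if (!bx && !by && !bz) continue;
        size_t i = (size_t)x + (size_t)nx * (y + (size_t)ny * z);
        if (!grid[i] && !reach[i]) { reach[i] = 1; stack.push_back((int)i); }
      }

  while (!stack.empty()) {
    int i = stack.back(); stack.pop_back();
    int x = i % nx, rem = i / nx;
    int y = rem % ny, z = rem / ny;
    const int dx[6] = {-1, 1, 0, 0, 0, 0};
    const int dy[6] = {0, 0, -1, 1, 0, 0};
    const int dz[6] = {0, 0, 0, 0, -1, 1};
    for (int k = 0; k < 6; ++k) {
      int x2 = x + dx[k], y2 = y + dy[k], z2 = z + dz[k];
      if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz) continue;
      size_t j = (size_t)x2 + (size_t)nx * (y2 + (size_t)ny * z2);
      if (!grid[j] && !reach[j]) { reach[j] = 1; stack.push_back((int)j); }
    }
  }

  LogicalVector out(N);
  for (size_t i = 0; i < N; ++i) out[i] = grid[i] || !reach[i];
  out.attr("dim") = dims;
  return out;
}

// [[Rcpp::export]]
List cpp_label_components_3d(LogicalVector grid, IntegerVector dims,
                             int connectivity = 26) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t N = (size_t)nx * ny * nz;
  std::vector<int> lab(N, 0);
  std::vector<int> stack;
  int ncomp = 0;

  std::vector<int> off;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        off.push_back(dx); off.push_back(dy); off.push_back(dz);
      }

  for (size_t s = 0; s < N; ++s) {
    if (!grid[s] || lab[s]) continue;
    ++ncomp;
    lab[s] = ncomp;
    stack.clear(); stack.push_back((int)s);
    while (!stack.empty()) {
      int i = stack.back(); stack.pop_back();
      int x = i % nx, rem = i / nx;
      int y = rem % ny, z = rem / ny;
      for (size_t k = 0; k < off.size(); k += 3) {
        int x2 = x + off[k], y2 = y + off[k + 1], z2 = z + off[k + 2];
        if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz) continue;
        size_t j = (size_t)x2 + (size_t)nx * (y2 + (size_t)ny * z2);
        if (grid[j] && !lab[j]) { lab[j] = ncomp; stack.push_back((int)j); }
      }
    }
  }

  IntegerVector labels(lab.begin(), lab.end());
  labels.attr("dim") = dims;
  return List::create(Named("labels") = labels, Named("n_components") = ncomp);
}

namespace {
struct UF {
  std::vector<int> parent, rank_;
  void init(int n) {
    parent.resize(n); rank_.assign(n, 0);
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  }
  bool unite(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return false;
    if (rank_[a] < rank_[b]) std::swap(a, b);
    parent[b] = a;
    if (rank_[a] == rank_[b]) ++rank_[a];
    return true;
  }
};
} // namespace

// Connected components of the kept-tetrahedra complex at each query alpha
// (ascending), where a tet is kept when circumradius <= alpha and two kept
// tets are adjacent when they share a face.  Incremental union-find sweep.
// [[Rcpp::export]]
IntegerVector cpp_filtration_components(NumericVector tet_radius,
                                        IntegerMatrix face_tets,
                                        NumericVector alphas) {
  int T = tet_radius.size();
  int F = face_tets.nrow();
  int A = alphas.size();

  // infinite radii (flat tets) sort last and activate only at alpha = Inf,
  // so the same sweep serves finite alphas and the convex-hull limit
  std::vector<int> tetOrder(T);
  for (int i = 0; i < T; ++i) tetOrder[i] = i;
  std::sort(tetOrder.begin(), tetOrder.end(),
            [&](int a, int b) { return tet_radius[a] < tet_radius[b]; });

  std::vector<std::pair<double, std::pair<int, int> > > edges;
  edges.reserve(F);
  for (int f = 0; f < F; ++f) {
    int t1 = face_tets(f, 0), t2 = face_tets(f, 1);
    if (t1 <= 0 || t2 <= 0) continue;
    double r1 = tet_radius[t1 - 1], r2 = tet_radius[t2 - 1];
    edges.push_back(std::make_pair(std::max(r1, r2),
                                   std::make_pair(t1 - 1, t2 - 1)));
  }
  std::sort(edges.begin(), edges.end(),
            [](const std::pair<double, std::pair<int, int> > &a,
               const std::pair<double, std::pair<int, int> > &b) {
              return a.first < b.first;
            });

  UF uf; uf.init(T);
  IntegerVector out(A);
  size_t ti = 0, ei = 0;
  int comps = 0;
  for (int a = 0; a < A; ++a) {
    double al = alphas[a];
    while (ti < tetOrder.size() && tet_radius[tetOrder[ti]] <= al) { ++comps; ++ti; }
    while (ei < edges.size() && edges[ei].first <= al) {
      if (uf.unite(edges[ei].second.first, edges[ei].second.second)) --comps;
      ++ei;
    }
    out[a] = comps;
  }
  return out;
}
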