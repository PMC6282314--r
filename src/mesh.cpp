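// Isosurface extraction and mesh processing for the dissection index:
// marching tetrahedra over the binary grid (Kuhn 6-tet cube decomposition,
// watertight by construction), Taubin smoothing, and quadric-error-metric
// edge-collapse decimation to a target face count.

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <unordered_map>
#include <algorithm>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

inline void cross3(const double *a, const double *b, double *c) {
  c[0] = a[1] * b[2] - a[2] * b[1];
  c[1] = a[2] * b[0] - a[0] * b[2];
  c[2] = a[0] * b[1] - a[1] * b[0];
}

} // namespace

// [[Rcpp::export]]
List cpp_marching_tets(LogicalVector grid, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  auto val = [&](int x, int y, int z) -> int {
    if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) return 0;
    return grid[(size_t)x + (size_t)nx * (y + (size_t)ny * z)] ? 1 : 0;
  };
  auto vid = [&](int x, int y, int z) -> int64_t {
    return (int64_t)(x + 1) +
           (int64_t)(nx + 2) * ((int64_t)(y + 1) + (int64_t)(ny + 2) * (z + 1));
  };

  std::unordered_map<uint64_t, int> vmap;
  std::vector<double> VX, VY, VZ;
  std::vector<int> tri;

  // vertex on the edge between two voxel centres (midpoint: binary data)
  auto edgeVertex = [&](int x1, int y1, int z1, int x2, int y2, int z2) -> int {
    int64_t a = vid(x1, y1, z1), b = vid(x2, y2, z2);
    if (a > b) std::swap(a, b);
    uint64_t key = (uint64_t)a * 2000000011ull + (uint64_t)b;
    std::unordered_map<uint64_t, int>::iterator it = vmap.find(key);
    if (it != vmap.end()) return it->second;
    int id = (int)VX.size();
    VX.push_back(0.5 * (x1 + x2));
    VY.push_back(0.5 * (y1 + y2));
    VZ.push_back(0.5 * (z1 + z2));
    vmap[key] = id;
    return id;
  };

  // Kuhn decomposition: six tets, all sharing the main diagonal c000-c111
  const int perms[6][3] = {{0, 1, 2}, {0, 2, 1}, {1, 0, 2},
                           {1, 2, 0}, {2, 0, 1}, {2, 1, 0}};
  int corner[4][3];

  auto emit = [&](int e0a[3], int e0b[3], int e1a[3], int e1b[3],
                  int e2a[3], int e2b[3], const double *ref, bool away) {
    int i0 = edgeVertex(e0a[0], e0a[1], e0a[2], e0b[0], e0b[1], e0b[2]);
    int i1 = edgeVertex(e1a[0], e1a[1], e1a[2], e1b[0], e1b[1], e1b[2]);
    int i2 = edgeVertex(e2a[0], e2a[1], e2a[2], e2b[0], e2b[1], e2b[2]);
    if (i0 == i1 || i1 == i2 || i0 == i2) return;
    double u[3] = {VX[i1] - VX[i0], VY[i1] - VY[i0], VZ[i1] - VZ[i0]};
    double v[3] = {VX[i2] - VX[i0], VY[i2] - VY[i0], VZ[i2] - VZ[i0]};
    double nrm[3];
    cross3(u, v, nrm);
    double w[3] = {ref[0] - VX[i0], ref[1] - VY[i0], ref[2] - VZ[i0]};
    double d = nrm[0] * w[0] + nrm[1] * w[1] + nrm[2] * w[2];
    bool flip = away ? (d > 0) : (d < 0);   // away: normal points away from ref
    if (flip) std::swap(i1, i2);
    tri.push_back(i0); tri.push_back(i1); tri.push_back(i2);
  };

  for (int z = -1; z < nz; ++z)
    for (int y = -1; y < ny; ++y)
      for (int x = -1; x < nx; ++x) {
        // quick skip: uniform cube
        int sum = 0;
        for (int c = 0; c < 8; ++c)
          sum += val(x + (c & 1), y + ((c >> 1) & 1), z + ((c >> 2) & 1));
        if (sum == 0 || sum == 8) continue;

        for (int pq = 0; pq < 6; ++pq) {
          int code[4] = {0, 0, 0, 0};
          code[1] = 1 << perms[pq][0];
          code[2] = code[1] | (1 << perms[pq][1]);
          code[3] = 7;
          int inside[4], nIn = 0;
          for (int i = 0; i < 4; ++i) {
            corner[i][0] = x + (code[i] & 1);
            corner[i][1] = y + ((code[i] >> 1) & 1);
            corner[i][2] = z + ((code[i] >> 2) & 1);
            inside[i] = val(corner[i][0], corner[i][1], corner[i][2]);
            nIn += inside[i];
          }
          if (nIn == 0 || nIn == 4) continue;

          if (nIn == 1 || nIn == 3) {
            int apex = -1;
            for (int i = 0; i < 4; ++i)
              if ((nIn == 1 && inside[i]) || (nIn == 3 && !inside[i])) apex = i;
            int oth[3], no = 0;
            for (int i = 0; i < 4; ++i) if (i != apex) oth[no++] = i;
            double ref[3] = {(double)corner[apex][0], (double)corner[apex][1],
                             (double)corner[apex][2]};
            // nIn==1: apex inside, normal away from apex;
            // nIn==3: apex outside, normal towards apex
            emit(corner[apex], corner[oth[0]], corner[apex], corner[oth[1]],
                 corner[apex], corner[oth[2]], ref, nIn == 1);
          } else {
            int in2[2], out2[2], ni = 0, no = 0;
            for (int i = 0; i < 4; ++i)
              if (inside[i]) in2[ni++] = i; else out2[no++] = i;
            int A = in2[0], B = in2[1], C = out2[0], D = out2[1];
            int iAC = edgeVertex(corner[A][0], corner[A][1], corner[A][2],
                                 corner[C][0], corner[C][1], corner[C][2]);
            int iAD = edgeVertex(corner[A][0], corner[A][1], corner[A][2],
                                 corner[D][0], corner[D][1], corner[D][2]);
            int iBD = edgeVertex(corner[B][0], corner[B][1], corner[B][2],
                                 corner[D][0], corner[D][1], corner[D][2]);
            int iBC = edgeVertex(corner[B][0], corner[B][1], corner[B][2],
                                 corner[C][0], corner[C][1], corner[C][2]);
            double ref[3] = {0.5 * (corner[A][0] + corner[B][0]),
                             0.5 * (corner[A][1] + corner[B][1]),
                             0.5 * (corner[A][2] + corner[B][2])};
            int quad[4] = {iAC, iAD, iBD, iBC};
            int tris[2][3] = {{quad[0], quad[1], quad[2]}, {quad[0], quad[2], quad[3]}};
            for (int tt = 0; tt < 2; ++tt) {
              int i0 = tris[tt][0], i1 = tris[tt][1], i2 = tris[tt][2];
              if (i0 == i1 || i1 == i2 || i0 == i2) continue;
              double u[3] = {VX[i1] - VX[i0], VY[i1] - VY[i0], VZ[i1] - VZ[i0]};
              double v[3] = {VX[i2] - VX[i0], VY[i2] - VY[i0], VZ[i2] - VZ[i0]};
              double nrm[3];
              cross3(u, v, nrm);
              double w[3] = {ref[0] - VX[i0], ref[1] - VY[i0], ref[2] - VZ[i0]};
              double d = nrm[0] * w[0] + nrm[1] * w[1] + nrm[2] * w[2];
              if (d > 0) std::swap(i1, i2);   // normal away from the inside pair
              tri.push_back(i0); tri.push_back(i1); tri.push_back(i2);
            }
          }
        }
      }

  int nv = (int)VX.size(), nf = (int)tri.size() / 3;
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; ++i) { V(i, 0) = VX[i]; V(i, 1) = VY[i]; V(i, 2) = VZ[i]; }
  IntegerMatrix Fm(nf, 3);
  for (int i = 0; i < nf; ++i) {
    Fm(i, 0) = tri[3 * i] + 1; Fm(i, 1) = tri[3 * i + 1] + 1; Fm(i, 2) = tri[3 * i + 2] + 1;
  }
  return List::create(Named("vertices") = V, Named("faces") = Fm);
}

// [[Rcpp::export]]
NumericMatrix cpp_taubin_smooth(NumericMatrix V, IntegerMatrix F,
                                int iterations, double lambda, double mu) {
  int nv = V.nrow(), nf = F.nrow();
  std::vector<std::vector<int> > adj(nv);
  for (int f = 0; f < nf; ++f) {
    int a = F(f, 0) - 1, b = F(f, 1) - 1, c = F(f, 2) - 1;
    adj[a].push_back(b); adj[a].push_back(c);
    adj[b].push_back(a); adj[b].push_back(c);
    adj[c].push_back(a); adj[c].push_back(b);
  }
  for (int i = 0; i < nv; ++i) {
    std::sort(adj[i].begin(), adj[i].end());
    adj[i].erase(std::unique(adj[i].begin(), adj[i].end()), adj[i].end());
  }
  std::vector<double> x(nv), y(nv), z(nv), x2(nv), y2(nv), z2(nv);
  for (int i = 0; i < nv; ++i) { x[i] = V(i, 0); y[i] = V(i, 1); z[i] = V(i, 2); }
  for (int it = 0; it < iterations; ++it) {
    for (int pass = 0; pass < 2; ++pass) {
      double fct = pass == 0 ? lambda : mu;
      for (int i = 0; i < nv; ++i) {
        if (adj[i].empty()) { x2[i] = x[i]; y2[i] = y[i]; z2[i] = z[i]; continue; }
        double mx = 0, my = 0, mz = 0;
        for (size_t k = 0; k < adj[i].size(); ++k) {
          mx += x[adj[i][k]]; my += y[adj[i][k]]; mz += z[adj[i][k]];
        }
        double inv = 1.0 / adj[i].size();
        x2[i] = x[i] + fct * (mx * inv - x[i]);
        y2[i] = y[i] + fct * (my * inv - y[i]);
        z2[i] = z[i] + fct * (mz * inv - z[i]);
      }
      x.swap(x2); y.swap(y2); z.swap(z2);
    }
  }
  NumericMatrix out(nv, 3);
  for (int i = 0; i < nv; ++i) { out(i, 0) = x[i]; out(i, 1) = y[i]; out(i, 2) = z[i]; }
  return out;
}

namespace {

struct Quadric {
  double q[10]; // symmetric 4x4: xx xy xz xw yy yz yw zz zw ww
  Quadric() { std::fill(q, q + 10, 0.0); }
  void addPlane(double a, double b, double c, double d, double w) {
    q[0] += w * a * a; q[1] += w * a * b; q[2] += w * a * c; q[3] += w * a * d;
    q[4] += w * b * b; q[5] += w * b * c; q[6] += w * b * d;
    q[7] += w * c * c; q[8] += w * c * d;
    q[9] += w * d * d;
  }
  void add(const Quadric &o) { for (int i = 0; i < 10; ++i) q[i] += o.q[i]; }
  double eval(double x, double y, double z) const {
    return q[0] * x * x + 2 * q[1] * x * y + 2 * q[2] * x * z + 2 * q[3] * x +
           q[4] * y * y + 2 * q[5] * y * z + 2 * q[6] * y +
           q[7] * z * z + 2 * q[8] * z + q[9];
  }
  bool optimal(double &x, double &y, double &z) const {
    double a11 = q[0], a12 = q[1], a13 = q[2];
    double a22 = q[4], a23 = q[5], a33 = q[7];
    double det = a11 * (a22 * a33 - a23 * a23) - a12 * (a12 * a33 - a23 * a13) +
                 a13 * (a12 * a23 - a22 * a13);
    double scale = std::fabs(a11) + std::fabs(a22) + std::fabs(a33);
    if (std::fabs(det) < 1e-10 * scale * scale * scale) return false;
    double b1 = -q[3], b2 = -q[6], b3 = -q[8];
    x = (b1 * (a22 * a33 - a23 * a23) - a12 * (b2 * a33 - a23 * b3) +
         a13 * (b2 * a23 - a22 * b3)) / det;
    y = (a11 * (b2 * a33 - a23 * b3) - b1 * (a12 * a33 - a13 * a23) +
         a13 * (a12 * b3 - b2 * a13)) / det;
    z = (a11 * (a22 * b3 - b2 * a23) - a12 * (a12 * b3 - b2 * a13) +
         b1 * (a12 * a23 - a22 * a13)) / det;
    return true;
  }
};

struct HeapEntry {
  double cost;
  int u, v;
  uint32_t stamp;
  bool operator<(const HeapEntry &o) const { return cost > o.cost; } // min-heap
};

} // namespace

// [[Rcpp::export]]
List cpp_decimate_qem(NumericMatrix Vin, IntegerMatrix Fin, int target_faces) {
  int nv = Vin.nrow(), nf = Fin.nrow();
  std::vector<double> X(nv), Y(nv), Z(nv);
  for (int i = 0; i < nv; ++i) { X[i] = Vin(i, 0); Y[i] = Vin(i, 1); Z[i] = Vin(i, 2); }
  std::vector<int> FA(nf), FB(nf), FC(nf);
  std::vector<char> fAlive(nf, 1);
  std::vector<char> vAlive(nv, 1);
  for (int f = 0; f < nf; ++f) { FA[f] = Fin(f, 0) - 1; FB[f] = Fin(f, 1) - 1; FC[f] = Fin(f, 2) - 1; }

  std::vector<std::vector<int> > vFaces(nv);
  for (int f = 0; f < nf; ++f) {
    vFaces[FA[f]].push_back(f); vFaces[FB[f]].push_back(f); vFaces[FC[f]].push_back(f);
  }

  auto faceNormal = [&](int f, double *nrm) {
    double u[3] = {X[FB[f]] - X[FA[f]], Y[FB[f]] - Y[FA[f]], Z[FB[f]] - Z[FA[f]]};
    double v[3] = {X[FC[f]] - X[FA[f]], Y[FC[f]] - Y[FA[f]], Z[FC[f]] - Z[FA[f]]};
    cross3(u, v, nrm);
  };

  std::vector<Quadric> Q(nv);
  for (int f = 0; f < nf; ++f) {
    double nrm[3];
    faceNormal(f, nrm);
    double len = std::sqrt(nrm[0] * nrm[0] + nrm[1] * nrm[1] + nrm[2] * nrm[2]);
    if (len <= 0) continue;
    double area = 0.5 * len;
    double a = nrm[0] / len, b = nrm[1] / len, c = nrm[2] / len;
    double d = -(a * X[FA[f]] + b * Y[FA[f]] + c * Z[FA[f]]);
    Q[FA[f]].addPlane(a, b, c, d, area);
    Q[FB[f]].addPlane(a, b, c, d, area);
    Q[FC[f]].addPlane(a, b, c, d, area);
  }

  std::vector<uint32_t> stamp(nv, 0);
  std::priority_queue<HeapEntry> heap;

  auto neighborVerts = [&](int u, std::vector<int> &out) {
    out.clear();
    for (size_t k = 0; k < vFaces[u].size(); ++k) {
      int f = vFaces[u][k];
      if (!fAlive[f]) continue;
      int vv[3] = {FA[f], FB[f], FC[f]};
      for (int j = 0; j < 3; ++j) if (vv[j] != u) out.push_back(vv[j]);
    }
    std::sort(out.begin(), out.end());
    out.erase(std::unique(out.begin(), out.end()), out.end());
  };

  auto edgeCost = [&](int u, int v, double &cx, double &cy, double &cz) -> double {
    Quadric Qe = Q[u];
    Qe.add(Q[v]);
    double ox, oy, oz;
    double bestCost;
    if (Qe.optimal(ox, oy, oz)) {
      cx = ox; cy = oy; cz = oz;
      bestCost = Qe.eval(ox, oy, oz);
    } else {
      double mx = 0.5 * (X[u] + X[v]), my = 0.5 * (Y[u] + Y[v]), mz = 0.5 * (Z[u] + Z[v]);
      double cm = Qe.eval(mx, my, mz);
      double cu = Qe.eval(X[u], Y[u], Z[u]);
      double cv = Qe.eval(X[v], Y[v], Z[v]);
      if (cm <= cu && cm <= cv) { cx = mx; cy = my; cz = mz; bestCost = cm; }
      else if (cu <= cv) { cx = X[u]; cy = Y[u]; cz = Z[u]; bestCost = cu; }
      else { cx = X[v]; cy = Y[v]; cz = Z[v]; bestCost = cv; }
    }
    return bestCost;
  };

  auto pushEdge = [&](int u, int v) {
    if (u > v) std::swap(u, v);
    double cx, cy, cz;
    HeapEntry e;
    e.cost = edgeCost(u, v, cx, cy, cz);
    e.u = u; e.v = v;
    e.stamp = stamp[u] + stamp[v];
    heap.push(e);
  };

  {
    std::vector<std::pair<int, int> > edges;
    edges.reserve((size_t)nf * 3);
    for (int f = 0; f < nf; ++f) {
      int vv[3] = {FA[f], FB[f], FC[f]};
      for (int j = 0; j < 3; ++j) {
        int a = vv[j], b = vv[(j + 1) % 3];
        if (a > b) std::swap(a, b);
        edges.push_back(std::make_pair(a, b));
      }
    }
    std::sort(edges.begin(), edges.end());
    edges.erase(std::unique(edges.begin(), edges.end()), edges.end());
    for (size_t i = 0; i < edges.size(); ++i) pushEdge(edges[i].first, edges[i].second);
  }

  int liveFaces = nf;
  std::vector<int> nbU, nbV, commonNb;

  while (liveFaces > target_faces && !heap.empty()) {
    HeapEntry e = heap.top(); heap.pop();
    int u = e.u, v = e.v;
    if (!vAlive[u] || !vAlive[v]) continue;
    if (e.stamp != stamp[u] + stamp[v]) continue;

    // edge must still exist and be shared by exactly two live faces
    int shared = 0;
    for (size_t k = 0; k < vFaces[u].size(); ++k) {
      int f = vFaces[u][k];
      if (!fAlive[f]) continue;
      if (FA[f] == v || FB[f] == v || FC[f] == v) ++shared;
    }
    if (shared != 2) continue;

    // link condition: u and v share exactly two neighbour vertices
    neighborVerts(u, nbU);
    neighborVerts(v, nbV);
    commonNb.clear();
    std::set_intersection(nbU.begin(), nbU.end(), nbV.begin(), nbV.end(),
                          std::back_inserter(commonNb));
    if (commonNb.size() != 2) continue;

    double cx, cy, cz;
    edgeCost(u, v, cx, cy, cz);

    // reject collapses that flip surviving faces
    bool flip = false;
    for (int side = 0; side < 2 && !flip; ++side) {
      int w = side == 0 ? u : v;
      for (size_t k = 0; k < vFaces[w].size() && !flip; ++k) {
        int f = vFaces[w][k];
        if (!fAlive[f]) continue;
        int vv[3] = {FA[f], FB[f], FC[f]};
        bool dying = false;
        for (int j = 0; j < 3; ++j)
          if (vv[j] == (side == 0 ? v : u)) dying = true;
        if (dying) continue;
        double before[3], after[3];
        faceNormal(f, before);
        double sx[3], sy[3], sz[3];
        for (int j = 0; j < 3; ++j) {
          if (vv[j] == w) { sx[j] = cx; sy[j] = cy; sz[j] = cz; }
          else { sx[j] = X[vv[j]]; sy[j] = Y[vv[j]]; sz[j] = Z[vv[j]]; }
        }
        double uvec[3] = {sx[1] - sx[0], sy[1] - sy[0], sz[1] - sz[0]};
        double vvec[3] = {sx[2] - sx[0], sy[2] - sy[0], sz[2] - sz[0]};
        cross3(uvec, vvec, after);
        double dot = before[0] * after[0] + before[1] * after[1] + before[2] * after[2];
        double a2 = after[0] * after[0] + after[1] * after[1] + after[2] * after[2];
        if (dot <= 0 || a2 <= 0) flip = true;
      }
    }
    if (flip) continue;

    // perform the collapse: v merges into u at (cx, cy, cz)
    X[u] = cx; Y[u] = cy; Z[u] = cz;
    Q[u].add(Q[v]);
    vAlive[v] = 0;
    for (size_t k = 0; k < vFaces[v].size(); ++k) {
      int f = vFaces[v][k];
      if (!fAlive[f]) continue;
      bool hasU = (FA[f] == u || FB[f] == u || FC[f] == u);
      if (hasU) { fAlive[f] = 0; --liveFaces; continue; }
      if (FA[f] == v) FA[f] = u;
      if (FB[f] == v) FB[f] = u;
      if (FC[f] == v) FC[f] = u;
      vFaces[u].push_back(f);
    }
    vFaces[v].clear();
    ++stamp[u];
    neighborVerts(u, nbU);
    for (size_t k = 0; k < nbU.size(); ++k) pushEdge(u, nbU[k]);
    if (heap.size() > (size_t)40 * nf + 1000000) break; // runaway guard
  }

  // compact
  std::vector<int> vmap(nv, -1);
  int nv2 = 0;
  for (int i = 0; i < nv; ++i) if (vAlive[i]) vmap[i] = nv2++;
  int nf2 = 0;
  for (int f = 0; f < nf; ++f) if (fAlive[f]) ++nf2;
  NumericMatrix V2(nv2, 3);
  for (int i = 0; i < nv; ++i)
    if (vAlive[i]) { V2(vmap[i], 0) = X[i]; V2(vmap[i], 1) = Y[i]; V2(vmap[i], 2) = Z[i]; }
  IntegerMatrix F2(nf2, 3);
  int fi = 0;
  for (int f = 0; f < nf; ++f) {
    if (!fAlive[f]) continue;
    F2(fi, 0) = vmap[FA[f]] + 1; F2(fi, 1) = vmap[FB[f]] + 1; F2(fi, 2) = vmap[FC[f]] + 1;
    ++fi;
  }
  return List::create(Named("vertices") = V2, Named("faces") = F2);
}
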