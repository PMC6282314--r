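// Quickhull 3D, used both as the alpha = infinity oracle and for hull
// volumes.  Independent of the Delaunay engine in delaunay.cpp.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <map>
using namespace Rcpp;

namespace {

struct HFace {
  int v[3];
  int nb[3];                 // nb[i] across edge (v[i], v[(i+1)%3])
  double nx, ny, nz, off;    // outward plane: n . x = off
  std::vector<int> out;
  double farD; int farId;
  char alive;
};

struct Hull {
  const double *px, *py, *pz;
  int n;
  std::vector<HFace> faces;
  double eps;

  double dist(const HFace &f, int p) const {
    return f.nx * px[p] + f.ny * py[p] + f.nz * pz[p] - f.off;
  }

  void setPlane(HFace &f, double cx, double cy, double cz) {
    int a = f.v[0], b = f.v[1], c = f.v[2];
    double ux = px[b] - px[a], uy = py[b] - py[a], uz = pz[b] - pz[a];
    double vx = px[c] - px[a], vy = py[c] - py[a], vz = pz[c] - pz[a];
    double nx = uy * vz - uz * vy, ny = uz * vx - ux * vz, nz = ux * vy - uy * vx;
    double nrm = std::sqrt(nx * nx + ny * ny + nz * nz);
    if (nrm > 0) { nx /= nrm; ny /= nrm; nz /= nrm; }
    double off = nx * px[a] + ny * py[a] + nz * pz[a];
    // outward: interior reference point on the negative side
    if (nx * cx + ny * cy + nz * cz - off > 0) {
      std::swap(f.v[1], f.v[2]);
      nx = -nx; ny = -ny; nz = -nz; off = -off;
    }
    f.nx = nx; f.ny = ny; f.nz = nz; f.off = off;
  }
};

} // namespace

// [[Rcpp::export]]
List cpp_convex_hull(NumericMatrix pts) {
  int n = pts.nrow();
  if (n < 4) return List::create(Named("error") = "degenerate");
  std::vector<double> X(n), Y(n), Z(n);
  for (int i = 0; i < n; ++i) { X[i] = pts(i, 0); Y[i] = pts(i, 1); Z[i] = pts(i, 2); }
  Hull H;
  H.px = X.data(); H.py = Y.data(); H.pz = Z.data(); H.n = n;

  // initial simplex from extreme points
  int mn[3] = {0, 0, 0}, mx[3] = {0, 0, 0};
  for (int i = 1; i < n; ++i) {
    if (X[i] < X[mn[0]]) mn[0] = i;
    if (Y[i] < Y[mn[1]]) mn[1] = i;
    if (Z[i] < Z[mn[2]]) mn[2] = i;
    if (X[i] > X[mx[0]]) mx[0] = i;
    if (Y[i] > Y[mx[1]]) mx[1] = i;
    if (Z[i] > Z[mx[2]]) mx[2] = i;
  }
  double diag = std::sqrt((X[mx[0]] - X[mn[0]]) * (X[mx[0]] - X[mn[0]]) +
                          (Y[mx[1]] - Y[mn[1]]) * (Y[mx[1]] - Y[mn[1]]) +
                          (Z[mx[2]] - Z[mn[2]]) * (Z[mx[2]] - Z[mn[2]]));
  if (diag <= 0) return List::create(Named("error") = "degenerate");
  H.eps = 1e-12 * diag;

  int i0 = -1, i1 = -1;
  double best = -1;
  int cand[6] = {mn[0], mn[1], mn[2], mx[0], mx[1], mx[2]};
  for (int a = 0; a < 6; ++a)
    for (int b = a + 1; b < 6; ++b) {
      double dx = X[cand[a]] - X[cand[b]], dy = Y[cand[a]] - Y[cand[b]],
             dz = Z[cand[a]] - Z[cand[b]];
      double d = dx * dx + dy * dy + dz * dz;
      if (d > best) { best = d; i0 = cand[a]; i1 = cand[b]; }
    }
  if (best <= 0) return List::create(Named("error") = "degenerate");

  int i2 = -1; best = -1;
  for (int i = 0; i < n; ++i) {
    double ux = X[i1] - X[i0], uy = Y[i1] - Y[i0], uz = Z[i1] - Z[i0];
    double wx = X[i] - X[i0], wy = Y[i] - Y[i0], wz = Z[i] - Z[i0];
    double cx = uy * wz - uz * wy, cy = uz * wx - ux * wz, cz = ux * wy - uy * wx;
    double d = cx * cx + cy * cy + cz * cz;
    if (d > best) { best = d; i2 = i; }
  }
  if (best <= H.eps * H.eps * best * 0 + 1e-24 * diag * diag * diag * diag)
    return List::create(Named("error") = "degenerate");

  int i3 = -1; best = -1;
  {
    double ux = X[i1] - X[i0], uy = Y[i1] - Y[i0], uz = Z[i1] - Z[i0];
    double vx = X[i2] - X[i0], vy = Y[i2] - Y[i0], vz = Z[i2] - Z[i0];
    double nx = uy * vz - uz * vy, ny = uz * vx - ux * vz, nz = ux * vy - uy * vx;
    double nrm = std::sqrt(nx * nx + ny * ny + nz * nz);
    nx /= nrm; ny /= nrm; nz /= nrm;
    for (int i = 0; i < n; ++i) {
      double d = std::fabs(nx * (X[i] - X[i0]) + ny * (Y[i] - Y[i0]) + nz * (Z[i] - Z[i0]));
      if (d > best) { best = d; i3 = i; }
    }
  }
  if (best <= 10 * H.eps) return List::create(Named("error") = "degenerate");

  double cx = (X[i0] + X[i1] + X[i2] + X[i3]) / 4.0;
  double cy = (Y[i0] + Y[i1] + Y[i2] + Y[i3]) / 4.0;
  double cz = (Z[i0] + Z[i1] + Z[i2] + Z[i3]) / 4.0;

  int fv[4][3] = {{i0, i1, i2}, {i0, i1, i3}, {i0, i2, i3}, {i1, i2, i3}};
  for (int f = 0; f < 4; ++f) {
    HFace F;
    F.v[0] = fv[f][0]; F.v[1] = fv[f][1]; F.v[2] = fv[f][2];
    F.alive = 1; F.farD = 0; F.farId = -1;
    F.nb[0] = F.nb[1] = F.nb[2] = -1;
    H.setPlane(F, cx, cy, cz);
    H.faces.push_back(F);
  }
  // adjacency of the initial simplex via shared-edge matching
  for (int f = 0; f < 4; ++f)
    for (int e = 0; e < 3; ++e) {
      int a = H.faces[f].v[e], b = H.faces[f].v[(e + 1) % 3];
      for (int g = 0; g < 4 && H.faces[f].nb[e] < 0; ++g) {
        if (g == f) continue;
        for (int e2 = 0; e2 < 3; ++e2) {
          int a2 = H.faces[g].v[e2], b2 = H.faces[g].v[(e2 + 1) % 3];
          if ((a2 == a && b2 == b) || (a2 == b && b2 == a)) { H.faces[f].nb[e] = g; break; }
        }
      }
    }

  // assign points
  std::vector<int> stack;
  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1 || i == i2 || i == i3) continue;
    for (int f = 0; f < 4; ++f) {
      double d = H.dist(H.faces[f], i);
      if (d > H.eps) {
        H.faces[f].out.push_back(i);
        if (d > H.faces[f].farD) { H.faces[f].farD = d; H.faces[f].farId = i; }
        break;
      }
    }
  }
  for (int f = 0; f < 4; ++f) if (!H.faces[f].out.empty()) stack.push_back(f);

  std::vector<char> visited(H.faces.size(), 0);
  while (!stack.empty()) {
    int f = stack.back(); stack.pop_back();
    if (!H.faces[f].alive || H.faces[f].out.empty()) continue;
    int p = H.faces[f].farId;

    // visible region BFS
    struct HEdge { int u, w, hidden, hiddenSlot; };
    std::vector<HEdge> horizon;
    std::vector<int> vis;
    visited.resize(H.faces.size(), 0);
    std::fill(visited.begin(), visited.end(), 0);
    vis.push_back(f); visited[f] = 1;
    for (size_t q = 0; q < vis.size(); ++q) {
      int g = vis[q];
      for (int e = 0; e < 3; ++e) {
        int h = H.faces[g].nb[e];
        if (h < 0 || visited[h]) continue;
        if (H.dist(H.faces[h], p) > H.eps) { visited[h] = 1; vis.push_back(h); }
      }
    }
    for (size_t q = 0; q < vis.size(); ++q) {
      int g = vis[q];
      for (int e = 0; e < 3; ++e) {
        int h = H.faces[g].nb[e];
        if (h < 0 || visited[h]) continue;
        HEdge E;
        E.u = H.faces[g].v[e]; E.w = H.faces[g].v[(e + 1) % 3];
        E.hidden = h;
        E.hiddenSlot = -1;
        for (int e2 = 0; e2 < 3; ++e2) {
          int a2 = H.faces[h].v[e2], b2 = H.faces[h].v[(e2 + 1) % 3];
          if ((a2 == E.u && b2 == E.w) || (a2 == E.w && b2 == E.u)) { E.hiddenSlot = e2; break; }
        }
        horizon.push_back(E);
      }
    }
    if (horizon.empty()) { H.faces[f].out.clear(); continue; }

    // new faces around p
    std::vector<int> newFaces;
    std::map<std::pair<int, int>, std::pair<int, int> > emap; // edge -> (face, slot)
    for (size_t q = 0; q < horizon.size(); ++q) {
      HFace F;
      F.v[0] = horizon[q].u; F.v[1] = horizon[q].w; F.v[2] = p;
      F.alive = 1; F.farD = 0; F.farId = -1;
      F.nb[0] = F.nb[1] = F.nb[2] = -1;
      H.setPlane(F, cx, cy, cz);
      H.faces.push_back(F);
      int id = (int)H.faces.size() - 1;
      newFaces.push_back(id);
      // wire across the horizon edge: find slot holding edge (u,w)
      int slotUW = -1;
      for (int e = 0; e < 3; ++e) {
        int a = H.faces[id].v[e], b = H.faces[id].v[(e + 1) % 3];
        if ((a == horizon[q].u && b == horizon[q].w) ||
            (a == horizon[q].w && b == horizon[q].u)) { slotUW = e; break; }
      }
      H.faces[id].nb[slotUW] = horizon[q].hidden;
      H.faces[horizon[q].hidden].nb[horizon[q].hiddenSlot] = id;
      // wire the two p-edges through the pairing map
      for (int e = 0; e < 3; ++e) {
        if (e == slotUW) continue;
        int a = H.faces[id].v[e], b = H.faces[id].v[(e + 1) % 3];
        std::pair<int, int> key(std::min(a, b), std::max(a, b));
        std::map<std::pair<int, int>, std::pair<int, int> >::iterator it = emap.find(key);
        if (it == emap.end()) emap[key] = std::make_pair(id, e);
        else {
          H.faces[id].nb[e] = it->second.first;
          H.faces[it->second.first].nb[it->second.second] = id;
          emap.erase(it);
        }
      }
    }

    // redistribute outside points of visible faces
    for (size_t q = 0; q < vis.size(); ++q) {
      int g = vis[q];
      for (size_t m = 0; m < H.faces[g].out.size(); ++m) {
        int pt = H.faces[g].out[m];
        if (pt == p) continue;
        for (size_t r = 0; r < newFaces.size(); ++r) {
          int id = newFaces[r];
          double d = H.dist(H.faces[id], pt);
          if (d > H.eps) {
            H.faces[id].out.push_back(pt);
            if (d > H.faces[id].farD) { H.faces[id].farD = d; H.faces[id].farId = pt; }
            break;
          }
        }
      }
      H.faces[g].alive = 0;
      H.faces[g].out.clear();
    }
    for (size_t r = 0; r < newFaces.size(); ++r)
      if (!H.faces[newFaces[r]].out.empty()) stack.push_back(newFaces[r]);
    Rcpp::checkUserInterrupt();
  }

  // volume, area, facets
  double vol = 0, area = 0;
  int nf = 0;
  for (size_t f = 0; f < H.faces.size(); ++f) if (H.faces[f].alive) ++nf;
  IntegerMatrix facets(nf, 3);
  int fi = 0;
  for (size_t f = 0; f < H.faces.size(); ++f) {
    if (!H.faces[f].alive) continue;
    int a = H.faces[f].v[0], b = H.faces[f].v[1], c = H.faces[f].v[2];
    double ax = X[a] - cx, ay = Y[a] - cy, az = Z[a] - cz;
    double bx = X[b] - cx, by = Y[b] - cy, bz = Z[b] - cz;
    double ccx = X[c] - cx, ccy = Y[c] - cy, ccz = Z[c] - cz;
    double crx = by * ccz - bz * ccy, cry = bz * ccx - bx * ccz, crz = bx * ccy - by * ccx;
    vol += (ax * crx + ay * cry + az * crz) / 6.0;
    double ux = X[b] - X[a], uy = Y[b] - Y[a], uz = Z[b] - Z[a];
    double vx = X[c] - X[a], vy = Y[c] - Y[a], vz = Z[c] - Z[a];
    double qx = uy * vz - uz * vy, qy = uz * vx - ux * vz, qz = ux * vy - uy * vx;
    area += 0.5 * std::sqrt(qx * qx + qy * qy + qz * qz);
    facets(fi, 0) = a + 1; facets(fi, 1) = b + 1; facets(fi, 2) = c + 1;
    ++fi;
  }
  return List::create(Named("volume") = vol,
                      Named("area") = area,
                      Named("facets") = facets);
}
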