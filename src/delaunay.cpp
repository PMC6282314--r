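// Incremental (Bowyer-Watson) Delaunay tetrahedralization.
//
// The triangulation is closed by a single symbolic vertex "at infinity":
// every convex-hull facet carries one infinite tetrahedron, which avoids the
// precision pathologies of a finite super-tetrahedron.  Predicates are plain
// double determinants with per-call magnitude estimates; decisions closer to
// zero than relEps * magnitude are treated as "not inside" (ties-out), and a
// cavity star-shape repair pass guarantees a valid triangulation even when
// the input carries the exact degeneracies typical of voxel-grid data
// (cospherical and coplanar point groups).

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

const int INFV = -1;

struct Tet {
  int v[4];
  int nb[4];      // nb[i] is the tet across the face opposite v[i]
  uint32_t stamp;
  char alive;
};

// faceOrd[i] lists the face opposite vertex i, ordered so that
// orient(face, v[i]) > 0 for a positively oriented tet
const int faceOrd[4][3] = {{2, 1, 3}, {0, 2, 3}, {0, 3, 1}, {0, 1, 2}};

inline double det3x3(double a11, double a12, double a13,
                     double a21, double a22, double a23,
                     double a31, double a32, double a33,
                     double &mag) {
  double m1 = a22 * a33 - a23 * a32, p1 = std::fabs(a22 * a33) + std::fabs(a23 * a32);
  double m2 = a21 * a33 - a23 * a31, p2 = std::fabs(a21 * a33) + std::fabs(a23 * a31);
  double m3 = a21 * a32 - a22 * a31, p3 = std::fabs(a21 * a32) + std::fabs(a22 * a31);
  mag = std::fabs(a11) * p1 + std::fabs(a12) * p2 + std::fabs(a13) * p3;
  return a11 * m1 - a12 * m2 + a13 * m3;
}

struct DT {
  int n;
  std::vector<double> px, py, pz;
  std::vector<Tet> tets;
  std::vector<int> freeList;
  uint32_t curStamp;
  int lastFinite;
  uint64_t rng;
  double relEps;
  std::string failMsg;

  DT() : curStamp(1), lastFinite(0), rng(0x9E3779B97F4A7C15ull), relEps(1e-12) {}

  inline uint32_t rnd() {
    rng ^= rng << 13; rng ^= rng >> 7; rng ^= rng << 17;
    return (uint32_t)(rng >> 32);
  }

  inline bool isInf(int t) const { return tets[t].v[3] == INFV; }

  inline double orient(int a, int b, int c, int d, double &mag) const {
    return det3x3(px[b] - px[a], py[b] - py[a], pz[b] - pz[a],
                  px[c] - px[a], py[c] - py[a], pz[c] - pz[a],
                  px[d] - px[a], py[d] - py[a], pz[d] - pz[a], mag);
  }

  // positive when p is strictly inside the circumsphere of the positively
  // oriented tet (a,b,c,d)
  inline double insphere(int a, int b, int c, int d, int p, double &mag) const {
    double ax = px[a] - px[p], ay = py[a] - py[p], az = pz[a] - pz[p];
    double bx = px[b] - px[p], by = py[b] - py[p], bz = pz[b] - pz[p];
    double cx = px[c] - px[p], cy = py[c] - py[p], cz = pz[c] - pz[p];
    double dx = px[d] - px[p], dy = py[d] - py[p], dz = pz[d] - pz[p];
    double al = ax * ax + ay * ay + az * az;
    double bl = bx * bx + by * by + bz * bz;
    double cl = cx * cx + cy * cy + cz * cz;
    double dl = dx * dx + dy * dy + dz * dz;
    double m1, m2, m3, m4;
    double d1 = det3x3(bx, by, bz, cx, cy, cz, dx, dy, dz, m1);
    double d2 = det3x3(ax, ay, az, cx, cy, cz, dx, dy, dz, m2);
    double d3 = det3x3(ax, ay, az, bx, by, bz, dx, dy, dz, m3);
    double d4 = det3x3(ax, ay, az, bx, by, bz, cx, cy, cz, m4);
    mag = al * m1 + bl * m2 + cl * m3 + dl * m4;
    return al * d1 - bl * d2 + cl * d3 - dl * d4;
  }

  // is p inside the circumcircle of triangle (a,b,c) within its own plane?
  bool inCircumdisk(int a, int b, int c, int p) const {
    double ux = px[b] - px[a], uy = py[b] - py[a], uz = pz[b] - pz[a];
    double vx = px[c] - px[a], vy = py[c] - py[a], vz = pz[c] - pz[a];
    double uu = ux * ux + uy * uy + uz * uz;
    double vv = vx * vx + vy * vy + vz * vz;
    double uv = ux * vx + uy * vy + uz * vz;
    double det = uu * vv - uv * uv;
    if (det <= 1e-14 * uu * vv) return false;           // collinear facet
    double alph = 0.5 * (uu * vv - vv * uv) / det;
    double beta = 0.5 * (vv * uu - uu * uv) / det;
    double ccx = px[a] + alph * ux + beta * vx;
    double ccy = py[a] + alph * uy + beta * vy;
    double ccz = pz[a] + alph * uz + beta * vz;
    double r2 = (ccx - px[a]) * (ccx - px[a]) + (ccy - py[a]) * (ccy - py[a]) +
                (ccz - pz[a]) * (ccz - pz[a]);
    double d2 = (ccx - px[p]) * (ccx - px[p]) + (ccy - py[p]) * (ccy - py[p]) +
                (ccz - pz[p]) * (ccz - pz[p]);
    return (r2 - d2) > 1e-12 * r2;
  }

  int newTet(int a, int b, int c, int d) {
    int id;
    if (!freeList.empty()) { id = freeList.back(); freeList.pop_back(); }
    else { tets.push_back(Tet()); id = (int)tets.size() - 1; }
    Tet &t = tets[id];
    t.v[0] = a; t.v[1] = b; t.v[2] = c; t.v[3] = d;
    t.nb[0] = t.nb[1] = t.nb[2] = t.nb[3] = -1;
    t.stamp = 0; t.alive = 1;
    return id;
  }

  // conflict predicate: does the (symbolic, for infinite tets) circumsphere
  // of tet t contain point p?
  bool inConflict(int t, int p) {
    const Tet &T = tets[t];
    if (T.v[3] != INFV) {
      double mag;
      double D = insphere(T.v[0], T.v[1], T.v[2], T.v[3], p, mag);
      return D > relEps * mag;
    }
    // infinite tet: outward side of its finite face (a,b,c) is the side away
    // from d, the apex of the finite neighbour across the infinite vertex
    int a = T.v[0], b = T.v[1], c = T.v[2];
    const Tet &N = tets[T.nb[3]];
    int d = -2;
    for (int i = 0; i < 4; ++i) {
      int w = N.v[i];
      if (w != a && w != b && w != c) { d = w; break; }
    }
    double m1, m2;
    double s1 = orient(a, b, c, d, m1);
    double s2 = orient(a, b, c, p, m2);
    if (std::fabs(s2) <= relEps * m2)        // coplanar with the hull facet
      return inCircumdisk(a, b, c, p);
    return (s1 > 0.0) ? (s2 < 0.0) : (s2 > 0.0);
  }

  // walk towards p starting from a finite tet; returns a tet that either
  // contains p (finite) or certifies p outside the hull (infinite);
  // -2 when the walk gave up (caller falls back to exhaustive search)
  int locate(int p) {
    int t = lastFinite;
    if (t < 0 || t >= (int)tets.size() || !tets[t].alive || isInf(t)) {
      t = -1;
      for (int i = 0; i < (int)tets.size(); ++i)
        if (tets[i].alive && !isInf(i)) { t = i; break; }
      if (t < 0) return -1;
    }
    size_t maxSteps = tets.size() * 4 + 1000;
    for (size_t step = 0; step < maxSteps; ++step) {
      if (isInf(t)) return t;
      const Tet &T = tets[t];
      int exits[4]; int nExit = 0;
      for (int i = 0; i < 4; ++i) {
        int x = T.v[faceOrd[i][0]], y = T.v[faceOrd[i][1]], z = T.v[faceOrd[i][2]];
        double mag;
        double s = orient(x, y, z, p, mag);
        if (s < -relEps * mag) exits[nExit++] = i;
      }
      if (nExit == 0) return t;
      int pick = exits[nExit == 1 ? 0 : (int)(rnd() % nExit)];
      t = T.nb[pick];
    }
    return -2;
  }

  // is the finite boundary face (slot i of cavity tet t) valid for the star
  // on p? (p strictly on the cavity side)
  bool boundaryFaceOk(int t, int i, int p) {
    int x = tets[t].v[faceOrd[i][0]], y = tets[t].v[faceOrd[i][1]],
        z = tets[t].v[faceOrd[i][2]];
    double mag;
    double s = orient(x, y, z, p, mag);
    if (!isInf(t)) return s > relEps * mag;
    // infinite cavity tet: its stored order is arbitrary; derive the cavity
    // side from the outside (finite) tet's apex
    int o = tets[t].nb[i];
    int d = -2;
    for (int j = 0; j < 4; ++j) {
      int w = tets[o].v[j];
      if (w != x && w != y && w != z) { d = w; break; }
    }
    double m1;
    double s1 = orient(x, y, z, d, m1);
    if (std::fabs(s1) <= relEps * m1 || std::fabs(s) <= relEps * mag) return false;
    return (s1 > 0.0) != (s > 0.0);
  }

  void insert(int p) {
    int t0 = locate(p);
    std::vector<int> cavity;
    ++curStamp;

    bool seeded = false;
    if (t0 >= 0) {
      if (inConflict(t0, p)) {
        cavity.push_back(t0); tets[t0].stamp = curStamp; seeded = true;
      } else if (!isInf(t0)) {
        const Tet &T = tets[t0];
        for (int i = 0; i < 4; ++i) {
          double dx = px[T.v[i]] - px[p], dy = py[T.v[i]] - py[p], dz = pz[T.v[i]] - pz[p];
          if (dx * dx + dy * dy + dz * dz == 0.0) return;   // exact duplicate
        }
        // p inside t0 but the insphere test fell on a tie: force-include
        cavity.push_back(t0); tets[t0].stamp = curStamp; seeded = true;
      }
    }
    if (!seeded) {
      for (int i = 0; i < (int)tets.size() && !seeded; ++i)
        if (tets[i].alive && inConflict(i, p)) {
          cavity.push_back(i); tets[i].stamp = curStamp; seeded = true;
        }
      if (!seeded) return;  // duplicate or fully degenerate: drop the point
    }

    // grow the conflict region
    for (size_t q = 0; q < cavity.size(); ++q) {
      int t = cavity[q];
      for (int i = 0; i < 4; ++i) {
        int nbT = tets[t].nb[i];
        if (nbT < 0 || tets[nbT].stamp == curStamp) continue;
        if (inConflict(nbT, p)) { tets[nbT].stamp = curStamp; cavity.push_back(nbT); }
      }
    }

    // star-shape repair: every finite boundary face must see p strictly from
    // the cavity side, else absorb the outside tet and rescan
    bool changed = true;
    size_t guard = 0;
    while (changed && guard++ < tets.size() + 16) {
      changed = false;
      for (size_t q = 0; q < cavity.size() && !changed; ++q) {
        int t = cavity[q];
        for (int i = 0; i < 4; ++i) {
          int nbT = tets[t].nb[i];
          if (nbT < 0 || tets[nbT].stamp == curStamp) continue;
          int x = tets[t].v[faceOrd[i][0]], y = tets[t].v[faceOrd[i][1]],
              z = tets[t].v[faceOrd[i][2]];
          if (x == INFV || y == INFV || z == INFV) continue;
          if (!boundaryFaceOk(t, i, p)) {
            tets[nbT].stamp = curStamp; cavity.push_back(nbT);
            changed = true; break;
          }
        }
      }
    }

    // collect boundary faces
    struct BFace { int x, y, z; int outside; int outSlot; };
    std::vector<BFace> bfaces;
    for (size_t q = 0; q < cavity.size(); ++q) {
      int t = cavity[q];
      for (int i = 0; i < 4; ++i) {
        int nbT = tets[t].nb[i];
        if (nbT >= 0 && tets[nbT].stamp == curStamp) continue;
        BFace f;
        f.x = tets[t].v[faceOrd[i][0]];
        f.y = tets[t].v[faceOrd[i][1]];
        f.z = tets[t].v[faceOrd[i][2]];
        f.outside = nbT;
        f.outSlot = -1;
        if (nbT >= 0) {
          for (int j = 0; j < 4; ++j) {
            int w = tets[nbT].v[j];
            if (w != f.x && w != f.y && w != f.z) { f.outSlot = j; break; }
          }
        }
        bfaces.push_back(f);
      }
    }
    if (bfaces.empty()) return;

    // retriangulate the cavity as a star on p; wire internal faces through a
    // small (edge -> tet,slot) map keyed by the two non-p vertices
    std::vector<int64_t> ekey; std::vector<int> etet, eslot;
    ekey.reserve(bfaces.size() * 3);
    std::vector<int> newTets; newTets.reserve(bfaces.size());

    for (size_t q = 0; q < bfaces.size(); ++q) {
      BFace &f = bfaces[q];
      int id, slotOppBoundary;
      if (f.x == INFV || f.y == INFV || f.z == INFV) {
        int fin[2]; int nf = 0;
        int vv[3] = {f.x, f.y, f.z};
        for (int i = 0; i < 3; ++i) if (vv[i] != INFV) fin[nf++] = vv[i];
        id = newTet(fin[0], fin[1], p, INFV);
        slotOppBoundary = 2;   // face {fin0, fin1, INF} is opposite p (slot 2)
      } else {
        double mag;
        double s = orient(f.x, f.y, f.z, p, mag);
        if (s < 0) std::swap(f.x, f.y);   // infinite-source faces need reordering
        id = newTet(f.x, f.y, f.z, p);
        slotOppBoundary = 3;
      }
      newTets.push_back(id);
      tets[id].nb[slotOppBoundary] = f.outside;
      if (f.outside >= 0) tets[f.outside].nb[f.outSlot] = id;
      for (int i = 0; i < 4; ++i) {
        if (i == slotOppBoundary) continue;
        int o[3] = {tets[id].v[faceOrd[i][0]], tets[id].v[faceOrd[i][1]],
                    tets[id].v[faceOrd[i][2]]};
        int kk[2]; int nk = 0;
        for (int j = 0; j < 3; ++j) if (o[j] != p) kk[nk++] = o[j];
        int64_t a = kk[0] + 1, b = kk[1] + 1;   // shift so INFV -> 0
        if (a > b) std::swap(a, b);
        int64_t key = (a << 24) | b;
        bool wired = false;
        for (size_t m = 0; m < ekey.size(); ++m) {
          if (ekey[m] == key) {
            tets[id].nb[i] = etet[m];
            tets[etet[m]].nb[eslot[m]] = id;
            ekey[m] = -1;
            wired = true;
            break;
          }
        }
        if (!wired) { ekey.push_back(key); etet.push_back(id); eslot.push_back(i); }
      }
    }

    for (size_t q = 0; q < cavity.size(); ++q) {
      tets[cavity[q]].alive = 0;
      freeList.push_back(cavity[q]);
    }
    for (size_t q = 0; q < newTets.size(); ++q)
      if (!isInf(newTets[q])) { lastFinite = newTets[q]; break; }
  }

  bool bootstrap(std::vector<int> &order) {
    int i0 = order[0];
    int i1 = -1, i2 = -1, i3 = -1;
    for (size_t q = 1; q < order.size(); ++q) {
      int j = order[q];
      double dx = px[j] - px[i0], dy = py[j] - py[i0], dz = pz[j] - pz[i0];
      if (dx * dx + dy * dy + dz * dz > 0) { i1 = j; break; }
    }
    if (i1 < 0) { failMsg = "degenerate"; return false; }
    for (size_t q = 1; q < order.size(); ++q) {
      int j = order[q];
      if (j == i1) continue;
      double ux = px[i1] - px[i0], uy = py[i1] - py[i0], uz = pz[i1] - pz[i0];
      double vx = px[j] - px[i0], vy = py[j] - py[i0], vz = pz[j] - pz[i0];
      double cx = uy * vz - uz * vy, cy = uz * vx - ux * vz, cz = ux * vy - uy * vx;
      double c2 = cx * cx + cy * cy + cz * cz;
      double u2 = ux * ux + uy * uy + uz * uz;
      double v2 = vx * vx + vy * vy + vz * vz;
      if (c2 > 1e-20 * u2 * v2) { i2 = j; break; }
    }
    if (i2 < 0) { failMsg = "degenerate"; return false; }
    for (size_t q = 1; q < order.size(); ++q) {
      int j = order[q];
      if (j == i1 || j == i2) continue;
      double mag;
      double s = orient(i0, i1, i2, j, mag);
      if (mag > 0 && std::fabs(s) > relEps * mag) { i3 = j; break; }
    }
    if (i3 < 0) { failMsg = "degenerate"; return false; }

    double mag;
    if (orient(i0, i1, i2, i3, mag) < 0) std::swap(i1, i2);
    int t = newTet(i0, i1, i2, i3);
    int inf[4];
    for (int i = 0; i < 4; ++i) {
      int x = tets[t].v[faceOrd[i][0]], y = tets[t].v[faceOrd[i][1]],
          z = tets[t].v[faceOrd[i][2]];
      inf[i] = newTet(x, y, z, INFV);
      tets[inf[i]].nb[3] = t;
      tets[t].nb[i] = inf[i];
    }
    // wire infinite tets across shared (edge, INF) faces
    for (int i = 0; i < 4; ++i)
      for (int a = 0; a < 3; ++a) {
        int o1 = tets[inf[i]].v[(a + 1) % 3], o2 = tets[inf[i]].v[(a + 2) % 3];
        for (int j = 0; j < 4; ++j) {
          if (j == i) continue;
          int match = 0;
          for (int b = 0; b < 3; ++b) {
            int w = tets[inf[j]].v[b];
            if (w == o1 || w == o2) ++match;
          }
          if (match == 2) { tets[inf[i]].nb[a] = inf[j]; break; }
        }
      }
    lastFinite = t;
    std::vector<int> rest;
    rest.reserve(order.size());
    for (size_t q = 0; q < order.size(); ++q) {
      int j = order[q];
      if (j != i0 && j != i1 && j != i2 && j != i3) rest.push_back(j);
    }
    order.swap(rest);
    return true;
  }
};

} // namespace

// [[Rcpp::export]]
List cpp_delaunay(NumericMatrix pts, double degenerate_rel_tol = 1e-12) {
  int n = pts.nrow();
  if (n < 4) return List::create(Named("error") = "degenerate");
  DT dt;
  dt.n = n;
  dt.px.resize(n); dt.py.resize(n); dt.pz.resize(n);
  for (int i = 0; i < n; ++i) {
    dt.px[i] = pts(i, 0); dt.py[i] = pts(i, 1); dt.pz[i] = pts(i, 2);
  }

  // deterministic pseudo-random insertion order
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  for (int i = n - 1; i > 0; --i) {
    int j = (int)(dt.rnd() % (uint32_t)(i + 1));
    std::swap(order[i], order[j]);
  }

  if (!dt.bootstrap(order))
    return List::create(Named("error") = "degenerate");
  for (size_t q = 0; q < order.size(); ++q) {
    dt.insert(order[q]);
    if (q % 4096 == 0) Rcpp::checkUserInterrupt();
  }

  std::vector<int> keep;
  for (int i = 0; i < (int)dt.tets.size(); ++i)
    if (dt.tets[i].alive && dt.tets[i].v[3] != INFV) keep.push_back(i);
  int T = (int)keep.size();
  if (T == 0) return List::create(Named("error") = "degenerate");

  double lo[3] = {R_PosInf, R_PosInf, R_PosInf}, hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int i = 0; i < n; ++i) {
    lo[0] = std::min(lo[0], dt.px[i]); hi[0] = std::max(hi[0], dt.px[i]);
    lo[1] = std::min(lo[1], dt.py[i]); hi[1] = std::max(hi[1], dt.py[i]);
    lo[2] = std::min(lo[2], dt.pz[i]); hi[2] = std::max(hi[2], dt.pz[i]);
  }
  double diag = std::sqrt((hi[0] - lo[0]) * (hi[0] - lo[0]) +
                          (hi[1] - lo[1]) * (hi[1] - lo[1]) +
                          (hi[2] - lo[2]) * (hi[2] - lo[2]));
  double volTol = degenerate_rel_tol * diag * diag * diag;

  IntegerMatrix tetM(T, 4);
  NumericVector vol(T), crad(T);
  for (int q = 0; q < T; ++q) {
    const Tet &t = dt.tets[keep[q]];
    for (int i = 0; i < 4; ++i) tetM(q, i) = t.v[i] + 1;
    double mag;
    double o = dt.orient(t.v[0], t.v[1], t.v[2], t.v[3], mag);
    vol[q] = std::fabs(o) / 6.0;
    // circumcentre via the linear system in coordinates translated to v0
    double ax = dt.px[t.v[0]], ay = dt.py[t.v[0]], az = dt.pz[t.v[0]];
    double r1x = dt.px[t.v[1]] - ax, r1y = dt.py[t.v[1]] - ay, r1z = dt.pz[t.v[1]] - az;
    double r2x = dt.px[t.v[2]] - ax, r2y = dt.py[t.v[2]] - ay, r2z = dt.pz[t.v[2]] - az;
    double r3x = dt.px[t.v[3]] - ax, r3y = dt.py[t.v[3]] - ay, r3z = dt.pz[t.v[3]] - az;
    double b1 = 0.5 * (r1x * r1x + r1y * r1y + r1z * r1z);
    double b2 = 0.5 * (r2x * r2x + r2y * r2y + r2z * r2z);
    double b3 = 0.5 * (r3x * r3x + r3y * r3y + r3z * r3z);
    double mg;
    double D = det3x3(r1x, r1y, r1z, r2x, r2y, r2z, r3x, r3y, r3z, mg);
    if (vol[q] <= volTol || std::fabs(D) <= 1e-14 * mg) {
      crad[q] = R_PosInf;   // numerically flat: kept only at alpha = infinity
      continue;
    }
    double m2_;
    double Dx = det3x3(b1, r1y, r1z, b2, r2y, r2z, b3, r3y, r3z, m2_);
    double Dy = det3x3(r1x, b1, r1z, r2x, b2, r2z, r3x, b3, r3z, m2_);
    double Dz = det3x3(r1x, r1y, b1, r2x, r2y, b2, r3x, r3y, b3, m2_);
    double cx = Dx / D, cy = Dy / D, cz = Dz / D;
    crad[q] = std::sqrt(cx * cx + cy * cy + cz * cz);
  }

  // face table via a sort over the 4T (sorted-triple, tet) records
  std::vector<std::pair<int64_t, int> > rec;
  rec.reserve((size_t)T * 4);
  for (int q = 0; q < T; ++q) {
    const Tet &t = dt.tets[keep[q]];
    for (int i = 0; i < 4; ++i) {
      int a = t.v[faceOrd[i][0]], b = t.v[faceOrd[i][1]], c = t.v[faceOrd[i][2]];
      int s0 = std::min(a, std::min(b, c));
      int s2 = std::max(a, std::max(b, c));
      int s1 = a + b + c - s0 - s2;
      int64_t key = ((int64_t)s0 << 42) | ((int64_t)s1 << 21) | (int64_t)s2;
      rec.push_back(std::make_pair(key, q));
    }
  }
  std::sort(rec.begin(), rec.end());
  int F = 0;
  for (size_t i = 0; i < rec.size();) {
    size_t j = i;
    while (j < rec.size() && rec[j].first == rec[i].first) ++j;
    ++F; i = j;
  }
  IntegerMatrix faceM(F, 3), faceT(F, 2);
  int fi = 0;
  for (size_t i = 0; i < rec.size();) {
    size_t j = i;
    while (j < rec.size() && rec[j].first == rec[i].first) ++j;
    int64_t key = rec[i].first;
    faceM(fi, 0) = (int)(key >> 42) + 1;
    faceM(fi, 1) = (int)((key >> 21) & 0x1FFFFF) + 1;
    faceM(fi, 2) = (int)(key & 0x1FFFFF) + 1;
    faceT(fi, 0) = rec[i].second + 1;
    faceT(fi, 1) = (j - i > 1) ? rec[i + 1].second + 1 : 0;
    ++fi; i = j;
  }

  return List::create(Named("tets") = tetM,
                      Named("volume") = vol,
                      Named("circumradius") = crad,
                      Named("faces") = faceM,
                      Named("face_tets") = faceT);
}
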