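// Quadric edge-collapse decimation (Garland & Heckbert error quadrics).
// Collapses the cheapest valid edge repeatedly until the face budget is met,
// rejecting collapses that would break edge-manifoldness (link condition)
// or flip triangle normals.
#include <Rcpp.h>
#include <vector>
#include <queue>
#include <set>
#include <array>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Quadric {
  // symmetric 4x4 quadric, stored as upper triangle
  double q[10] = {0,0,0,0,0,0,0,0,0,0};
  // order: xx xy xz xw yy yz yw zz zw ww
  void add_plane(double a, double b, double c, double d, double w) {
    q[0]+=w*a*a; q[1]+=w*a*b; q[2]+=w*a*c; q[3]+=w*a*d;
    q[4]+=w*b*b; q[5]+=w*b*c; q[6]+=w*b*d;
    q[7]+=w*c*c; q[8]+=w*c*d; q[9]+=w*d*d;
  }
  void add(const Quadric &o) { for (int i = 0; i < 10; ++i) q[i] += o.q[i]; }
  double eval(double x, double y, double z) const {
    return q[0]*x*x + 2*q[1]*x*y + 2*q[2]*x*z + 2*q[3]*x
         + q[4]*y*y + 2*q[5]*y*z + 2*q[6]*y
         + q[7]*z*z + 2*q[8]*z + q[9];
  }
  // minimise: solve 3x3 system A v = -b
  bool optimum(double &x, double &y, double &z) const {
    double a11=q[0], a12=q[1], a13=q[2], a22=q[4], a23=q[5], a33=q[7];
    double b1=-q[3], b2=-q[6], b3=-q[8];
    double det = a11*(a22*a33 - a23*a23) - a12*(a12*a33 - a23*a13)
               + a13*(a12*a23 - a22*a13);
    double scale = std::max({std::fabs(a11), std::fabs(a22), std::fabs(a33), 1e-300});
    if (std::fabs(det) < 1e-10 * scale * scale * scale) return false;
    double ix = ( (a22*a33 - a23*a23)*b1 + (a13*a23 - a12*a33)*b2 + (a12*a23 - a13*a22)*b3) / det;
    double iy = ( (a23*a13 - a12*a33)*b1 + (a11*a33 - a13*a13)*b2 + (a12*a13 - a11*a23)*b3) / det;
    double iz = ( (a12*a23 - a13*a22)*b1 + (a12*a13 - a11*a23)*b2 + (a11*a22 - a12*a12)*b3) / det;
    x = ix; y = iy; z = iz;
    return true;
  }
};

struct HeapItem {
  double cost; int u, v; long stamp;
  bool operator<(const HeapItem &o) const {
    if (cost != o.cost) return cost > o.cost; // min-heap
    if (u != o.u) return u > o.u;
    return v > o.v;
  }
};

} // namespace

// [[Rcpp::export]]
List cpp_decimate(NumericMatrix Vin, IntegerMatrix Fin, int target_faces) {
  int nv = Vin.nrow(), nf = Fin.nrow();
  std::vector<std::array<double,3>> V(nv);
  for (int i = 0; i < nv; ++i) V[i] = {Vin(i,0), Vin(i,1), Vin(i,2)};
  std::vector<std::array<int,3>> F(nf);
  for (int i = 0; i < nf; ++i) F[i] = {Fin(i,0) - 1, Fin(i,1) - 1, Fin(i,2) - 1};
  std::vector<char> fdead(nf, 0), vdead(nv, 0);
  std::vector<std::vector<int>> vfaces(nv);
  for (int f = 0; f < nf; ++f)
    for (int k = 0; k < 3; ++k) vfaces[F[f][k]].push_back(f);

  auto face_normal = [&](int f, double *n, double *area) {
    auto &a = V[F[f][0]]; auto &b = V[F[f][1]]; auto &c = V[F[f][2]];
    double ux = b[0]-a[0], uy = b[1]-a[1], uz = b[2]-a[2];
    double wx = c[0]-a[0], wy = c[1]-a[1], wz = c[2]-a[2];
    n[0] = uy*wz - uz*wy; n[1] = uz*wx - ux*wz; n[2] = ux*wy - uy*wx;
    double len = std::sqrt(n[0]*n[0] + n[1]*n[1] + n[2]*n[2]);
    *area = 0.5 * len;
    if (len > 0) { n[0] /= len; n[1] /= len; n[2] /= len; }
  };

  std::vector<Quadric> Q(nv);
  for (int f = 0; f < nf; ++f) {
    double n[3], area;
    face_normal(f, n, &area);
    if (area <= 0) continue;
    auto &a = V[F[f][0]];
    double d = -(n[0]*a[0] + n[1]*a[1] + n[2]*a[2]);
    for (int k = 0; k < 3; ++k) Q[F[f][k]].add_plane(n[0], n[1], n[2], d, area);
  }

  std::vector<long> vstamp(nv, 0);
  std::priority_queue<HeapItem> heap;

  auto neighbours = [&](int u) {
    std::set<int> nb;
    for (int f : vfaces[u]) {
      if (fdead[f]) continue;
      for (int k = 0; k < 3; ++k) if (F[f][k] != u) nb.insert(F[f][k]);
    }
    return nb;
  };

  auto edge_cost = [&](int u, int v, double *pos) -> double {
    Quadric q = Q[u]; q.add(Q[v]);
    double x, y, z;
    if (!q.optimum(x, y, z)) {
      // degenerate quadric: best of endpoints and midpoint
      double mx = 0.5*(V[u][0]+V[v][0]), my = 0.5*(V[u][1]+V[v][1]), mz = 0.5*(V[u][2]+V[v][2]);
      double cu = q.eval(V[u][0],V[u][1],V[u][2]);
      double cv = q.eval(V[v][0],V[v][1],V[v][2]);
      double cm = q.eval(mx,my,mz);
      if (cm <= cu && cm <= cv) { x = mx; y = my; z = mz; }
      else if (cu <= cv) { x = V[u][0]; y = V[u][1]; z = V[u][2]; }
      else { x = V[v][0]; y = V[v][1]; z = V[v][2]; }
    }
    pos[0] = x; pos[1] = y; pos[2] = z;
    return q.eval(x, y, z);
  };

  auto push_edges_of = [&](int u) {
    for (int v : neighbours(u)) {
      int a = std::min(u, v), b = std::max(u, v);
      double pos[3];
      double c = edge_cost(a, b, pos);
      heap.push({c, a, b, vstamp[a] + vstamp[b]});
    }
  };
  for (int u = 0; u < nv; ++u) {
    for (int v : neighbours(u)) if (v > u) {
      double pos[3];
      heap.push({edge_cost(u, v, pos), u, v, 0});
    }
  }

  int faces_alive = nf;
  int warn_stuck = 0;
  while (faces_alive > target_faces && !heap.empty()) {
    HeapItem it = heap.top(); heap.pop();
    int u = it.u, v = it.v;
    if (vdead[u] || vdead[v]) continue;
    if (it.stamp != vstamp[u] + vstamp[v]) continue; // stale entry
    // still an edge?
    auto nu = neighbours(u);
    if (!nu.count(v)) continue;
    // link condition: common neighbours must be exactly the two wing vertices
    auto nv2 = neighbours(v);
    std::vector<int> common;
    for (int w : nu) if (nv2.count(w)) common.push_back(w);
    // faces shared by u and v
    std::vector<int> shared;
    for (int f : vfaces[u]) {
      if (fdead[f]) continue;
      for (int k = 0; k < 3; ++k) if (F[f][k] == v) { shared.push_back(f); break; }
    }
    if (shared.size() != 2 || common.size() != 2) continue;

    double pos[3];
    edge_cost(u, v, pos);
    // normal-flip test for surviving faces around u and v
    bool flip = false;
    for (int w : {u, v}) {
      for (int f : vfaces[w]) {
        if (fdead[f]) continue;
        bool gone = false;
        for (int s : shared) if (s == f) gone = true;
        if (gone) continue;
        double n0[3], area0; face_normal(f, n0, &area0);
        std::array<double,3> savedu = V[u], savedv = V[v];
        V[u] = {pos[0], pos[1], pos[2]}; V[v] = {pos[0], pos[1], pos[2]};
        double n1[3], area1; face_normal(f, n1, &area1);
        V[u] = savedu; V[v] = savedv;
        if (area1 < 1e-14 || n0[0]*n1[0] + n0[1]*n1[1] + n0[2]*n1[2] < 0.0) { flip = true; break; }
      }
      if (flip) break;
    }
    if (flip) continue;

    // perform collapse: v -> u at pos
    V[u] = {pos[0], pos[1], pos[2]};
    Q[u].add(Q[v]);
    for (int f : shared) { fdead[f] = 1; --faces_alive; }
    for (int f : vfaces[v]) {
      if (fdead[f]) continue;
      for (int k = 0; k < 3; ++k) if (F[f][k] == v) F[f][k] = u;
      vfaces[u].push_back(f);
    }
    vdead[v] = 1;
    ++vstamp[u];
    push_edges_of(u);
  }
  if (faces_alive > target_faces) warn_stuck = 1;

  // compact output
  std::vector<int> vmap(nv, -1);
  int nvo = 0;
  for (int i = 0; i < nv; ++i) if (!vdead[i]) vmap[i] = nvo++;
  // some surviving vertices may have lost all faces; drop them
  std::vector<char> used(nv, 0);
  int nfo = 0;
  for (int f = 0; f < nf; ++f) if (!fdead[f]) { ++nfo; for (int k = 0; k < 3; ++k) used[F[f][k]] = 1; }
  std::fill(vmap.begin(), vmap.end(), -1);
  nvo = 0;
  for (int i = 0; i < nv; ++i) if (used[i]) vmap[i] = nvo++;
  NumericMatrix Vout(nvo, 3);
  for (int i = 0; i < nv; ++i) if (used[i])
    for (int k = 0; k < 3; ++k) Vout(vmap[i], k) = V[i][k];
  IntegerMatrix Fout(nfo, 3);
  int fi = 0;
  for (int f = 0; f < nf; ++f) if (!fdead[f]) {
    for (int k = 0; k < 3; ++k) Fout(fi, k) = vmap[F[f][k]] + 1;
    ++fi;
  }
  return List::create(_["vertices"] = Vout, _["faces"] = Fout,
                      _["reached_target"] = (warn_stuck == 0));
}
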