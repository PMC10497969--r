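// Iso-surface extraction on a voxel-node scalar field by marching over the
// Freudenthal (Kuhn) 6-tetrahedra decomposition of each grid cube. The
// decomposition is translation-consistent, so shared cube faces carry the
// same diagonal and the resulting surface is watertight by construction.
#include <Rcpp.h>
#include <unordered_map>
#include <array>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

struct V3 { double x, y, z; };

static inline V3 vsub(const V3 &a, const V3 &b) { return {a.x-b.x, a.y-b.y, a.z-b.z}; }
static inline V3 vcross(const V3 &a, const V3 &b) {
  return {a.y*b.z - a.z*b.y, a.z*b.x - a.x*b.z, a.x*b.y - a.y*b.x};
}
static inline double vdot(const V3 &a, const V3 &b) { return a.x*b.x + a.y*b.y + a.z*b.z; }

// field: dim (nz, ny, nx), values at voxel-node positions
// node (iz,iy,ix) sits at origin + (ix*sx, iy*sy, iz*sz) in (x,y,z) µm.
// Returns list(vertices = V x 3 (x,y,z), faces = F x 3, 1-based), surface at
// field == iso oriented outward from the region field > iso.
// [[Rcpp::export]]
List cpp_marching_tets(NumericVector field, IntegerVector dim,
                       NumericVector spacing, NumericVector origin,
                       double iso) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  double sz = spacing[0], sy = spacing[1], sx = spacing[2];
  double oz = origin[0], oy = origin[1], ox = origin[2];
  auto nid = [&](int iz, int iy, int ix) -> int64_t {
    return (int64_t)iz + (int64_t)nz * ((int64_t)iy + (int64_t)ny * ix);
  };
  auto fval = [&](int64_t id) { return field[id]; };
  auto npos = [&](int64_t id) -> V3 {
    int iz = id % nz; int64_t r = id / nz;
    int iy = r % ny; int ix = r / ny;
    return {ox + ix * sx, oy + iy * sy, oz + iz * sz};
  };
  // nudge values landing exactly on the iso level so edge interpolation never
  // produces degenerate (zero-length) edges
  double scale = 0.0;
  for (R_xlen_t i = 0; i < field.size(); ++i) scale = std::max(scale, std::fabs(field[i] - iso));
  double eps = (scale > 0 ? scale : 1.0) * 1e-9;

  std::unordered_map<uint64_t, int> vmap; // edge key -> vertex index
  std::vector<V3> verts;
  std::vector<std::array<int,3>> tris;

  auto edge_vertex = [&](int64_t a, int64_t b) -> int {
    if (a > b) std::swap(a, b);
    // node ids fit in 32 bits for any grid this package handles
    uint64_t key = ((uint64_t)a << 32) | (uint64_t)(uint32_t)b;
    auto it = vmap.find(key);
    if (it != vmap.end()) return it->second;
    double fa = fval(a) - iso, fb = fval(b) - iso;
    if (std::fabs(fa) < eps) fa = (fa >= 0 ? eps : -eps);
    if (std::fabs(fb) < eps) fb = (fb >= 0 ? eps : -eps);
    double t = fa / (fa - fb);
    if (t < 1e-7) t = 1e-7;
    if (t > 1 - 1e-7) t = 1 - 1e-7;
    V3 pa = npos(a), pb = npos(b);
    verts.push_back({pa.x + t * (pb.x - pa.x), pa.y + t * (pb.y - pa.y),
                     pa.z + t * (pb.z - pa.z)});
    int id = (int)verts.size() - 1;
    vmap.emplace(key, id);
    return id;
  };

  // orientation fix: outward normal must point away from the inside point q
  auto emit = [&](int i0, int i1, int i2, const V3 &inside_pt) {
    V3 n = vcross(vsub(verts[i1], verts[i0]), vsub(verts[i2], verts[i0]));
    V3 c = {(verts[i0].x + verts[i1].x + verts[i2].x) / 3.0,
            (verts[i0].y + verts[i1].y + verts[i2].y) / 3.0,
            (verts[i0].z + verts[i1].z + verts[i2].z) / 3.0};
    if (vdot(n, vsub(c, inside_pt)) < 0) std::swap(i1, i2);
    tris.push_back({i0, i1, i2});
  };

  // the 6 permutations of axis insertion orders (Freudenthal path 000 -> 111)
  static const int perms[6][3] = {{0,1,2},{0,2,1},{1,0,2},{1,2,0},{2,0,1},{2,1,0}};
  // axis 0 = z, 1 = y, 2 = x (steps in node indices)
  for (int ix = 0; ix < nx - 1; ++ix)
    for (int iy = 0; iy < ny - 1; ++iy)
      for (int iz = 0; iz < nz - 1; ++iz) {
        // quick reject: all 8 corners same side
        bool anyIn = false, anyOut = false;
        for (int d = 0; d < 8; ++d) {
          double v = fval(nid(iz + (d & 1), iy + ((d >> 1) & 1), ix + ((d >> 2) & 1))) - iso;
          if (v > 0) anyIn = true; else anyOut = true;
        }
        if (!anyIn || !anyOut) continue;
        for (int pp = 0; pp < 6; ++pp) {
          int czyx[3] = {iz, iy, ix};
          int64_t tv[4];
          tv[0] = nid(czyx[0], czyx[1], czyx[2]);
          for (int s = 0; s < 3; ++s) {
            czyx[perms[pp][s]] += 1;
            tv[s + 1] = nid(czyx[0], czyx[1], czyx[2]);
          }
          bool in[4]; int nin = 0;
          for (int s = 0; s < 4; ++s) {
            double v = fval(tv[s]) - iso;
            if (std::fabs(v) < eps) v = eps; // on-surface nodes count as inside
            in[s] = v > 0; if (in[s]) ++nin;
          }
          if (nin == 0 || nin == 4) continue;
          int ins[4], outs[4]; int ni = 0, no = 0;
          for (int s = 0; s < 4; ++s) (in[s] ? ins[ni++] : outs[no++]) = s;
          if (nin == 1) {
            V3 q = npos(tv[ins[0]]);
            int a = edge_vertex(tv[ins[0]], tv[outs[0]]);
            int b = edge_vertex(tv[ins[0]], tv[outs[1]]);
            int c = edge_vertex(tv[ins[0]], tv[outs[2]]);
            emit(a, b, c, q);
          } else if (nin == 3) {
            // inside centroid of the three interior nodes
            V3 p0 = npos(tv[ins[0]]), p1 = npos(tv[ins[1]]), p2 = npos(tv[ins[2]]);
            V3 q = {(p0.x + p1.x + p2.x) / 3, (p0.y + p1.y + p2.y) / 3,
                    (p0.z + p1.z + p2.z) / 3};
            int a = edge_vertex(tv[ins[0]], tv[outs[0]]);
            int b = edge_vertex(tv[ins[1]], tv[outs[0]]);
            int c = edge_vertex(tv[ins[2]], tv[outs[0]]);
            emit(a, b, c, q);
          } else { // nin == 2: quad split into two triangles
            V3 p0 = npos(tv[ins[0]]), p1 = npos(tv[ins[1]]);
            V3 q = {(p0.x + p1.x) / 2, (p0.y + p1.y) / 2, (p0.z + p1.z) / 2};
            int a = edge_vertex(tv[ins[0]], tv[outs[0]]);
            int b = edge_vertex(tv[ins[0]], tv[outs[1]]);
            int c = edge_vertex(tv[ins[1]], tv[outs[1]]);
            int d = edge_vertex(tv[ins[1]], tv[outs[0]]);
            emit(a, b, c, q);
            emit(a, c, d, q);
          }
        }
      }

  NumericMatrix V((int)verts.size(), 3);
  for (size_t i = 0; i < verts.size(); ++i) {
    V(i, 0) = verts[i].x; V(i, 1) = verts[i].y; V(i, 2) = verts[i].z;
  }
  IntegerMatrix F((int)tris.size(), 3);
  for (size_t i = 0; i < tris.size(); ++i) {
    F(i, 0) = tris[i][0] + 1; F(i, 1) = tris[i][1] + 1; F(i, 2) = tris[i][2] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}
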