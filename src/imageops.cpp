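// Low-level 3D image operations on arrays with dim = c(nz, ny, nx)
// (column-major linear index: iz + nz*(iy + ny*ix)).
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

static inline int idx3(int iz, int iy, int ix, int nz, int ny) {
  return iz + nz * (iy + ny * ix);
}

// ---------------------------------------------------------------------------
// Separable Gaussian blur, reflect boundary. sigma is in voxels per axis
// (z, y, x); sigma <= 0 skips that axis.
// [[Rcpp::export]]
NumericVector cpp_gauss_blur(NumericVector img, IntegerVector dim,
                             NumericVector sigma) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  std::vector<double> a(img.begin(), img.end()), b(a.size());
  int n[3] = {nz, ny, nx};
  // stride along each axis in the linear layout
  long str[3] = {1, (long)nz, (long)nz * ny};
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma[ax];
    if (s <= 0) continue;
    int r = (int)std::ceil(3.0 * s);
    std::vector<double> k(2 * r + 1);
    double ksum = 0;
    for (int i = -r; i <= r; ++i) { k[i + r] = std::exp(-0.5 * i * i / (s * s)); ksum += k[i + r]; }
    for (double &v : k) v /= ksum;
    int len = n[ax];
    long nlines = (long)nz * ny * nx / len;
    // enumerate lines: iterate over the other two axes
    int o1 = (ax == 0) ? 1 : 0;
    int o2 = (ax == 2) ? 1 : 2;
    for (int j2 = 0; j2 < n[o2]; ++j2) {
      for (int j1 = 0; j1 < n[o1]; ++j1) {
        long base = (long)j1 * str[o1] + (long)j2 * str[o2];
        for (int i = 0; i < len; ++i) {
          double acc = 0;
          for (int t = -r; t <= r; ++t) {
            int p = i + t;
            // reflect repeatedly (kernel may be wider than the axis)
            while (p < 0 || p >= len) {
              if (p < 0) p = -p - 1;
              if (p >= len) p = 2 * len - p - 1;
            }
            acc += k[t + r] * a[base + (long)p * str[ax]];
          }
          b[base + (long)i * str[ax]] = acc;
        }
      }
    }
    std::swap(a, b);
    (void)nlines;
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dim;
  return out;
}

// ---------------------------------------------------------------------------
// Squared Euclidean distance transform (Felzenszwalb & Huttenlocher),
// distance of foreground voxels to the nearest background voxel, in
// physical units given per-axis spacing (z, y, x).
static void dt1d(const std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &z, int n, double w2) {
  int k = 0;
  v[0] = 0; z[0] = -INFINITY; z[1] = INFINITY;
  for (int q = 1; q < n; q++) {
    double s;
    while (true) {
      s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) / (2.0 * w2 * (q - v[k]));
      if (s <= z[k]) { k--; } else break;
    }
    k++;
    v[k] = q; z[k] = s; z[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    d[q] = w2 * (q - v[k]) * (q - v[k]) + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt(IntegerVector mask, IntegerVector dim,
                      NumericVector spacing) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  long nv = (long)nz * ny * nx;
  const double BIG = 1e30;
  std::vector<double> d(nv);
  for (long i = 0; i < nv; ++i) d[i] = mask[i] ? BIG : 0.0;
  int n[3] = {nz, ny, nx};
  long str[3] = {1, (long)nz, (long)nz * ny};
  for (int ax = 0; ax < 3; ++ax) {
    int len = n[ax];
    if (len == 1) continue;
    double w2 = spacing[ax] * spacing[ax];
    int o1 = (ax == 0) ? 1 : 0;
    int o2 = (ax == 2) ? 1 : 2;
    std::vector<double> f(len), dd(len), z(len + 1);
    std::vector<int> v(len);
    for (int j2 = 0; j2 < n[o2]; ++j2)
      for (int j1 = 0; j1 < n[o1]; ++j1) {
        long base = (long)j1 * str[o1] + (long)j2 * str[o2];
        for (int i = 0; i < len; ++i) f[i] = d[base + (long)i * str[ax]];
        dt1d(f, dd, v, z, len, w2);
        for (int i = 0; i < len; ++i) d[base + (long)i * str[ax]] = dd[i];
      }
  }
  NumericVector out(nv);
  for (long i = 0; i < nv; ++i) out[i] = std::sqrt(d[i]);
  out.attr("dim") = dim;
  return out;
}

// ---------------------------------------------------------------------------
// neighbour offsets for 6- or 26-connectivity
static std::vector<std::array<int,3>> neigh_offsets(int conn) {
  std::vector<std::array<int,3>> off;
  if (conn == 6) {
    off = {{{1,0,0}},{{-1,0,0}},{{0,1,0}},{{0,-1,0}},{{0,0,1}},{{0,0,-1}}};
  } else {
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx)
          if (dz || dy || dx) off.push_back({{dz, dy, dx}});
  }
  return off;
}

// 3D connected-component labelling (BFS, deterministic scan order).
// [[Rcpp::export]]
IntegerVector cpp_label3d(IntegerVector mask, IntegerVector dim, int conn) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  long nv = (long)nz * ny * nx;
  IntegerVector lab(nv, 0);
  lab.attr("dim") = dim;
  auto off = neigh_offsets(conn);
  int cur = 0;
  std::vector<long> stack;
  for (long s = 0; s < nv; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++cur;
    stack.push_back(s);
    lab[s] = cur;
    while (!stack.empty()) {
      long p = stack.back(); stack.pop_back();
      int iz = p % nz, iy = (p / nz) % ny, ix = p / ((long)nz * ny);
      for (auto &o : off) {
        int z = iz + o[0], y = iy + o[1], x = ix + o[2];
        if (z < 0 || z >= nz || y < 0 || y >= ny || x < 0 || x >= nx) continue;
        long q = idx3(z, y, x, nz, ny);
        if (mask[q] && !lab[q]) { lab[q] = cur; stack.push_back(q); }
      }
    }
  }
  return lab;
}

// 2D connected components on a matrix (ny x nx), 4- or 8-connectivity.
// [[Rcpp::export]]
IntegerMatrix cpp_label2d(IntegerMatrix mask, int conn) {
  int ny = mask.nrow(), nx = mask.ncol();
  IntegerMatrix lab(ny, nx);
  std::vector<std::array<int,2>> off;
  if (conn == 4) off = {{{1,0}},{{-1,0}},{{0,1}},{{0,-1}}};
  else for (int dy = -1; dy <= 1; ++dy) for (int dx = -1; dx <= 1; ++dx)
    if (dy || dx) off.push_back({{dy, dx}});
  int cur = 0;
  std::vector<std::pair<int,int>> stack;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      if (!mask(y, x) || lab(y, x)) continue;
      ++cur;
      stack.push_back({y, x}); lab(y, x) = cur;
      while (!stack.empty()) {
        auto p = stack.back(); stack.pop_back();
        for (auto &o : off) {
          int yy = p.first + o[0], xx = p.second + o[1];
          if (yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
          if (mask(yy, xx) && !lab(yy, xx)) { lab(yy, xx) = cur; stack.push_back({yy, xx}); }
        }
      }
    }
  return lab;
}

// ---------------------------------------------------------------------------
// Grayscale morphological reconstruction by dilation (Vincent's hybrid
// algorithm): marker <= mask, dilate marker constrained by mask.
// [[Rcpp::export]]
NumericVector cpp_reconstruct(NumericVector marker, NumericVector mask,
                              IntegerVector dim, int conn) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  long nv = (long)nz * ny * nx;
  std::vector<double> J(marker.begin(), marker.end());
  auto off = neigh_offsets(conn);
  // raster then anti-raster pass
  for (int pass = 0; pass < 2; ++pass) {
    for (long s = 0; s < nv; ++s) {
      long p = (pass == 0) ? s : (nv - 1 - s);
      int iz = p % nz, iy = (p / nz) % ny, ix = p / ((long)nz * ny);
      double m = J[p];
      for (auto &o : off) {
        int z = iz + o[0], y = iy + o[1], x = ix + o[2];
        if (z < 0 || z >= nz || y < 0 || y >= ny || x < 0 || x >= nx) continue;
        long q = idx3(z, y, x, nz, ny);
        // only neighbours already visited in this pass direction
        bool before = (pass == 0) ? (q < p) : (q > p);
        if (before && J[q] > m) m = J[q];
      }
      J[p] = std::min(m, (double)mask[p]);
    }
  }
  // FIFO propagation
  std::queue<long> fifo;
  for (long p = 0; p < nv; ++p) {
    int iz = p % nz, iy = (p / nz) % ny, ix = p / ((long)nz * ny);
    for (auto &o : off) {
      int z = iz + o[0], y = iy + o[1], x = ix + o[2];
      if (z < 0 || z >= nz || y < 0 || y >= ny || x < 0 || x >= nx) continue;
      long q = idx3(z, y, x, nz, ny);
      if (J[q] < J[p] && J[q] < mask[q]) { fifo.push(p); break; }
    }
  }
  while (!fifo.empty()) {
    long p = fifo.front(); fifo.pop();
    int iz = p % nz, iy = (p / nz) % ny, ix = p / ((long)nz * ny);
    for (auto &o : off) {
      int z = iz + o[0], y = iy + o[1], x = ix + o[2];
      if (z < 0 || z >= nz || y < 0 || y >= ny || x < 0 || x >= nx) continue;
      long q = idx3(z, y, x, nz, ny);
      if (J[q] < J[p] && J[q] < mask[q]) {
        J[q] = std::min(J[p], (double)mask[q]);
        fifo.push(q);
      }
    }
  }
  NumericVector out(J.begin(), J.end());
  out.attr("dim") = dim;
  return out;
}

// ---------------------------------------------------------------------------
// Seeded watershed by priority flooding of a height map (flood from high to
// low: used with the distance map so basins grow downhill from maxima).
// Deterministic: ties broken by insertion order.
struct WsEntry {
  double h; long ord; long p; int lab;
};
struct WsCmp {
  bool operator()(const WsEntry &a, const WsEntry &b) const {
    if (a.h != b.h) return a.h < b.h;   // max-heap on height
    return a.ord > b.ord;               // FIFO among equal heights
  }
};

// [[Rcpp::export]]
IntegerVector cpp_watershed(NumericVector height, IntegerVector seeds,
                            IntegerVector mask, IntegerVector dim, int conn) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  long nv = (long)nz * ny * nx;
  IntegerVector lab(nv, 0);
  lab.attr("dim") = dim;
  auto off = neigh_offsets(conn);
  std::priority_queue<WsEntry, std::vector<WsEntry>, WsCmp> pq;
  long ord = 0;
  for (long p = 0; p < nv; ++p)
    if (seeds[p] > 0 && mask[p]) { lab[p] = seeds[p]; }
  for (long p = 0; p < nv; ++p) {
    if (lab[p] == 0) continue;
    pq.push({height[p], ord++, p, lab[p]});
  }
  while (!pq.empty()) {
    WsEntry e = pq.top(); pq.pop();
    int iz = e.p % nz, iy = (e.p / nz) % ny, ix = e.p / ((long)nz * ny);
    for (auto &o : off) {
      int z = iz + o[0], y = iy + o[1], x = ix + o[2];
      if (z < 0 || z >= nz || y < 0 || y >= ny || x < 0 || x >= nx) continue;
      long q = idx3(z, y, x, nz, ny);
      if (!mask[q] || lab[q]) continue;
      lab[q] = e.lab;
      pq.push({height[q], ord++, q, e.lab});
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Fill enclosed background cavities: background connected (6-conn) to the
// array border stays background, everything else becomes foreground.
// [[Rcpp::export]]
IntegerVector cpp_fill_holes(IntegerVector mask, IntegerVector dim) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  long nv = (long)nz * ny * nx;
  std::vector<char> outside(nv, 0);
  std::vector<long> stack;
  auto push_if = [&](int z, int y, int x) {
    long q = idx3(z, y, x, nz, ny);
    if (!mask[q] && !outside[q]) { outside[q] = 1; stack.push_back(q); }
  };
  for (int y = 0; y < ny; ++y) for (int x = 0; x < nx; ++x) {
    push_if(0, y, x); push_if(nz - 1, y, x);
  }
  for (int z = 0; z < nz; ++z) for (int x = 0; x < nx; ++x) {
    push_if(z, 0, x); push_if(z, ny - 1, x);
  }
  for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y) {
    push_if(z, y, 0); push_if(z, y, nx - 1);
  }
  auto off = neigh_offsets(6);
  while (!stack.empty()) {
    long p = stack.back(); stack.pop_back();
    int iz = p % nz, iy = (p / nz) % ny, ix = p / ((long)nz * ny);
    for (auto &o : off) {
      int z = iz + o[0], y = iy + o[1], x = ix + o[2];
      if (z < 0 || z >= nz || y < 0 || y >= ny || x < 0 || x >= nx) continue;
      push_if(z, y, x);
    }
  }
  IntegerVector out(nv);
  for (long p = 0; p < nv; ++p) out[p] = (mask[p] || !outside[p]) ? 1 : 0;
  out.attr("dim") = dim;
  return out;
}

// ---------------------------------------------------------------------------
// Rasterise ellipsoids into a label grid by the analytic membership test at
// voxel centres. centers/semiaxes are n x 3 in (x, y, z) µm; rot is a list of
// 3x3 rotation matrices (local -> world). Overlaps resolved by the smallest
// normalised ellipsoid coordinate (deepest interior wins); exact ties by the
// smaller label.
// [[Rcpp::export]]
IntegerVector cpp_render_labels(NumericMatrix centers, NumericMatrix semiaxes,
                                List rot, IntegerVector labels,
                                IntegerVector dim, NumericVector voxel) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  double vz = voxel[0], vy = voxel[1], vx = voxel[2];
  long nv = (long)nz * ny * nx;
  IntegerVector lab(nv, 0);
  lab.attr("dim") = dim;
  std::vector<double> depth(nv, 1e30);
  int n = centers.nrow();
  for (int c = 0; c < n; ++c) {
    NumericMatrix R = rot[c];
    double cx = centers(c, 0), cy = centers(c, 1), cz = centers(c, 2);
    double a = semiaxes(c, 0), b = semiaxes(c, 1), cc = semiaxes(c, 2);
    double rmax = std::max(a, std::max(b, cc));
    int z0 = std::max(0, (int)std::floor((cz - rmax) / vz - 0.5));
    int z1 = std::min(nz - 1, (int)std::ceil((cz + rmax) / vz - 0.5));
    int y0 = std::max(0, (int)std::floor((cy - rmax) / vy - 0.5));
    int y1 = std::min(ny - 1, (int)std::ceil((cy + rmax) / vy - 0.5));
    int x0 = std::max(0, (int)std::floor((cx - rmax) / vx - 0.5));
    int x1 = std::min(nx - 1, (int)std::ceil((cx + rmax) / vx - 0.5));
    for (int ix = x0; ix <= x1; ++ix) {
      double px = (ix + 0.5) * vx - cx;
      for (int iy = y0; iy <= y1; ++iy) {
        double py = (iy + 0.5) * vy - cy;
        for (int iz = z0; iz <= z1; ++iz) {
          double pz = (iz + 0.5) * vz - cz;
          // local coordinates u = R^T p, then scale by semi-axes
          double ux = (R(0,0) * px + R(1,0) * py + R(2,0) * pz) / a;
          double uy = (R(0,1) * px + R(1,1) * py + R(2,1) * pz) / b;
          double uz = (R(0,2) * px + R(1,2) * py + R(2,2) * pz) / cc;
          double m = ux * ux + uy * uy + uz * uz;
          if (m <= 1.0) {
            long p = idx3(iz, iy, ix, nz, ny);
            if (m < depth[p] || (m == depth[p] && lab[p] > labels[c])) {
              depth[p] = m;
              lab[p] = labels[c];
            }
          }
        }
      }
    }
  }
  return lab;
}
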