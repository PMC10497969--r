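// Conjugate Orthogonal Conjugate Gradient (COCG) solver for the complex
// symmetric admittance-network system arising from the electro-quasistatic
// voxel discretisation. The operator lives on a structured (nz, ny, nx)
// node grid with per-face branch admittances; Dirichlet plates enter
// through an extra diagonal term and the right-hand side.
#include <Rcpp.h>
#include <complex>
#include <vector>
#include <cmath>
using namespace Rcpp;
typedef std::complex<double> cd;

static inline long id3(int iz, int iy, int ix, int nz, int ny) {
  return iz + (long)nz * (iy + (long)ny * ix);
}

struct GridOp {
  int nz, ny, nx;
  const cd *bz, *by, *bx; // branch admittances along z, y, x
  std::vector<cd> diag;

  void build_diag(const cd *dex) {
    long nv = (long)nz * ny * nx;
    diag.assign(nv, cd(0, 0));
    for (long p = 0; p < nv; ++p) diag[p] = dex[p];
    for (int ix = 0; ix < nx; ++ix)
      for (int iy = 0; iy < ny; ++iy)
        for (int iz = 0; iz < nz - 1; ++iz) {
          cd y = bz[iz + (long)(nz - 1) * (iy + (long)ny * ix)];
          diag[id3(iz, iy, ix, nz, ny)] += y;
          diag[id3(iz + 1, iy, ix, nz, ny)] += y;
        }
    for (int ix = 0; ix < nx; ++ix)
      for (int iy = 0; iy < ny - 1; ++iy)
        for (int iz = 0; iz < nz; ++iz) {
          cd y = by[iz + (long)nz * (iy + (long)(ny - 1) * ix)];
          diag[id3(iz, iy, ix, nz, ny)] += y;
          diag[id3(iz, iy + 1, ix, nz, ny)] += y;
        }
    for (int ix = 0; ix < nx - 1; ++ix)
      for (int iy = 0; iy < ny; ++iy)
        for (int iz = 0; iz < nz; ++iz) {
          cd y = bx[iz + (long)nz * (iy + (long)ny * ix)];
          diag[id3(iz, iy, ix, nz, ny)] += y;
          diag[id3(iz, iy, ix + 1, nz, ny)] += y;
        }
  }

  void apply(const cd *x, cd *out) const {
    long nv = (long)nz * ny * nx;
    for (long p = 0; p < nv; ++p) out[p] = diag[p] * x[p];
    for (int ix = 0; ix < nx; ++ix)
      for (int iy = 0; iy < ny; ++iy)
        for (int iz = 0; iz < nz - 1; ++iz) {
          cd y = bz[iz + (long)(nz - 1) * (iy + (long)ny * ix)];
          long p = id3(iz, iy, ix, nz, ny), q = p + 1;
          out[p] -= y * x[q];
          out[q] -= y * x[p];
        }
    for (int ix = 0; ix < nx; ++ix)
      for (int iy = 0; iy < ny - 1; ++iy)
        for (int iz = 0; iz < nz; ++iz) {
          cd y = by[iz + (long)nz * (iy + (long)(ny - 1) * ix)];
          long p = id3(iz, iy, ix, nz, ny), q = p + nz;
          out[p] -= y * x[q];
          out[q] -= y * x[p];
        }
    long snx = (long)nz * ny;
    for (int ix = 0; ix < nx - 1; ++ix)
      for (int iy = 0; iy < ny; ++iy)
        for (int iz = 0; iz < nz; ++iz) {
          cd y = bx[iz + (long)nz * (iy + (long)ny * ix)];
          long p = id3(iz, iy, ix, nz, ny), q = p + snx;
          out[p] -= y * x[q];
          out[q] -= y * x[p];
        }
  }
};

static std::vector<cd> as_cvec(const ComplexVector &v) {
  std::vector<cd> out(v.size());
  for (R_xlen_t i = 0; i < v.size(); ++i) out[i] = cd(v[i].r, v[i].i);
  return out;
}

// [[Rcpp::export]]
ComplexVector cpp_grid_matvec(IntegerVector dim, ComplexVector bz,
                              ComplexVector by, ComplexVector bx,
                              ComplexVector diagextra, ComplexVector x) {
  GridOp op;
  op.nz = dim[0]; op.ny = dim[1]; op.nx = dim[2];
  std::vector<cd> vbz = as_cvec(bz), vby = as_cvec(by), vbx = as_cvec(bx);
  std::vector<cd> vde = as_cvec(diagextra), vx = as_cvec(x);
  op.bz = vbz.data(); op.by = vby.data(); op.bx = vbx.data();
  op.build_diag(vde.data());
  std::vector<cd> out(vx.size());
  op.apply(vx.data(), out.data());
  ComplexVector res(out.size());
  for (size_t i = 0; i < out.size(); ++i) { res[i].r = out[i].real(); res[i].i = out[i].imag(); }
  return res;
}

// [[Rcpp::export]]
List cpp_cocg(IntegerVector dim, ComplexVector bz, ComplexVector by,
              ComplexVector bx, ComplexVector diagextra, ComplexVector rhs,
              double tol, int maxit) {
  GridOp op;
  op.nz = dim[0]; op.ny = dim[1]; op.nx = dim[2];
  std::vector<cd> vbz = as_cvec(bz), vby = as_cvec(by), vbx = as_cvec(bx);
  std::vector<cd> vde = as_cvec(diagextra), b = as_cvec(rhs);
  op.bz = vbz.data(); op.by = vby.data(); op.bx = vbx.data();
  op.build_diag(vde.data());
  long nv = b.size();

  std::vector<cd> x(nv, cd(0, 0)), r(b), z(nv), p(nv), q(nv);
  std::vector<cd> minv(nv);
  for (long i = 0; i < nv; ++i) {
    cd d = op.diag[i];
    minv[i] = (std::abs(d) > 0) ? cd(1, 0) / d : cd(1, 0);
  }
  double bnorm = 0;
  for (long i = 0; i < nv; ++i) bnorm += std::norm(b[i]);
  bnorm = std::sqrt(bnorm);
  if (bnorm == 0) {
    ComplexVector phi(nv);
    for (long i = 0; i < nv; ++i) { phi[i].r = 0; phi[i].i = 0; }
    return List::create(_["phi"] = phi, _["relres"] = 0.0, _["iter"] = 0,
                        _["converged"] = true);
  }
  for (long i = 0; i < nv; ++i) { z[i] = minv[i] * r[i]; p[i] = z[i]; }
  cd rz(0, 0);
  for (long i = 0; i < nv; ++i) rz += r[i] * z[i]; // unconjugated
  double relres = 1.0;
  int it = 0;
  bool ok = false;
  for (it = 1; it <= maxit; ++it) {
    op.apply(p.data(), q.data());
    cd pq(0, 0);
    for (long i = 0; i < nv; ++i) pq += p[i] * q[i];
    if (pq == cd(0, 0)) break;
    cd alpha = rz / pq;
    double rnorm = 0;
    for (long i = 0; i < nv; ++i) {
      x[i] += alpha * p[i];
      r[i] -= alpha * q[i];
      rnorm += std::norm(r[i]);
    }
    relres = std::sqrt(rnorm) / bnorm;
    if (relres <= tol) { ok = true; break; }
    cd rznew(0, 0);
    for (long i = 0; i < nv; ++i) { z[i] = minv[i] * r[i]; rznew += r[i] * z[i]; }
    if (rznew == cd(0, 0)) break;
    cd beta = rznew / rz;
    rz = rznew;
    for (long i = 0; i < nv; ++i) p[i] = z[i] + beta * p[i];
  }
  ComplexVector phi(nv);
  for (long i = 0; i < nv; ++i) { phi[i].r = x[i].real(); phi[i].i = x[i].imag(); }
  return List::create(_["phi"] = phi, _["relres"] = relres, _["iter"] = it,
                      _["converged"] = ok);
}
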