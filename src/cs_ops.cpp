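#include <Rcpp.h>
using namespace Rcpp;

// First-order forward differences along y and z per frame, zero at the
// trailing boundary, stacked as two coefficient channels.
// [[Rcpp::export]]
ComplexVector sfd_cpp(ComplexVector x, IntegerVector dims) {
  const int ny = dims[0], nz = dims[1], nt = dims[2];
  const R_xlen_t N = (R_xlen_t)ny * nz * nt;
  ComplexVector out(2 * N);
  for (R_xlen_t i = 0; i < 2 * N; ++i) { out[i].r = 0.0; out[i].i = 0.0; }
  for (int t = 0; t < nt; ++t) for (int z = 0; z < nz; ++z) {
    const R_xlen_t base = (R_xlen_t)t * ny * nz + (R_xlen_t)z * ny;
    for (int y = 0; y < ny - 1; ++y) {
      out[base + y].r = x[base + y + 1].r - x[base + y].r;
      out[base + y].i = x[base + y + 1].i - x[base + y].i;
    }
    if (z < nz - 1)
      for (int y = 0; y < ny; ++y) {
        out[N + base + y].r = x[base + ny + y].r - x[base + y].r;
        out[N + base + y].i = x[base + ny + y].i - x[base + y].i;
      }
  }
  return out;
}

// Exact transpose of sfd_cpp.
// [[Rcpp::export]]
ComplexVector sfd_adj_cpp(ComplexVector u, IntegerVector dims) {
  const int ny = dims[0], nz = dims[1], nt = dims[2];
  const R_xlen_t N = (R_xlen_t)ny * nz * nt;
  ComplexVector out(N);
  for (R_xlen_t i = 0; i < N; ++i) { out[i].r = 0.0; out[i].i = 0.0; }
  for (int t = 0; t < nt; ++t) for (int z = 0; z < nz; ++z) {
    const R_xlen_t base = (R_xlen_t)t * ny * nz + (R_xlen_t)z * ny;
    for (int y = 0; y < ny - 1; ++y) {
      out[base + y + 1].r += u[base + y].r;  out[base + y + 1].i += u[base + y].i;
      out[base + y].r -= u[base + y].r;      out[base + y].i -= u[base + y].i;
    }
    if (z < nz - 1)
      for (int y = 0; y < ny; ++y) {
        out[base + ny + y].r += u[N + base + y].r;
        out[base + ny + y].i += u[N + base + y].i;
        out[base + y].r -= u[N + base + y].r;
        out[base + y].i -= u[N + base + y].i;
      }
  }
  return out;
}

// Second-order temporal differences at interior frames (third STFD channel).
// [[Rcpp::export]]
ComplexVector tdiff2_cpp(ComplexVector x, IntegerVector dims) {
  const int ny = dims[0], nz = dims[1], nt = dims[2];
  const R_xlen_t P = (R_xlen_t)ny * nz, N = P * nt;
  ComplexVector out(N);
  for (R_xlen_t i = 0; i < N; ++i) { out[i].r = 0.0; out[i].i = 0.0; }
  for (int t = 1; t < nt - 1; ++t)
    for (R_xlen_t p = 0; p < P; ++p) {
      const R_xlen_t c = (R_xlen_t)t * P + p;
      out[c].r = x[c - P].r - 2.0 * x[c].r + x[c + P].r;
      out[c].i = x[c - P].i - 2.0 * x[c].i + x[c + P].i;
    }
  return out;
}

// Exact transpose of tdiff2_cpp (boundary coefficient frames are ignored).
// [[Rcpp::export]]
ComplexVector tdiff2_adj_cpp(ComplexVector u, IntegerVector dims) {
  const int ny = dims[0], nz = dims[1], nt = dims[2];
  const R_xlen_t P = (R_xlen_t)ny * nz, N = P * nt;
  ComplexVector out(N);
  for (R_xlen_t i = 0; i < N; ++i) { out[i].r = 0.0; out[i].i = 0.0; }
  for (int t = 1; t < nt - 1; ++t)
    for (R_xlen_t p = 0; p < P; ++p) {
      const R_xlen_t c = (R_xlen_t)t * P + p;
      out[c - P].r += u[c].r;        out[c - P].i += u[c].i;
      out[c].r -= 2.0 * u[c].r;      out[c].i -= 2.0 * u[c].i;
      out[c + P].r += u[c].r;        out[c + P].i += u[c].i;
    }
  return out;
}

// Pointwise complex magnitude clipping: z <- z * min(1, mu / |z|).
// [[Rcpp::export]]
ComplexVector shrink_ball_cpp(ComplexVector z, double mu) {
  const R_xlen_t n = z.size();
  ComplexVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const double m = std::sqrt(z[i].r * z[i].r + z[i].i * z[i].i);
    if (m > mu && m > 0) {
      const double s = mu / m;
      out[i].r = z[i].r * s; out[i].i = z[i].i * s;
    } else {
      out[i] = z[i];
    }
  }
  return out;
}

// Sum of complex magnitudes (the l1 norm of transform coefficients).
// [[Rcpp::export]]
double l1_norm_cpp(ComplexVector u) {
  double s = 0.0;
  for (R_xlen_t i = 0; i < u.size(); ++i)
    s += std::sqrt(u[i].r * u[i].r + u[i].i * u[i].i);
  return s;
}

// ---- fused projected dual-ascent prox loop ---------------------------------
// Solves min_x 0.5||x - v||^2 + mu ||T x||_1 by `inner` iterations of
// z <- Proj_{|.|<=mu}(z + sigma T(v - T* z)), x = v - T* z, entirely in C++.
// T is SFD (nchan = 2) or STFD (nchan = 3).

static void apply_T(const Rcomplex* x, Rcomplex* u, int ny, int nz, int nt,
                    int nchan) {
  const R_xlen_t P = (R_xlen_t)ny * nz, N = P * nt;
  for (R_xlen_t i = 0; i < (R_xlen_t)nchan * N; ++i) { u[i].r = 0.0; u[i].i = 0.0; }
  for (int t = 0; t < nt; ++t) for (int z = 0; z < nz; ++z) {
    const R_xlen_t base = (R_xlen_t)t * P + (R_xlen_t)z * ny;
    for (int y = 0; y < ny - 1; ++y) {
      u[base + y].r = x[base + y + 1].r - x[base + y].r;
      u[base + y].i = x[base + y + 1].i - x[base + y].i;
    }
    if (z < nz - 1)
      for (int y = 0; y < ny; ++y) {
        u[N + base + y].r = x[base + ny + y].r - x[base + y].r;
        u[N + base + y].i = x[base + ny + y].i - x[base + y].i;
      }
  }
  if (nchan == 3)
    for (int t = 1; t < nt - 1; ++t)
      for (R_xlen_t p = 0; p < P; ++p) {
        const R_xlen_t c = (R_xlen_t)t * P + p;
        u[2 * N + c].r = x[c - P].r - 2.0 * x[c].r + x[c + P].r;
        u[2 * N + c].i = x[c - P].i - 2.0 * x[c].i + x[c + P].i;
      }
}

static void apply_Tt(const Rcomplex* u, Rcomplex* x, int ny, int nz, int nt,
                     int nchan) {
  const R_xlen_t P = (R_xlen_t)ny * nz, N = P * nt;
  for (R_xlen_t i = 0; i < N; ++i) { x[i].r = 0.0; x[i].i = 0.0; }
  for (int t = 0; t < nt; ++t) for (int z = 0; z < nz; ++z) {
    const R_xlen_t base = (R_xlen_t)t * P + (R_xlen_t)z * ny;
    for (int y = 0; y < ny - 1; ++y) {
      x[base + y + 1].r += u[base + y].r;  x[base + y + 1].i += u[base + y].i;
      x[base + y].r -= u[base + y].r;      x[base + y].i -= u[base + y].i;
    }
    if (z < nz - 1)
      for (int y = 0; y < ny; ++y) {
        x[base + ny + y].r += u[N + base + y].r;
        x[base + ny + y].i += u[N + base + y].i;
        x[base + y].r -= u[N + base + y].r;
        x[base + y].i -= u[N + base + y].i;
      }
  }
  if (nchan == 3)
    for (int t = 1; t < nt - 1; ++t)
      for (R_xlen_t p = 0; p < P; ++p) {
        const R_xlen_t c = (R_xlen_t)t * P + p;
        x[c - P].r += u[2 * N + c].r;      x[c - P].i += u[2 * N + c].i;
        x[c].r -= 2.0 * u[2 * N + c].r;    x[c].i -= 2.0 * u[2 * N + c].i;
        x[c + P].r += u[2 * N + c].r;      x[c + P].i += u[2 * N + c].i;
      }
}

// [[Rcpp::export]]
List prox_l1_dual_cpp(ComplexVector v, ComplexVector z0, double mu,
                      double sigma, int inner, IntegerVector dims, int nchan) {
  const int ny = dims[0], nz = dims[1], nt = dims[2];
  const R_xlen_t N = (R_xlen_t)ny * nz * nt, K = (R_xlen_t)nchan * N;
  ComplexVector z(clone(z0));
  ComplexVector x(N);
  std::vector<Rcomplex> tx(K);
  for (int it = 0; it < inner; ++it) {
    apply_Tt(&z[0], &x[0], ny, nz, nt, nchan);
    for (R_xlen_t i = 0; i < N; ++i) {
      x[i].r = v[i].r - x[i].r;
      x[i].i = v[i].i - x[i].i;
    }
    apply_T(&x[0], tx.data(), ny, nz, nt, nchan);
    for (R_xlen_t i = 0; i < K; ++i) {
      double zr = z[i].r + sigma * tx[i].r;
      double zi = z[i].i + sigma * tx[i].i;
      const double m = std::sqrt(zr * zr + zi * zi);
      if (m > mu && m > 0.0) { zr *= mu / m; zi *= mu / m; }
      z[i].r = zr; z[i].i = zi;
    }
  }
  apply_Tt(&z[0], &x[0], ny, nz, nt, nchan);
  for (R_xlen_t i = 0; i < N; ++i) {
    x[i].r = v[i].r - x[i].r;
    x[i].i = v[i].i - x[i].i;
  }
  return List::create(_["x"] = x, _["z"] = z);
}
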