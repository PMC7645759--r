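#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Zero-padded same-size cross-correlation of a 2-channel field with one
// centered odd kernel: out[n] = sum_{d,ch} x[n+d, ch] k[d, ch].
// [[Rcpp::export]]
NumericVector vn_corr_cpp(NumericVector xr, IntegerVector xdim,
                          NumericVector kern, IntegerVector kdim) {
  const int ny = xdim[0], nz = xdim[1], nt = xdim[2];
  const int ky = kdim[0], kz = kdim[1], kt = kdim[2];
  const int cy = (ky - 1) / 2, cz = (kz - 1) / 2, ct = (kt - 1) / 2;
  const int plane = ny * nz, vol = plane * nt;
  NumericVector out(vol);
  for (int ch = 0; ch < 2; ++ch) {
    const double* x = &xr[0] + (size_t)ch * vol;
    for (int it = 0; it < kt; ++it) for (int iz = 0; iz < kz; ++iz)
      for (int iy = 0; iy < ky; ++iy) {
        const double w = kern[iy + ky * (iz + kz * (it + kt * ch))];
        if (w == 0.0) continue;
        const int dy = iy - cy, dz = iz - cz, dt = it - ct;
        const int y0 = std::max(0, -dy), y1 = std::min(ny, ny - dy);
        const int z0 = std::max(0, -dz), z1 = std::min(nz, nz - dz);
        const int t0 = std::max(0, -dt), t1 = std::min(nt, nt - dt);
        for (int t = t0; t < t1; ++t) for (int z = z0; z < z1; ++z) {
          const double* src = x + (size_t)(t + dt) * plane + (size_t)(z + dz) * ny + dy;
          double* dst = &out[0] + (size_t)t * plane + (size_t)z * ny;
          for (int y = y0; y < y1; ++y) dst[y] += w * src[y];
        }
      }
  }
  return out;
}

// Exact transpose of vn_corr_cpp.
// [[Rcpp::export]]
NumericVector vn_corr_t_cpp(NumericVector resp, IntegerVector xdim,
                            NumericVector kern, IntegerVector kdim) {
  const int ny = xdim[0], nz = xdim[1], nt = xdim[2];
  const int ky = kdim[0], kz = kdim[1], kt = kdim[2];
  const int cy = (ky - 1) / 2, cz = (kz - 1) / 2, ct = (kt - 1) / 2;
  const int plane = ny * nz, vol = plane * nt;
  NumericVector out(2 * vol);
  for (int ch = 0; ch < 2; ++ch) {
    double* o = &out[0] + (size_t)ch * vol;
    for (int it = 0; it < kt; ++it) for (int iz = 0; iz < kz; ++iz)
      for (int iy = 0; iy < ky; ++iy) {
        const double w = kern[iy + ky * (iz + kz * (it + kt * ch))];
        if (w == 0.0) continue;
        const int dy = iy - cy, dz = iz - cz, dt = it - ct;
        const int y0 = std::max(0, -dy), y1 = std::min(ny, ny - dy);
        const int z0 = std::max(0, -dz), z1 = std::min(nz, nz - dz);
        const int t0 = std::max(0, -dt), t1 = std::min(nt, nt - dt);
        for (int t = t0; t < t1; ++t) for (int z = z0; z < z1; ++z) {
          const double* src = &resp[0] + (size_t)t * plane + (size_t)z * ny;
          double* dst = o + (size_t)(t + dt) * plane + (size_t)(z + dz) * ny + dy;
          for (int y = y0; y < y1; ++y) dst[y] += w * src[y];
        }
      }
  }
  return out;
}

// Gradient of <up, corr(xr, k)> with respect to the kernel entries.
// [[Rcpp::export]]
NumericVector vn_kernel_grad_cpp(NumericVector xr, IntegerVector xdim,
                                 NumericVector up, IntegerVector kdim) {
  const int ny = xdim[0], nz = xdim[1], nt = xdim[2];
  const int ky = kdim[0], kz = kdim[1], kt = kdim[2];
  const int cy = (ky - 1) / 2, cz = (kz - 1) / 2, ct = (kt - 1) / 2;
  const int plane = ny * nz, vol = plane * nt;
  NumericVector g(ky * kz * kt * 2);
  for (int ch = 0; ch < 2; ++ch) {
    const double* x = &xr[0] + (size_t)ch * vol;
    for (int it = 0; it < kt; ++it) for (int iz = 0; iz < kz; ++iz)
      for (int iy = 0; iy < ky; ++iy) {
        const int dy = iy - cy, dz = iz - cz, dt = it - ct;
        const int y0 = std::max(0, -dy), y1 = std::min(ny, ny - dy);
        const int z0 = std::max(0, -dz), z1 = std::min(nz, nz - dz);
        const int t0 = std::max(0, -dt), t1 = std::min(nt, nt - dt);
        double acc = 0.0;
        for (int t = t0; t < t1; ++t) for (int z = z0; z < z1; ++z) {
          const double* u = &up[0] + (size_t)t * plane + (size_t)z * ny;
          const double* src = x + (size_t)(t + dt) * plane + (size_t)(z + dz) * ny + dy;
          for (int y = y0; y < y1; ++y) acc += u[y] * src[y];
        }
        g[iy + ky * (iz + kz * (it + kt * ch))] = acc;
      }
  }
  return g;
}

// Gaussian RBF basis on evenly spaced knots (spacing sigma), evaluated with a
// window of half-width RBF_WIN knots around the input: contributions beyond
// that are below exp(-18) and are dropped consistently in the forward and
// backward passes, so gradients stay exact for the evaluated function.
static const int RBF_WIN = 6;

// Gaussian radial-basis activation: value only (inputs clamped to the knot range).
// [[Rcpp::export]]
NumericVector rbf_eval_cpp(NumericVector u, NumericVector w, NumericVector knots) {
  const int n = u.size(), J = knots.size();
  const double lo = knots[0], hi = knots[J - 1];
  const double sigma = knots[1] - knots[0];
  std::vector<double> gaussm(RBF_WIN + 1);
  for (int m = 0; m <= RBF_WIN; ++m) gaussm[m] = std::exp(-0.5 * m * m);
  NumericVector val(n);
  for (int i = 0; i < n; ++i) {
    const double uc = u[i] < lo ? lo : (u[i] > hi ? hi : u[i]);
    const double a = (uc - lo) / sigma;           // knot units
    const int j0 = (int)std::lround(a);
    const double delta = a - j0;                  // in [-0.5, 0.5]
    const double g0 = std::exp(-0.5 * delta * delta);
    const double r = std::exp(delta);             // exp(delta*m) = r^m
    double v = 0.0, rp = 1.0, rn = 1.0;
    for (int m = 0; m <= RBF_WIN; ++m) {
      // phi_{j0+m} = g0 * exp(-delta*m) * exp(-m^2/2); phi_{j0-m} symmetric
      const int jp = j0 + m, jn = j0 - m;
      if (jp < J) v += w[jp] * g0 * rp * gaussm[m];
      if (m > 0 && jn >= 0) v += w[jn] * g0 * rn * gaussm[m];
      rp *= r; rn /= r;
    }
    val[i] = v;
  }
  return val;
}

// Backward pass of the activation: value, the input-gradient term
// u_bar = Phi''(u) * a_bar (zero where clamped), and the knot-weight
// gradient gw[j] = sum_i a_bar[i] phi_j(u[i]).
// [[Rcpp::export]]
List rbf_backward_cpp(NumericVector u, NumericVector w, NumericVector knots,
                      NumericVector a_bar) {
  const int n = u.size(), J = knots.size();
  const double lo = knots[0], hi = knots[J - 1];
  const double sigma = knots[1] - knots[0];
  const double invs2 = 1.0 / (sigma * sigma);
  std::vector<double> gaussm(RBF_WIN + 1);
  for (int m = 0; m <= RBF_WIN; ++m) gaussm[m] = std::exp(-0.5 * m * m);
  NumericVector val(n), u_bar(n), gw(J);
  for (int i = 0; i < n; ++i) {
    const bool inside = u[i] > lo && u[i] < hi;
    const double uc = u[i] < lo ? lo : (u[i] > hi ? hi : u[i]);
    const double a = (uc - lo) / sigma;
    const int j0 = (int)std::lround(a);
    const double delta = a - j0;
    const double g0 = std::exp(-0.5 * delta * delta);
    const double r = std::exp(delta);
    const double ab = a_bar[i];
    double v = 0.0, dv = 0.0, rp = 1.0, rn = 1.0;
    for (int m = 0; m <= RBF_WIN; ++m) {
      const int jp = j0 + m, jn = j0 - m;
      if (jp < J) {
        const double phi = g0 * rp * gaussm[m];
        const double d = uc - knots[jp];
        v += w[jp] * phi;
        dv += w[jp] * phi * (-d * invs2);
        gw[jp] += ab * phi;
      }
      if (m > 0 && jn >= 0) {
        const double phi = g0 * rn * gaussm[m];
        const double d = uc - knots[jn];
        v += w[jn] * phi;
        dv += w[jn] * phi * (-d * invs2);
        gw[jn] += ab * phi;
      }
      rp *= r; rn /= r;
    }
    val[i] = v;
    u_bar[i] = inside ? dv * ab : 0.0;
  }
  return List::create(_["value"] = val, _["u_bar"] = u_bar, _["gw"] = gw);
}
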