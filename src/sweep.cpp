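#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Fast-sweeping solver for the eikonal equation |grad u| = 1 on the voxel
// grid, with fixed boundary values at interface voxels. Unsigned distances;
// callers apply the sign. 8 sweep orderings per pass, Godunov upwind update.

static inline double eik_update(double a1, double h1, double a2, double h2,
                                double a3, double h3) {
  // sort the three neighbor values ascending, keeping spacings attached
  if (a1 > a2) { std::swap(a1, a2); std::swap(h1, h2); }
  if (a2 > a3) { std::swap(a2, a3); std::swap(h2, h3); }
  if (a1 > a2) { std::swap(a1, a2); std::swap(h1, h2); }
  double u = a1 + h1;
  if (u <= a2) return u;
  // two-term quadratic: ((u-a1)/h1)^2 + ((u-a2)/h2)^2 = 1
  double w1 = 1.0 / (h1 * h1), w2 = 1.0 / (h2 * h2);
  double A = w1 + w2, B = -2.0 * (a1 * w1 + a2 * w2);
  double C = a1 * a1 * w1 + a2 * a2 * w2 - 1.0;
  double disc = B * B - 4 * A * C;
  if (disc >= 0) {
    u = (-B + std::sqrt(disc)) / (2 * A);
    if (u <= a3) return u;
  }
  double w3 = 1.0 / (h3 * h3);
  A = w1 + w2 + w3;
  B = -2.0 * (a1 * w1 + a2 * w2 + a3 * w3);
  C = a1 * a1 * w1 + a2 * a2 * w2 + a3 * a3 * w3 - 1.0;
  disc = B * B - 4 * A * C;
  if (disc < 0) return a1 + h1;
  return (-B + std::sqrt(disc)) / (2 * A);
}

static const double BIG = 1e30;

// upwind value/spacing for one axis; second-order one-sided difference when
// a monotone second neighbor is available (Zhao's high-order sweeping)
static inline double axis_value(const double *u, R_xlen_t i, R_xlen_t stride,
                                int pos, int n, double h, double &heff) {
  double m1 = pos > 0 ? u[i - stride] : BIG;
  double p1 = pos < n - 1 ? u[i + stride] : BIG;
  double a, a2;
  if (m1 <= p1) {
    a = m1;
    a2 = pos > 1 ? u[i - 2 * stride] : BIG;
  } else {
    a = p1;
    a2 = pos < n - 2 ? u[i + 2 * stride] : BIG;
  }
  if (a < BIG && a2 < BIG && a2 <= a) {
    heff = 2.0 * h / 3.0;
    return (4.0 * a - a2) / 3.0;
  }
  heff = h;
  return a;
}

// [[Rcpp::export]]
NumericVector cpp_fast_sweep(NumericVector seed, LogicalVector fixed,
                             IntegerVector dim, NumericVector spacing,
                             int n_pass = 3) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t nxy = (R_xlen_t)nx * ny;
  R_xlen_t nvox = nxy * nz;
  NumericVector u(nvox);
  for (R_xlen_t i = 0; i < nvox; i++) u[i] = fixed[i] ? seed[i] : BIG;
  double *up = REAL(u);
  double hx = spacing[0], hy = spacing[1], hz = spacing[2];
  double hmax = std::max(hx, std::max(hy, hz));
  for (int pass = 0; pass < n_pass; pass++) {
    for (int sweep = 0; sweep < 8; sweep++) {
      int sx = (sweep & 1) ? -1 : 1;
      int sy = (sweep & 2) ? -1 : 1;
      int sz = (sweep & 4) ? -1 : 1;
      int x0 = sx > 0 ? 0 : nx - 1, x1 = sx > 0 ? nx : -1;
      int y0 = sy > 0 ? 0 : ny - 1, y1 = sy > 0 ? ny : -1;
      int z0 = sz > 0 ? 0 : nz - 1, z1 = sz > 0 ? nz : -1;
      for (int z = z0; z != z1; z += sz)
        for (int y = y0; y != y1; y += sy)
          for (int x = x0; x != x1; x += sx) {
            R_xlen_t i = (R_xlen_t)z * nxy + (R_xlen_t)y * nx + x;
            if (fixed[i]) continue;
            double ex, ey, ez;
            double ax = axis_value(up, i, 1, x, nx, hx, ex);
            double ay = axis_value(up, i, nx, y, ny, hy, ey);
            double az = axis_value(up, i, nxy, z, nz, hz, ez);
            if (ax >= BIG && ay >= BIG && az >= BIG) continue;
            double cand = eik_update(ax, ex, ay, ey, az, ez);
            if (cand < up[i]) up[i] = cand;
          }
    }
  }
  for (R_xlen_t i = 0; i < nvox; i++)
    if (up[i] >= BIG) up[i] = (double)(nx + ny + nz) * hmax;
  return u;
}
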