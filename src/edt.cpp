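#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double EDT_INF = 1e30;

// Felzenszwalb & Huttenlocher lower-envelope distance transform of a sampled
// function f along one axis, with physical sample spacing h. Computes
// d[q] = min_v ( (h*(q-v))^2 + f[v] ).
static void dt1d(const double *f, double *d, int n, double h,
                 std::vector<int> &v, std::vector<double> &z) {
  int k = -1;
  double h2 = h * h;
  for (int q = 0; q < n; q++) {
    if (f[q] >= EDT_INF) continue;
    if (k < 0) {
      k = 0; v[0] = q; z[0] = -EDT_INF; z[1] = EDT_INF;
      continue;
    }
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + h2 * q * q) - (f[p] + h2 * p * p)) / (2.0 * h2 * (q - p));
      if (s <= z[k]) {
        k--;
        if (k < 0) break;
      } else break;
    }
    k++;
    v[k] = q; z[k] = s; z[k + 1] = EDT_INF;
  }
  if (k < 0) { // no finite sample in this line
    for (int q = 0; q < n; q++) d[q] = EDT_INF;
    return;
  }
  int j = 0;
  for (int q = 0; q < n; q++) {
    while (z[j + 1] < q) j++;
    double dq = h * (q - v[j]);
    d[q] = dq * dq + f[v[j]];
  }
}

// Squared Euclidean distance transform of an arbitrary seed-cost volume.
// Seeds carry their (squared) initial cost; non-seeds are +inf (>= 1e30).
// [[Rcpp::export]]
NumericVector cpp_edt_sq(NumericVector f, IntegerVector dim,
                         NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out = clone(f);
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> line(nmax), dline(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // axis x
  for (int kz = 0; kz < nz; kz++)
    for (int ky = 0; ky < ny; ky++) {
      R_xlen_t base = (R_xlen_t)kz * nx * ny + (R_xlen_t)ky * nx;
      for (int i = 0; i < nx; i++) line[i] = out[base + i];
      dt1d(line.data(), dline.data(), nx, spacing[0], v, z);
      for (int i = 0; i < nx; i++) out[base + i] = dline[i];
    }
  // axis y
  for (int kz = 0; kz < nz; kz++)
    for (int kx = 0; kx < nx; kx++) {
      R_xlen_t base = (R_xlen_t)kz * nx * ny + kx;
      for (int i = 0; i < ny; i++) line[i] = out[base + (R_xlen_t)i * nx];
      dt1d(line.data(), dline.data(), ny, spacing[1], v, z);
      for (int i = 0; i < ny; i++) out[base + (R_xlen_t)i * nx] = dline[i];
    }
  // axis z
  R_xlen_t nxy = (R_xlen_t)nx * ny;
  for (int ky = 0; ky < ny; ky++)
    for (int kx = 0; kx < nx; kx++) {
      R_xlen_t base = (R_xlen_t)ky * nx + kx;
      for (int i = 0; i < nz; i++) line[i] = out[base + (R_xlen_t)i * nxy];
      dt1d(line.data(), dline.data(), nz, spacing[2], v, z);
      for (int i = 0; i < nz; i++) out[base + (R_xlen_t)i * nxy] = dline[i];
    }
  return out;
}
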