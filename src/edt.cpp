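#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Felzenszwalb & Huttenlocher lower-envelope distance transform of a sampled
// quadratic, generalised to a physical sample step. `f` holds squared
// distances on entry; `d` receives the transformed squared distances.
static void dt1d(const double* f, double* d, int n, double step,
                 double* z, int* v) {
  if (n == 1) { d[0] = f[0]; return; }
  int k = 0;
  v[0] = 0;
  z[0] = -1e35;
  z[1] = 1e35;
  for (int q = 1; q < n; ++q) {
    double xq = q * step;
    double s = 0.0;
    while (true) {
      double xv = v[k] * step;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * (xq - xv));
      if (s <= z[k]) {
        --k;
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = 1e35;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * step;
    while (z[k + 1] < xq) ++k;
    double dx = xq - v[k] * step;
    d[q] = dx * dx + f[v[k]];
  }
}

// Exact squared Euclidean distance (mm^2) from every voxel to the nearest
// foreground voxel centre, on a grid with per-axis spacing.
// [[Rcpp::export(name = ".edt_sq")]]
NumericVector edt_sq(LogicalVector mask, IntegerVector dim, NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t N = (R_xlen_t)nx * ny * nz;
  if (mask.size() != N) stop("mask length does not match dim");
  NumericVector D(N);
  double* dp = REAL(D);
  const double FAR = 1e30;
  for (R_xlen_t i = 0; i < N; ++i) dp[i] = mask[i] ? 0.0 : FAR;

  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x (stride 1)
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      double* p = dp + (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx;
      dt1d(p, d.data(), nx, spacing[0], z.data(), v.data());
      std::copy(d.begin(), d.begin() + nx, p);
    }
  // pass along y (stride nx)
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      double* base = dp + (R_xlen_t)k * nx * ny + i;
      for (int j = 0; j < ny; ++j) f[j] = base[(R_xlen_t)j * nx];
      dt1d(f.data(), d.data(), ny, spacing[1], z.data(), v.data());
      for (int j = 0; j < ny; ++j) base[(R_xlen_t)j * nx] = d[j];
    }
  // pass along z (stride nx*ny)
  const R_xlen_t sz = (R_xlen_t)nx * ny;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      double* base = dp + (R_xlen_t)j * nx + i;
      for (int k = 0; k < nz; ++k) f[k] = base[k * sz];
      dt1d(f.data(), d.data(), nz, spacing[2], z.data(), v.data());
      for (int k = 0; k < nz; ++k) base[k * sz] = d[k];
    }
  return D;
}
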