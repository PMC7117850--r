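#include <Rcpp.h>
#include <vector>
#include <limits>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// 1D squared-distance transform (lower envelope of parabolas),
// Felzenszwalb & Huttenlocher. f and d have length n; v, z are scratch.
static void dt1d(const double* f, double* d, int n, int* v, double* z) {
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Squared Euclidean distance (voxel units) from every voxel to the nearest
// background (FALSE) voxel centre. mask has dim c(nx, ny, nz).
// border_background: treat out-of-bounds as background one voxel beyond the
// face (implemented by padding); otherwise out-of-bounds is ignored.
// [[Rcpp::export(name = ".edt3d_sq")]]
NumericVector edt3d_sq(LogicalVector mask, IntegerVector dims,
                       bool border_background) {
  const int nx0 = dims[0], ny0 = dims[1], nz0 = dims[2];
  const int pad = border_background ? 1 : 0;
  // a singleton z dimension means a 2D problem: never pad across the plane
  const int padz = (nz0 > 1) ? pad : 0;
  const int nx = nx0 + 2 * pad, ny = ny0 + 2 * pad, nz = nz0 + 2 * padz;
  // large finite sentinel: true infinities create NaNs in the envelope
  // recursion; anything this large is converted back to Inf on output
  const double INF = 1e15;
  std::vector<double> g((size_t)nx * ny * nz, 0.0);

  // 0 at background sites, +inf at foreground
  for (size_t i = 0; i < g.size(); ++i) g[i] = 0.0;
  if (!border_background) {
    for (int z = 0; z < nz0; ++z)
      for (int y = 0; y < ny0; ++y)
        for (int x = 0; x < nx0; ++x) {
          size_t idx = (size_t)x + nx * ((size_t)y + (size_t)ny * z);
          g[idx] = mask[(size_t)x + nx0 * ((size_t)y + (size_t)ny0 * z)] ? INF : 0.0;
        }
  } else {
    for (size_t i = 0; i < g.size(); ++i) g[i] = 0.0; // pad shell = background
    for (int z = 0; z < nz0; ++z)
      for (int y = 0; y < ny0; ++y)
        for (int x = 0; x < nx0; ++x) {
          size_t idx = (size_t)(x + pad) +
                       (size_t)nx * ((size_t)(y + pad) + (size_t)ny * (z + padz));
          g[idx] = mask[(size_t)x + nx0 * ((size_t)y + (size_t)ny0 * z)] ? INF : 0.0;
        }
  }

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), zz(nmax + 1);
  std::vector<int> vv(nmax);

  // pass along x
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      size_t base = (size_t)nx * ((size_t)y + (size_t)ny * z);
      bool any_finite = false;
      for (int x = 0; x < nx; ++x) { f[x] = g[base + x]; if (f[x] < INF) any_finite = true; }
      if (!any_finite) continue; // whole line foreground, stays +inf
      dt1d(f.data(), d.data(), nx, vv.data(), zz.data());
      for (int x = 0; x < nx; ++x) g[base + x] = d[x];
    }
  // pass along y
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      bool any_finite = false;
      for (int y = 0; y < ny; ++y) {
        f[y] = g[(size_t)x + nx * ((size_t)y + (size_t)ny * z)];
        if (f[y] < INF) any_finite = true;
      }
      if (!any_finite) continue;
      dt1d(f.data(), d.data(), ny, vv.data(), zz.data());
      for (int y = 0; y < ny; ++y)
        g[(size_t)x + nx * ((size_t)y + (size_t)ny * z)] = d[y];
    }
  // pass along z
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      bool any_finite = false;
      for (int z = 0; z < nz; ++z) {
        f[z] = g[(size_t)x + nx * ((size_t)y + (size_t)ny * z)];
        if (f[z] < INF) any_finite = true;
      }
      if (!any_finite) continue;
      dt1d(f.data(), d.data(), nz, vv.data(), zz.data());
      for (int z = 0; z < nz; ++z)
        g[(size_t)x + nx * ((size_t)y + (size_t)ny * z)] = d[z];
    }

  NumericVector out((R_xlen_t)nx0 * ny0 * nz0);
  for (int z = 0; z < nz0; ++z)
    for (int y = 0; y < ny0; ++y)
      for (int x = 0; x < nx0; ++x) {
        size_t src = (size_t)(x + pad) +
                     (size_t)nx * ((size_t)(y + pad) + (size_t)ny * (z + padz));
        double v = g[src];
        out[(size_t)x + nx0 * ((size_t)y + (size_t)ny0 * z)] =
          (v >= 1e14) ? std::numeric_limits<double>::infinity() : v;
      }
  out.attr("dim") = dims;
  return out;
}
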