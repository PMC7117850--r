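#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Local thickness by inscribed-sphere painting. rho[i] is the radius
// (voxel units, centre-to-boundary-surface) of the largest ball centred at
// voxel i that stays inside the foreground; rho <= 0 marks background.
// Every foreground voxel receives 2 * max{ rho(q) : ||p - q|| <= rho(q) }.
// Centres are processed in decreasing rho so each voxel keeps the largest
// covering sphere's diameter; result is exact for the stated definition.
// [[Rcpp::export(name = ".paint_thickness")]]
NumericVector paint_thickness(NumericVector rho, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t n = (size_t)nx * ny * nz;

  std::vector<size_t> centres;
  centres.reserve(n / 4);
  for (size_t i = 0; i < n; ++i)
    if (rho[i] > 0) centres.push_back(i);

  std::stable_sort(centres.begin(), centres.end(),
                   [&](size_t a, size_t b) { return rho[a] > rho[b]; });

  NumericVector th(n);
  for (size_t ci = 0; ci < centres.size(); ++ci) {
    size_t c = centres[ci];
    double r = rho[c];
    double r2 = r * r;
    int cx = (int)(c % nx);
    int cy = (int)((c / nx) % ny);
    int cz = (int)(c / ((size_t)nx * ny));
    int ir = (int)std::floor(r);
    double diam = 2.0 * r;
    int zlo = std::max(0, cz - ir), zhi = std::min(nz - 1, cz + ir);
    for (int z = zlo; z <= zhi; ++z) {
      double dz2 = (double)(z - cz) * (z - cz);
      int ylo = std::max(0, cy - ir), yhi = std::min(ny - 1, cy + ir);
      for (int y = ylo; y <= yhi; ++y) {
        double dyz2 = dz2 + (double)(y - cy) * (y - cy);
        if (dyz2 > r2) continue;
        int xr = (int)std::floor(std::sqrt(r2 - dyz2));
        int xlo = std::max(0, cx - xr), xhi = std::min(nx - 1, cx + xr);
        size_t base = (size_t)nx * ((size_t)y + (size_t)ny * z);
        for (int x = xlo; x <= xhi; ++x) {
          size_t p = base + x;
          if (th[p] < diam) th[p] = diam;
        }
      }
    }
  }
  th.attr("dim") = dims;
  return th;
}
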