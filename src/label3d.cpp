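#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 3D connected-component labelling (6 or 26 connectivity) by breadth-first
// search in raster order, so label ids increase with the component's first
// (lowest linear index) voxel.
// [[Rcpp::export(name = ".label3d")]]
IntegerVector label3d(LogicalVector mask, IntegerVector dims, int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t n = (size_t)nx * ny * nz;
  IntegerVector lab(n); // zero-initialised

  std::vector<int> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manhattan = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manhattan != 1) continue;
        offs.push_back(dx); offs.push_back(dy); offs.push_back(dz);
      }
  const int no = (int)offs.size() / 3;

  std::vector<size_t> queue;
  int next = 0;
  for (size_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    queue.clear();
    queue.push_back(s);
    size_t head = 0;
    while (head < queue.size()) {
      size_t cur = queue[head++];
      int x = (int)(cur % nx);
      int y = (int)((cur / nx) % ny);
      int z = (int)(cur / ((size_t)nx * ny));
      for (int k = 0; k < no; ++k) {
        int xx = x + offs[3 * k], yy = y + offs[3 * k + 1], zz = z + offs[3 * k + 2];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
        size_t q = (size_t)xx + nx * ((size_t)yy + (size_t)ny * zz);
        if (mask[q] && lab[q] == 0) { lab[q] = next; queue.push_back(q); }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}
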