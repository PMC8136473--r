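#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 3D connected-component labelling of a logical array by iterative flood
// fill. Connectivity 6 (faces), 18 (faces+edges) or 26 (full neighbourhood).
// Labels are dense from 1 in first-encounter (column-major scan) order;
// background is 0.
// [[Rcpp::export(name = ".label3d_cpp")]]
IntegerVector label3d_cpp(LogicalVector mask, IntegerVector dims,
                          int connectivity) {
  if (dims.size() != 3) stop("mask must have 3 dimensions");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");

  // neighbour offsets for the requested connectivity
  std::vector<int> dxs, dys, dzs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        dxs.push_back(dx); dys.push_back(dy); dzs.push_back(dz);
      }
  const int nnb = (int)dxs.size();

  IntegerVector lab(n, 0);
  int cur = 0;
  std::vector<R_xlen_t> stack;
  const R_xlen_t sxy = (R_xlen_t)nx * ny;

  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++cur;
    lab[i] = cur;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t v = stack.back(); stack.pop_back();
      int z = (int)(v / sxy);
      R_xlen_t r = v - (R_xlen_t)z * sxy;
      int y = (int)(r / nx);
      int x = (int)(r - (R_xlen_t)y * nx);
      for (int k = 0; k < nnb; ++k) {
        int xx = x + dxs[k], yy = y + dys[k], zz = z + dzs[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        R_xlen_t w = (R_xlen_t)zz * sxy + (R_xlen_t)yy * nx + xx;
        if (mask[w] && lab[w] == 0) {
          lab[w] = cur;
          stack.push_back(w);
        }
      }
    }
  }
  lab.attr("dim") = dims;
  lab.attr("n_components") = cur;
  return lab;
}
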