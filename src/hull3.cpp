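#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Volume of the 3D convex hull of a point cloud, by incremental insertion
// (quickhull-style visibility/horizon update without conflict lists).
// Intended for the modest point sets produced by reducing a voxel
// component to its axis-line-extreme cube corners; degenerate (flat or
// collinear) inputs return volume 0.

namespace {

struct Face {
  int a, b, c;       // vertex indices, outward orientation
  double nx, ny, nz; // outward normal (not normalised)
  double off;        // plane offset: n . x = off for x on the plane
  bool alive;
};

inline void face_plane(Face &f, const std::vector<double> &px,
                       const std::vector<double> &py,
                       const std::vector<double> &pz,
                       double ox, double oy, double oz) {
  double ux = px[f.b] - px[f.a], uy = py[f.b] - py[f.a], uz = pz[f.b] - pz[f.a];
  double vx = px[f.c] - px[f.a], vy = py[f.c] - py[f.a], vz = pz[f.c] - pz[f.a];
  f.nx = uy * vz - uz * vy;
  f.ny = uz * vx - ux * vz;
  f.nz = ux * vy - uy * vx;
  f.off = f.nx * px[f.a] + f.ny * py[f.a] + f.nz * pz[f.a];
  // orient away from the interior point o
  if (f.nx * ox + f.ny * oy + f.nz * oz > f.off) {
    std::swap(f.b, f.c);
    f.nx = -f.nx; f.ny = -f.ny; f.nz = -f.nz; f.off = -f.off;
  }
}

} // namespace

// [[Rcpp::export(name = ".hull_volume_cpp")]]
double hull_volume_cpp(NumericMatrix pts) {
  const int n = pts.nrow();
  if (pts.ncol() != 3) stop("pts must have 3 columns");
  if (n < 4) return 0.0;
  std::vector<double> px(n), py(n), pz(n);
  for (int i = 0; i < n; ++i) { px[i] = pts(i, 0); py[i] = pts(i, 1); pz[i] = pts(i, 2); }

  // scale-aware tolerance
  double span = 0.0;
  for (int d = 0; d < 3; ++d) {
    double lo = pts(0, d), hi = pts(0, d);
    for (int i = 1; i < n; ++i) { lo = std::min(lo, pts(i, d)); hi = std::max(hi, pts(i, d)); }
    span = std::max(span, hi - lo);
  }
  if (span <= 0.0) return 0.0;
  const double eps = 1e-9 * span * span; // compared against n . x - off (area * distance)

  // initial simplex: two extreme points in x, then farthest from the line,
  // then farthest from the plane
  int i0 = 0, i1 = 0;
  for (int i = 1; i < n; ++i) {
    if (px[i] < px[i0]) i0 = i;
    if (px[i] > px[i1]) i1 = i;
  }
  if (i0 == i1) { i1 = (i0 == 0) ? 1 : 0; }
  double ex = px[i1] - px[i0], ey = py[i1] - py[i0], ez = pz[i1] - pz[i0];
  int i2 = -1; double best = 0.0;
  for (int i = 0; i < n; ++i) {
    double wx = px[i] - px[i0], wy = py[i] - py[i0], wz = pz[i] - pz[i0];
    double cxx = ey * wz - ez * wy, cyy = ez * wx - ex * wz, czz = ex * wy - ey * wx;
    double d2 = cxx * cxx + cyy * cyy + czz * czz;
    if (d2 > best) { best = d2; i2 = i; }
  }
  if (i2 < 0 || best <= 0.0) return 0.0; // collinear
  double ux = px[i2] - px[i0], uy = py[i2] - py[i0], uz = pz[i2] - pz[i0];
  double nx0 = ey * uz - ez * uy, ny0 = ez * ux - ex * uz, nz0 = ex * uy - ey * ux;
  int i3 = -1; best = 0.0;
  for (int i = 0; i < n; ++i) {
    double d = std::abs(nx0 * (px[i] - px[i0]) + ny0 * (py[i] - py[i0]) +
                        nz0 * (pz[i] - pz[i0]));
    if (d > best) { best = d; i3 = i; }
  }
  if (i3 < 0 || best <= eps) return 0.0; // coplanar

  double ox = (px[i0] + px[i1] + px[i2] + px[i3]) / 4.0;
  double oy = (py[i0] + py[i1] + py[i2] + py[i3]) / 4.0;
  double oz = (pz[i0] + pz[i1] + pz[i2] + pz[i3]) / 4.0;

  std::vector<Face> faces;
  faces.reserve(128);
  int init[4][3] = {{i0, i1, i2}, {i0, i1, i3}, {i0, i2, i3}, {i1, i2, i3}};
  for (int k = 0; k < 4; ++k) {
    Face f; f.a = init[k][0]; f.b = init[k][1]; f.c = init[k][2]; f.alive = true;
    face_plane(f, px, py, pz, ox, oy, oz);
    faces.push_back(f);
  }

  std::vector<int> visible;
  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1 || i == i2 || i == i3) continue;
    visible.clear();
    for (int k = 0; k < (int)faces.size(); ++k) {
      if (!faces[k].alive) continue;
      double d = faces[k].nx * px[i] + faces[k].ny * py[i] + faces[k].nz * pz[i] -
                 faces[k].off;
      if (d > eps) visible.push_back(k);
    }
    if (visible.empty()) continue;
    // horizon: directed edges of visible faces whose reverse is not visible
    std::vector<std::pair<int, int> > edges;
    for (size_t v = 0; v < visible.size(); ++v) {
      const Face &f = faces[visible[v]];
      edges.push_back(std::make_pair(f.a, f.b));
      edges.push_back(std::make_pair(f.b, f.c));
      edges.push_back(std::make_pair(f.c, f.a));
    }
    for (size_t v = 0; v < visible.size(); ++v) faces[visible[v]].alive = false;
    for (size_t e = 0; e < edges.size(); ++e) {
      bool horizon = true;
      for (size_t e2 = 0; e2 < edges.size(); ++e2) {
        if (edges[e2].first == edges[e].second &&
            edges[e2].second == edges[e].first) { horizon = false; break; }
      }
      if (!horizon) continue;
      Face f; f.a = edges[e].first; f.b = edges[e].second; f.c = i; f.alive = true;
      face_plane(f, px, py, pz, ox, oy, oz);
      faces.push_back(f);
    }
  }

  // volume as the sum of signed tetrahedra (interior point, face)
  double vol6 = 0.0;
  for (size_t k = 0; k < faces.size(); ++k) {
    if (!faces[k].alive) continue;
    const Face &f = faces[k];
    double ax = px[f.a] - ox, ay = py[f.a] - oy, az = pz[f.a] - oz;
    double bx = px[f.b] - ox, by = py[f.b] - oy, bz = pz[f.b] - oz;
    double cx = px[f.c] - ox, cy = py[f.c] - oy, cz = pz[f.c] - oz;
    vol6 += ax * (by * cz - bz * cy) - ay * (bx * cz - bz * cx) +
            az * (bx * cy - by * cx);
  }
  return std::abs(vol6) / 6.0;
}
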