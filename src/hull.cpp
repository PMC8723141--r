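#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>
using namespace Rcpp;

// Randomized-order incremental 3-D convex hull, volume only.
// Faces are kept outward-oriented; a point is added by removing the faces it
// sees and stitching new faces along the horizon. O(n * f) overall, which is
// ample at desk scale (n up to ~1e4).

namespace {

struct Face {
  int a, b, c;      // vertex indices, outward orientation (counter-clockwise
                    // seen from outside)
  double nx, ny, nz, off;  // outward normal and plane offset n.x = off
  bool alive;
};

inline void plane(const NumericMatrix& P, Face& f) {
  double ux = P(f.b,0) - P(f.a,0), uy = P(f.b,1) - P(f.a,1), uz = P(f.b,2) - P(f.a,2);
  double vx = P(f.c,0) - P(f.a,0), vy = P(f.c,1) - P(f.a,1), vz = P(f.c,2) - P(f.a,2);
  f.nx = uy*vz - uz*vy;
  f.ny = uz*vx - ux*vz;
  f.nz = ux*vy - uy*vx;
  f.off = f.nx*P(f.a,0) + f.ny*P(f.a,1) + f.nz*P(f.a,2);
}

inline double sdist(const NumericMatrix& P, const Face& f, int i) {
  return f.nx*P(i,0) + f.ny*P(i,1) + f.nz*P(i,2) - f.off;
}

} // namespace

// [[Rcpp::export]]
double cpp_convex_hull_volume(NumericMatrix pts) {
  const int n = pts.nrow();
  if (n < 4) stop("convex hull volume needs at least 4 points");

  // scale-aware tolerance
  double scale = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < 3; ++j) scale = std::max(scale, std::fabs(pts(i,j)));
  if (scale == 0.0) scale = 1.0;
  const double eps = 1e-10 * scale * scale;  // normals scale as length^2

  // initial tetrahedron: furthest-point heuristics
  int i0 = 0, i1 = -1;
  double best = -1.0;
  for (int i = 1; i < n; ++i) {
    double d = 0;
    for (int j = 0; j < 3; ++j) { double t = pts(i,j) - pts(i0,j); d += t*t; }
    if (d > best) { best = d; i1 = i; }
  }
  if (best <= 0) stop("degenerate point set: all points coincide");
  // furthest from line i0-i1
  int i2 = -1; best = -1.0;
  double ax = pts(i1,0)-pts(i0,0), ay = pts(i1,1)-pts(i0,1), az = pts(i1,2)-pts(i0,2);
  for (int i = 0; i < n; ++i) {
    double bx = pts(i,0)-pts(i0,0), by = pts(i,1)-pts(i0,1), bz = pts(i,2)-pts(i0,2);
    double cx = ay*bz-az*by, cy = az*bx-ax*bz, cz = ax*by-ay*bx;
    double d = cx*cx + cy*cy + cz*cz;
    if (d > best) { best = d; i2 = i; }
  }
  if (best <= eps*eps) stop("degenerate point set: all points collinear");
  // furthest from plane i0-i1-i2
  Face f0{i0, i1, i2, 0,0,0,0, true};
  plane(pts, f0);
  int i3 = -1; best = 0.0;
  for (int i = 0; i < n; ++i) {
    double d = std::fabs(sdist(pts, f0, i));
    if (d > best) { best = d; i3 = i; }
  }
  if (best <= eps) stop("degenerate point set: all points coplanar");

  // interior reference point (centroid of the tetrahedron)
  double ox = (pts(i0,0)+pts(i1,0)+pts(i2,0)+pts(i3,0))/4.0;
  double oy = (pts(i0,1)+pts(i1,1)+pts(i2,1)+pts(i3,1))/4.0;
  double oz = (pts(i0,2)+pts(i1,2)+pts(i2,2)+pts(i3,2))/4.0;

  std::vector<Face> faces;
  auto addFace = [&](int a, int b, int c) {
    Face f{a, b, c, 0,0,0,0, true};
    plane(pts, f);
    // orient outward relative to interior point
    if (f.nx*ox + f.ny*oy + f.nz*oz - f.off > 0) {
      std::swap(f.b, f.c);
      plane(pts, f);
    }
    faces.push_back(f);
  };
  addFace(i0, i1, i2);
  addFace(i0, i1, i3);
  addFace(i0, i2, i3);
  addFace(i1, i2, i3);

  for (int p = 0; p < n; ++p) {
    if (p == i0 || p == i1 || p == i2 || p == i3) continue;
    // visible faces
    std::vector<int> vis;
    for (size_t k = 0; k < faces.size(); ++k)
      if (faces[k].alive && sdist(pts, faces[k], p) > eps) vis.push_back((int)k);
    if (vis.empty()) continue;  // inside current hull
    // horizon: edges of visible faces not shared with another visible face
    std::map<std::pair<int,int>, int> edgeCount;
    auto note = [&](int u, int v) {
      std::pair<int,int> key = u < v ? std::make_pair(u,v) : std::make_pair(v,u);
      edgeCount[key]++;
    };
    for (int k : vis) {
      note(faces[k].a, faces[k].b);
      note(faces[k].b, faces[k].c);
      note(faces[k].c, faces[k].a);
    }
    std::vector<std::pair<int,int>> horizon;  // directed as in visible face
    for (int k : vis) {
      const Face& f = faces[k];
      int e[3][2] = {{f.a,f.b},{f.b,f.c},{f.c,f.a}};
      for (auto& ed : e) {
        std::pair<int,int> key = ed[0] < ed[1] ? std::make_pair(ed[0],ed[1])
                                               : std::make_pair(ed[1],ed[0]);
        if (edgeCount[key] == 1) horizon.push_back({ed[0], ed[1]});
      }
    }
    for (int k : vis) faces[k].alive = false;
    // new faces keep the directed horizon edge so outward orientation is
    // inherited from the removed face
    for (auto& ed : horizon) {
      Face f{ed.first, ed.second, p, 0,0,0,0, true};
      plane(pts, f);
      faces.push_back(f);
    }
    // compact occasionally to bound memory
    if (faces.size() > 4096) {
      std::vector<Face> keep;
      keep.reserve(faces.size());
      for (auto& f : faces) if (f.alive) keep.push_back(f);
      faces.swap(keep);
    }
  }

  // volume by signed tetrahedra against the interior point
  double vol6 = 0.0;
  for (auto& f : faces) {
    if (!f.alive) continue;
    double ax_ = pts(f.a,0)-ox, ay_ = pts(f.a,1)-oy, az_ = pts(f.a,2)-oz;
    double bx_ = pts(f.b,0)-ox, by_ = pts(f.b,1)-oy, bz_ = pts(f.b,2)-oz;
    double cx_ = pts(f.c,0)-ox, cy_ = pts(f.c,1)-oy, cz_ = pts(f.c,2)-oz;
    vol6 += ax_*(by_*cz_ - bz_*cy_) - ay_*(bx_*cz_ - bz_*cx_) + az_*(bx_*cy_ - by_*cx_);
  }
  return vol6 / 6.0;
}
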