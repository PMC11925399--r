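// Incremental 3D convex hull, used to build spherical Delaunay/Voronoi
// tessellations for shell generation.  Points are assumed to be in general
// position (seeded random directions on a sphere); O(n^2) is fine at the
// mesh sizes used here (<= a few thousand sites).
#include <Rcpp.h>
#include <vector>
#include <set>
#include <utility>
#include <cmath>
using namespace Rcpp;

namespace {

struct Vec3 {
  double x, y, z;
};

inline Vec3 sub(const Vec3& a, const Vec3& b) {
  return Vec3{a.x - b.x, a.y - b.y, a.z - b.z};
}
inline Vec3 cross(const Vec3& a, const Vec3& b) {
  return Vec3{a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z,
              a.x * b.y - a.y * b.x};
}
inline double dot(const Vec3& a, const Vec3& b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}

// signed volume of tetrahedron (a,b,c,d): positive if d on the side of
// the normal of (a,b,c)
inline double orient(const Vec3& a, const Vec3& b, const Vec3& c,
                     const Vec3& d) {
  return dot(cross(sub(b, a), sub(c, a)), sub(d, a));
}

struct Face {
  int a, b, c;
  bool alive;
};

}  // namespace

// [[Rcpp::export]]
IntegerMatrix hull_triangles_cpp(NumericMatrix pts) {
  const int n = pts.nrow();
  if (n < 4) stop("convex hull needs at least 4 points");
  std::vector<Vec3> p(n);
  for (int i = 0; i < n; ++i) p[i] = Vec3{pts(i, 0), pts(i, 1), pts(i, 2)};

  const double eps = 1e-10;

  // initial simplex: i0 arbitrary, i1 far from i0, i2 far from line,
  // i3 far from plane
  int i0 = 0, i1 = -1, i2 = -1, i3 = -1;
  double best = -1.0;
  for (int i = 1; i < n; ++i) {
    Vec3 d = sub(p[i], p[i0]);
    double v = dot(d, d);
    if (v > best) { best = v; i1 = i; }
  }
  best = -1.0;
  Vec3 e01 = sub(p[i1], p[i0]);
  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1) continue;
    Vec3 c = cross(e01, sub(p[i], p[i0]));
    double v = dot(c, c);
    if (v > best) { best = v; i2 = i; }
  }
  if (best < eps) stop("degenerate point set (collinear)");
  best = -1.0;
  double sgn = 0.0;
  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1 || i == i2) continue;
    double v = orient(p[i0], p[i1], p[i2], p[i]);
    if (std::fabs(v) > best) { best = std::fabs(v); i3 = i; sgn = v; }
  }
  if (best < eps) stop("degenerate point set (coplanar)");
  if (sgn > 0) std::swap(i1, i2);  // make i3 lie below face (i0,i1,i2)

  std::vector<Face> faces;
  faces.push_back(Face{i0, i1, i2, true});
  faces.push_back(Face{i0, i2, i3, true});
  faces.push_back(Face{i2, i1, i3, true});
  faces.push_back(Face{i1, i0, i3, true});

  std::vector<bool> used(n, false);
  used[i0] = used[i1] = used[i2] = used[i3] = true;

  for (int ip = 0; ip < n; ++ip) {
    if (used[ip]) continue;
    used[ip] = true;
    // visible faces
    std::vector<int> vis;
    for (size_t f = 0; f < faces.size(); ++f) {
      if (!faces[f].alive) continue;
      if (orient(p[faces[f].a], p[faces[f].b], p[faces[f].c], p[ip]) > eps)
        vis.push_back((int)f);
    }
    if (vis.empty()) continue;  // inside current hull
    // horizon: directed edges of visible faces whose reverse is not
    // a directed edge of another visible face
    std::set<std::pair<int, int> > edges;
    for (size_t k = 0; k < vis.size(); ++k) {
      const Face& f = faces[vis[k]];
      edges.insert(std::make_pair(f.a, f.b));
      edges.insert(std::make_pair(f.b, f.c));
      edges.insert(std::make_pair(f.c, f.a));
    }
    for (size_t k = 0; k < vis.size(); ++k) faces[vis[k]].alive = false;
    for (std::set<std::pair<int, int> >::const_iterator it = edges.begin();
         it != edges.end(); ++it) {
      if (edges.count(std::make_pair(it->second, it->first))) continue;
      faces.push_back(Face{it->first, it->second, ip, true});
    }
  }

  int nf = 0;
  for (size_t f = 0; f < faces.size(); ++f)
    if (faces[f].alive) ++nf;
  IntegerMatrix out(nf, 3);
  int r = 0;
  for (size_t f = 0; f < faces.size(); ++f) {
    if (!faces[f].alive) continue;
    out(r, 0) = faces[f].a;
    out(r, 1) = faces[f].b;
    out(r, 2) = faces[f].c;
    ++r;
  }
  return out;
}
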