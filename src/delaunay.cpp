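// Incremental Bowyer-Watson Delaunay tetrahedralization in 3D with an
// infinite vertex.
//
// The triangulation is initialized from four input points in general
// position (one finite tetrahedron plus four infinite tetrahedra standing
// for its hull facets).  Finite tetrahedra cache their circumsphere; the
// conflict test compares squared distances with a small relative slack so
// numerically cospherical points count as conflicting.  Infinite tetrahedra
// correspond to convex-hull facets; their conflict test is the limit of the
// circumsphere test as the fourth vertex goes to infinity: the new point
// conflicts when it lies strictly outside the facet plane, or on the plane
// and inside the facet's circumcircle.  Exactly cospherical or degenerate
// inputs are the caller's responsibility (jitter-and-retry rule).

#include <Rcpp.h>
#include <array>
#include <map>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

namespace {

typedef std::array<double, 3> P3;

const int INF = -1;

struct Tet {
  int v[4];         // sorted vertex indices, INF first if present
  int face[3];      // for infinite tets: finite face oriented with the
                    // triangulation interior on the negative side
  double cc[3];
  double r2;        // +inf marks a degenerate (always-conflicting) tet
  bool infinite;
  bool alive;
};

double orient3d(const P3& a, const P3& b, const P3& c, const P3& d) {
  double adx = a[0] - d[0], ady = a[1] - d[1], adz = a[2] - d[2];
  double bdx = b[0] - d[0], bdy = b[1] - d[1], bdz = b[2] - d[2];
  double cdx = c[0] - d[0], cdy = c[1] - d[1], cdz = c[2] - d[2];
  return adx * (bdy * cdz - bdz * cdy)
       - ady * (bdx * cdz - bdz * cdx)
       + adz * (bdx * cdy - bdy * cdx);
}

bool circumsphere(const P3& a, const P3& b, const P3& c, const P3& d,
                  double cc[3], double& r2) {
  double A[3][3], rhs[3];
  const P3* rest[3] = {&b, &c, &d};
  for (int i = 0; i < 3; ++i) {
    const P3& p = *rest[i];
    rhs[i] = 0.0;
    for (int j = 0; j < 3; ++j) {
      A[i][j] = 2.0 * (p[j] - a[j]);
      rhs[i] += p[j] * p[j] - a[j] * a[j];
    }
  }
  double det = A[0][0] * (A[1][1] * A[2][2] - A[1][2] * A[2][1])
             - A[0][1] * (A[1][0] * A[2][2] - A[1][2] * A[2][0])
             + A[0][2] * (A[1][0] * A[2][1] - A[1][1] * A[2][0]);
  double scale = 0.0;
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j)
      scale = std::max(scale, std::fabs(A[i][j]));
  if (std::fabs(det) < 1e-12 * scale * scale * scale + 1e-300) return false;
  double inv[3][3];
  inv[0][0] =  (A[1][1] * A[2][2] - A[1][2] * A[2][1]) / det;
  inv[0][1] = -(A[0][1] * A[2][2] - A[0][2] * A[2][1]) / det;
  inv[0][2] =  (A[0][1] * A[1][2] - A[0][2] * A[1][1]) / det;
  inv[1][0] = -(A[1][0] * A[2][2] - A[1][2] * A[2][0]) / det;
  inv[1][1] =  (A[0][0] * A[2][2] - A[0][2] * A[2][0]) / det;
  inv[1][2] = -(A[0][0] * A[1][2] - A[0][2] * A[1][0]) / det;
  inv[2][0] =  (A[1][0] * A[2][1] - A[1][1] * A[2][0]) / det;
  inv[2][1] = -(A[0][0] * A[2][1] - A[0][1] * A[2][0]) / det;
  inv[2][2] =  (A[0][0] * A[1][1] - A[0][1] * A[1][0]) / det;
  for (int i = 0; i < 3; ++i)
    cc[i] = inv[i][0] * rhs[0] + inv[i][1] * rhs[1] + inv[i][2] * rhs[2];
  r2 = 0.0;
  for (int j = 0; j < 3; ++j) r2 += (cc[j] - a[j]) * (cc[j] - a[j]);
  return true;
}

// circumcircle of a triangle embedded in 3D
bool circumcircle3d(const P3& a, const P3& b, const P3& c,
                    double cc[3], double& r2) {
  double ab[3], ac[3];
  for (int j = 0; j < 3; ++j) { ab[j] = b[j] - a[j]; ac[j] = c[j] - a[j]; }
  double abab = 0, acac = 0, abac = 0;
  for (int j = 0; j < 3; ++j) {
    abab += ab[j] * ab[j];
    acac += ac[j] * ac[j];
    abac += ab[j] * ac[j];
  }
  // solve [abab abac; abac acac] [s t]' = [abab/2 acac/2]
  double d2 = abab * acac - abac * abac;
  if (std::fabs(d2) < 1e-14 * abab * acac + 1e-300) return false;
  double rhs0 = abab / 2.0, rhs1 = acac / 2.0;
  double s = (rhs0 * acac - rhs1 * abac) / d2;
  double t = (rhs1 * abab - rhs0 * abac) / d2;
  r2 = 0.0;
  for (int j = 0; j < 3; ++j) {
    cc[j] = a[j] + s * ab[j] + t * ac[j];
    r2 += (cc[j] - a[j]) * (cc[j] - a[j]);
  }
  return true;
}

struct Builder {
  const std::vector<P3>& pts;
  std::vector<Tet> tets;
  double orient_tol;

  explicit Builder(const std::vector<P3>& p, double span) : pts(p) {
    orient_tol = 1e-11 * span * span * span;
  }

  bool conflicts(const Tet& t, const P3& p) const {
    if (!t.infinite) {
      if (t.r2 == std::numeric_limits<double>::infinity()) return true;
      double s = 0.0;
      for (int j = 0; j < 3; ++j) s += (t.cc[j] - p[j]) * (t.cc[j] - p[j]);
      return s <= t.r2 * (1.0 + 1e-12);
    }
    const P3& a = pts[t.face[0]];
    const P3& b = pts[t.face[1]];
    const P3& c = pts[t.face[2]];
    double o = orient3d(a, b, c, p);
    if (o > orient_tol) return true;
    if (o < -orient_tol) return false;
    double cc[3], r2;
    if (!circumcircle3d(a, b, c, cc, r2)) return true;
    double s = 0.0;
    for (int j = 0; j < 3; ++j) s += (cc[j] - p[j]) * (cc[j] - p[j]);
    return s <= r2 * (1.0 + 1e-12);
  }

  void add_finite(int a, int b, int c, int d) {
    Tet t;
    t.v[0] = a; t.v[1] = b; t.v[2] = c; t.v[3] = d;
    std::sort(t.v, t.v + 4);
    t.infinite = false;
    t.alive = true;
    if (!circumsphere(pts[a], pts[b], pts[c], pts[d], t.cc, t.r2)) {
      t.cc[0] = t.cc[1] = t.cc[2] = 0.0;
      t.r2 = std::numeric_limits<double>::infinity();
    }
    tets.push_back(t);
  }

  // infinite tet over face (a,b,c); `interior` is any point strictly inside
  // the current hull, used to orient the face with the interior negative
  void add_infinite(int a, int b, int c, const P3& interior) {
    Tet t;
    t.v[0] = INF; t.v[1] = a; t.v[2] = b; t.v[3] = c;
    std::sort(t.v + 1, t.v + 4);
    t.infinite = true;
    t.alive = true;
    t.r2 = 0.0;
    t.cc[0] = t.cc[1] = t.cc[2] = 0.0;
    double o = orient3d(pts[a], pts[b], pts[c], interior);
    if (o < 0) { t.face[0] = a; t.face[1] = b; t.face[2] = c; }
    else       { t.face[0] = b; t.face[1] = a; t.face[2] = c; }
    tets.push_back(t);
  }
};

}  // namespace

// [[Rcpp::export(name = ".delaunay3d_cpp")]]
IntegerMatrix delaunay3d_cpp(NumericMatrix coords) {
  int n = coords.nrow();
  if (n < 4) stop("need at least 4 points");
  std::vector<P3> pts(n);
  double lo[3] = {1e300, 1e300, 1e300}, hi[3] = {-1e300, -1e300, -1e300};
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < 3; ++j) {
      pts[i][j] = coords(i, j);
      lo[j] = std::min(lo[j], pts[i][j]);
      hi[j] = std::max(hi[j], pts[i][j]);
    }
  double span = 1e-6;
  for (int j = 0; j < 3; ++j) span = std::max(span, hi[j] - lo[j]);

  // pick four points in general position for the initial tetrahedron
  double tol_len = 1e-8 * span;
  int i0 = 0, i1 = -1, i2 = -1, i3 = -1;
  for (int i = 1; i < n && i1 < 0; ++i) {
    double d = 0;
    for (int j = 0; j < 3; ++j)
      d += (pts[i][j] - pts[i0][j]) * (pts[i][j] - pts[i0][j]);
    if (d > tol_len * tol_len) i1 = i;
  }
  if (i1 < 0) return IntegerMatrix(0, 4);
  for (int i = 1; i < n && i2 < 0; ++i) {
    if (i == i1) continue;
    double u[3], v[3], cx[3];
    for (int j = 0; j < 3; ++j) {
      u[j] = pts[i1][j] - pts[i0][j];
      v[j] = pts[i][j] - pts[i0][j];
    }
    cx[0] = u[1] * v[2] - u[2] * v[1];
    cx[1] = u[2] * v[0] - u[0] * v[2];
    cx[2] = u[0] * v[1] - u[1] * v[0];
    double area2 = cx[0] * cx[0] + cx[1] * cx[1] + cx[2] * cx[2];
    if (area2 > std::pow(1e-7 * span * span, 2)) i2 = i;
  }
  if (i2 < 0) return IntegerMatrix(0, 4);
  double vol_tol = 1e-9 * span * span * span;
  for (int i = 1; i < n && i3 < 0; ++i) {
    if (i == i1 || i == i2) continue;
    if (std::fabs(orient3d(pts[i0], pts[i1], pts[i2], pts[i])) > vol_tol) i3 = i;
  }
  if (i3 < 0) return IntegerMatrix(0, 4);  // all (near-)coplanar: degenerate

  Builder B(pts, span);
  B.add_finite(i0, i1, i2, i3);
  P3 interior;
  for (int j = 0; j < 3; ++j)
    interior[j] = (pts[i0][j] + pts[i1][j] + pts[i2][j] + pts[i3][j]) / 4.0;
  B.add_infinite(i1, i2, i3, interior);
  B.add_infinite(i0, i2, i3, interior);
  B.add_infinite(i0, i1, i3, interior);
  B.add_infinite(i0, i1, i2, interior);

  // centroid of inserted points stays strictly inside the hull
  P3 csum = interior;
  for (int j = 0; j < 3; ++j) csum[j] *= 4.0;
  int n_inserted = 4;

  typedef std::array<int, 3> Face;
  std::map<Face, int> face_count;
  std::vector<Face> bound_faces;

  for (int ip = 0; ip < n; ++ip) {
    if (ip == i0 || ip == i1 || ip == i2 || ip == i3) continue;
    const P3& p = pts[ip];
    std::vector<int> bad;
    for (size_t t = 0; t < B.tets.size(); ++t) {
      if (!B.tets[t].alive) continue;
      if (B.conflicts(B.tets[t], p)) bad.push_back((int)t);
    }
    face_count.clear();
    static const int fidx[4][3] = {{0, 1, 2}, {0, 1, 3}, {0, 2, 3}, {1, 2, 3}};
    for (size_t b = 0; b < bad.size(); ++b) {
      const Tet& t = B.tets[bad[b]];
      for (int f = 0; f < 4; ++f) {
        Face fc = {t.v[fidx[f][0]], t.v[fidx[f][1]], t.v[fidx[f][2]]};
        face_count[fc] += 1;
      }
      B.tets[bad[b]].alive = false;
    }
    for (int j = 0; j < 3; ++j) csum[j] += p[j];
    ++n_inserted;
    P3 cen;
    for (int j = 0; j < 3; ++j) cen[j] = csum[j] / n_inserted;
    for (std::map<Face, int>::const_iterator it = face_count.begin();
         it != face_count.end(); ++it) {
      if (it->second != 1) continue;
      const Face& fc = it->first;
      if (fc[0] == INF)
        B.add_infinite(fc[1], fc[2], ip, cen);
      else
        B.add_finite(fc[0], fc[1], fc[2], ip);
    }
  }

  int kept = 0;
  for (size_t t = 0; t < B.tets.size(); ++t)
    if (B.tets[t].alive && !B.tets[t].infinite) ++kept;
  IntegerMatrix out(kept, 4);
  int row = 0;
  for (size_t t = 0; t < B.tets.size(); ++t) {
    if (!B.tets[t].alive || B.tets[t].infinite) continue;
    for (int k = 0; k < 4; ++k) out(row, k) = B.tets[t].v[k] + 1;
    ++row;
  }
  return out;
}
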