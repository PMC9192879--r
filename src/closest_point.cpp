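// Closest point on a triangle soup, with a uniform-grid acceleration
// structure. Used by the signed-distance map and by the ICP inner loop.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
#include <algorithm>

using namespace Rcpp;

namespace {

struct Vec3 {
  double x, y, z;
};

inline Vec3 operator-(const Vec3& a, const Vec3& b) {
  return {a.x - b.x, a.y - b.y, a.z - b.z};
}
inline Vec3 operator+(const Vec3& a, const Vec3& b) {
  return {a.x + b.x, a.y + b.y, a.z + b.z};
}
inline Vec3 operator*(double s, const Vec3& a) {
  return {s * a.x, s * a.y, s * a.z};
}
inline double dot(const Vec3& a, const Vec3& b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}

// Ericson, Real-Time Collision Detection, 5.1.5
Vec3 closest_on_triangle(const Vec3& p, const Vec3& a, const Vec3& b,
                         const Vec3& c) {
  Vec3 ab = b - a, ac = c - a, ap = p - a;
  double d1 = dot(ab, ap), d2 = dot(ac, ap);
  if (d1 <= 0.0 && d2 <= 0.0) return a;
  Vec3 bp = p - b;
  double d3 = dot(ab, bp), d4 = dot(ac, bp);
  if (d3 >= 0.0 && d4 <= d3) return b;
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    return a + v * ab;
  }
  Vec3 cp = p - c;
  double d5 = dot(ab, cp), d6 = dot(ac, cp);
  if (d6 >= 0.0 && d5 <= d6) return c;
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    return a + w * ac;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    return b + w * (c - b);
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  return a + v * ab + w * ac;
}

struct TriGrid {
  std::vector<Vec3> va, vb, vc;  // triangle vertices
  double cell;
  double x0, y0, z0;
  int nx, ny, nz;
  std::vector<std::vector<int>> cells;

  int cell_index(int i, int j, int k) const {
    return i + nx * (j + ny * k);
  }

  void build(const NumericMatrix& V, const IntegerMatrix& F,
             double cell_size) {
    int nf = F.nrow();
    va.resize(nf); vb.resize(nf); vc.resize(nf);
    double xmin = R_PosInf, ymin = R_PosInf, zmin = R_PosInf;
    double xmax = R_NegInf, ymax = R_NegInf, zmax = R_NegInf;
    for (int t = 0; t < nf; ++t) {
      int ia = F(t, 0) - 1, ib = F(t, 1) - 1, ic = F(t, 2) - 1;
      va[t] = {V(ia, 0), V(ia, 1), V(ia, 2)};
      vb[t] = {V(ib, 0), V(ib, 1), V(ib, 2)};
      vc[t] = {V(ic, 0), V(ic, 1), V(ic, 2)};
      xmin = std::min({xmin, va[t].x, vb[t].x, vc[t].x});
      ymin = std::min({ymin, va[t].y, vb[t].y, vc[t].y});
      zmin = std::min({zmin, va[t].z, vb[t].z, vc[t].z});
      xmax = std::max({xmax, va[t].x, vb[t].x, vc[t].x});
      ymax = std::max({ymax, va[t].y, vb[t].y, vc[t].y});
      zmax = std::max({zmax, va[t].z, vb[t].z, vc[t].z});
    }
    cell = cell_size;
    x0 = xmin; y0 = ymin; z0 = zmin;
    nx = std::max(1, (int)std::ceil((xmax - xmin) / cell) + 1);
    ny = std::max(1, (int)std::ceil((ymax - ymin) / cell) + 1);
    nz = std::max(1, (int)std::ceil((zmax - zmin) / cell) + 1);
    cells.assign((size_t)nx * ny * nz, {});
    for (int t = 0; t < nf; ++t) {
      double txmin = std::min({va[t].x, vb[t].x, vc[t].x});
      double txmax = std::max({va[t].x, vb[t].x, vc[t].x});
      double tymin = std::min({va[t].y, vb[t].y, vc[t].y});
      double tymax = std::max({va[t].y, vb[t].y, vc[t].y});
      double tzmin = std::min({va[t].z, vb[t].z, vc[t].z});
      double tzmax = std::max({va[t].z, vb[t].z, vc[t].z});
      int i0 = clampi((txmin - x0) / cell, nx), i1 = clampi((txmax - x0) / cell, nx);
      int j0 = clampi((tymin - y0) / cell, ny), j1 = clampi((tymax - y0) / cell, ny);
      int k0 = clampi((tzmin - z0) / cell, nz), k1 = clampi((tzmax - z0) / cell, nz);
      for (int k = k0; k <= k1; ++k)
        for (int j = j0; j <= j1; ++j)
          for (int i = i0; i <= i1; ++i)
            cells[cell_index(i, j, k)].push_back(t);
    }
  }

  static int clampi(double v, int n) {
    int i = (int)std::floor(v);
    if (i < 0) i = 0;
    if (i >= n) i = n - 1;
    return i;
  }

  // closest point to p over all triangles; returns squared distance,
  // closest point and triangle index
  void query(const Vec3& p, double& best_d2, Vec3& best_q, int& best_t) const {
    int ci = clampi((p.x - x0) / cell, nx);
    int cj = clampi((p.y - y0) / cell, ny);
    int ck = clampi((p.z - z0) / cell, nz);
    best_d2 = std::numeric_limits<double>::infinity();
    best_t = -1;
    int max_ring = std::max({nx, ny, nz});
    for (int ring = 0; ring <= max_ring; ++ring) {
      // once we have a candidate, stop when the nearest possible point in
      // this ring is farther than the current best
      if (best_t >= 0) {
        double ring_min = (ring - 1) * cell;  // conservative
        if (ring_min > 0 && ring_min * ring_min > best_d2) break;
      }
      bool any_cell = false;
      int i0 = ci - ring, i1 = ci + ring;
      int j0 = cj - ring, j1 = cj + ring;
      int k0 = ck - ring, k1 = ck + ring;
      for (int k = k0; k <= k1; ++k) {
        if (k < 0 || k >= nz) continue;
        for (int j = j0; j <= j1; ++j) {
          if (j < 0 || j >= ny) continue;
          for (int i = i0; i <= i1; ++i) {
            if (i < 0 || i >= nx) continue;
            // shell only: skip interior cells already visited
            if (ring > 0 && i != i0 && i != i1 && j != j0 && j != j1 &&
                k != k0 && k != k1)
              continue;
            any_cell = true;
            const std::vector<int>& lst = cells[cell_index(i, j, k)];
            for (int t : lst) {
              Vec3 q = closest_on_triangle(p, va[t], vb[t], vc[t]);
              Vec3 d = p - q;
              double d2 = dot(d, d);
              if (d2 < best_d2) {
                best_d2 = d2;
                best_q = q;
                best_t = t;
              }
            }
          }
        }
      }
      if (!any_cell && best_t >= 0) break;
    }
  }
};

}  // namespace

// [[Rcpp::export(name = "cpp_closest_points")]]
List cpp_closest_points(NumericMatrix query, NumericMatrix V,
                        IntegerMatrix F, double cell_size) {
  TriGrid grid;
  grid.build(V, F, cell_size);
  int n = query.nrow();
  NumericVector dist(n);
  IntegerVector face(n);
  NumericMatrix points(n, 3);
  for (int i = 0; i < n; ++i) {
    Vec3 p = {query(i, 0), query(i, 1), query(i, 2)};
    double d2;
    Vec3 q;
    int t;
    grid.query(p, d2, q, t);
    dist[i] = std::sqrt(d2);
    face[i] = t + 1;
    points(i, 0) = q.x;
    points(i, 1) = q.y;
    points(i, 2) = q.z;
  }
  return List::create(_["distance"] = dist, _["point"] = points,
                      _["face"] = face);
}
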