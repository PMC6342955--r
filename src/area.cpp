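#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Accessible area of a pore: the part of the Delaunay triangle whose points
// lie at distance >= sigma from all three vertices (obstacle centres).
// Computed exactly by Green's theorem over the oriented boundary of
// S = T ∩ (D1 ∪ D2 ∪ D3): A = area(T) - area(S). Boundary pieces of S are
// (i) sub-segments of the triangle's edges covered by some disc and
// (ii) arcs of each circle inside T and outside the other discs; pieces are
// classified by midpoint tests, which is robust for generic geometry.

namespace {

struct P2 { double x, y; };

inline double cross(const P2 &a, const P2 &b) { return a.x * b.y - a.y * b.x; }

inline double orient(const P2 &a, const P2 &b, const P2 &c) {
  return (b.x - a.x) * (c.y - a.y) - (b.y - a.y) * (c.x - a.x);
}

inline bool in_triangle(const P2 &p, const P2 v[3]) {
  // v is CCW; inclusive
  return orient(v[0], v[1], p) >= 0 && orient(v[1], v[2], p) >= 0 &&
         orient(v[2], v[0], p) >= 0;
}

// angles of intersection points of circle (c, r) with segment a-b, appended
inline void circle_segment_angles(const P2 &c, double r, const P2 &a,
                                  const P2 &b, std::vector<double> &out) {
  double dx = b.x - a.x, dy = b.y - a.y;
  double fx = a.x - c.x, fy = a.y - c.y;
  double A = dx * dx + dy * dy;
  double B = 2.0 * (fx * dx + fy * dy);
  double C = fx * fx + fy * fy - r * r;
  double disc = B * B - 4.0 * A * C;
  if (disc <= 0.0 || A == 0.0) return;
  double sq = std::sqrt(disc);
  for (int s = -1; s <= 1; s += 2) {
    double t = (-B + s * sq) / (2.0 * A);
    if (t >= 0.0 && t <= 1.0) {
      double px = a.x + t * dx - c.x, py = a.y + t * dy - c.y;
      out.push_back(std::atan2(py, px));
    }
  }
}

// angles on circle 1 of the two intersection points with circle 2 (equal radii r)
inline void circle_circle_angles(const P2 &c1, const P2 &c2, double r,
                                 std::vector<double> &out) {
  double dx = c2.x - c1.x, dy = c2.y - c1.y;
  double d2 = dx * dx + dy * dy, d = std::sqrt(d2);
  if (d >= 2.0 * r || d <= 0.0) return;
  double a = d / 2.0;                       // equal radii
  double h = std::sqrt(std::max(r * r - a * a, 0.0));
  double mx = c1.x + dx * (a / d), my = c1.y + dy * (a / d);
  double ux = -dy / d, uy = dx / d;
  out.push_back(std::atan2(my + h * uy - c1.y, mx + h * ux - c1.x));
  out.push_back(std::atan2(my - h * uy - c1.y, mx - h * ux - c1.x));
}

double tri_disc_union_area(const P2 v[3], double r) {
  double covered = 0.0;

  // (i) triangle edge pieces covered by the union of discs
  for (int e = 0; e < 3; ++e) {
    const P2 &a = v[e], &b = v[(e + 1) % 3];
    double dx = b.x - a.x, dy = b.y - a.y;
    // t-events from the three circles
    std::vector<double> ts; ts.push_back(0.0); ts.push_back(1.0);
    for (int i = 0; i < 3; ++i) {
      double fx = a.x - v[i].x, fy = a.y - v[i].y;
      double A = dx * dx + dy * dy;
      double B = 2.0 * (fx * dx + fy * dy);
      double C = fx * fx + fy * fy - r * r;
      double disc = B * B - 4.0 * A * C;
      if (disc <= 0.0 || A == 0.0) continue;
      double sq = std::sqrt(disc);
      double t1 = (-B - sq) / (2.0 * A), t2 = (-B + sq) / (2.0 * A);
      if (t1 > 0.0 && t1 < 1.0) ts.push_back(t1);
      if (t2 > 0.0 && t2 < 1.0) ts.push_back(t2);
    }
    std::sort(ts.begin(), ts.end());
    for (size_t k = 0; k + 1 < ts.size(); ++k) {
      double tm = 0.5 * (ts[k] + ts[k + 1]);
      if (ts[k + 1] - ts[k] <= 0.0) continue;
      P2 pm = { a.x + tm * dx, a.y + tm * dy };
      bool inside = false;
      for (int i = 0; i < 3 && !inside; ++i) {
        double qx = pm.x - v[i].x, qy = pm.y - v[i].y;
        if (qx * qx + qy * qy < r * r) inside = true;
      }
      if (inside) {
        P2 A2 = { a.x + ts[k] * dx,     a.y + ts[k] * dy };
        P2 B2 = { a.x + ts[k + 1] * dx, a.y + ts[k + 1] * dy };
        covered += 0.5 * cross(A2, B2);
      }
    }
  }

  // (ii) arcs of each circle inside T and outside the other discs
  const double TWO_PI = 2.0 * M_PI;
  for (int i = 0; i < 3; ++i) {
    const P2 &c = v[i];
    std::vector<double> th;
    for (int e = 0; e < 3; ++e)
      circle_segment_angles(c, r, v[e], v[(e + 1) % 3], th);
    for (int j = 0; j < 3; ++j)
      if (j != i) circle_circle_angles(c, v[j], r, th);
    for (size_t k = 0; k < th.size(); ++k)
      if (th[k] < 0.0) th[k] += TWO_PI;
    std::sort(th.begin(), th.end());
    size_t n_ev = th.size();
    if (n_ev == 0) th.push_back(0.0);
    th.push_back(th[0] + TWO_PI);
    for (size_t k = 0; k + 1 < th.size(); ++k) {
      double t0 = th[k], t1 = th[k + 1];
      if (t1 - t0 <= 0.0) continue;
      double tm = 0.5 * (t0 + t1);
      P2 pm = { c.x + r * std::cos(tm), c.y + r * std::sin(tm) };
      if (!in_triangle(pm, v)) continue;
      bool in_other = false;
      for (int j = 0; j < 3 && !in_other; ++j) {
        if (j == i) continue;
        double qx = pm.x - v[j].x, qy = pm.y - v[j].y;
        if (qx * qx + qy * qy < r * r) in_other = true;
      }
      if (in_other) continue;
      covered += 0.5 * (r * r * (t1 - t0)
                        + r * (c.x * (std::sin(t1) - std::sin(t0))
                             - c.y * (std::cos(t1) - std::cos(t0))));
    }
  }
  return covered;
}

} // namespace

// tri_coords: T x 6 matrix (x1,y1,x2,y2,x3,y3); returns accessible area per
// triangle, clamped to [0, area].
// [[Rcpp::export(rng = false)]]
NumericVector accessible_area_cpp(NumericMatrix tri_coords, double sigma) {
  int T = tri_coords.nrow();
  NumericVector out(T);
  for (int q = 0; q < T; ++q) {
    P2 v[3] = { { tri_coords(q, 0), tri_coords(q, 1) },
                { tri_coords(q, 2), tri_coords(q, 3) },
                { tri_coords(q, 4), tri_coords(q, 5) } };
    double s = orient(v[0], v[1], v[2]);
    if (s < 0.0) std::swap(v[1], v[2]);   // enforce CCW
    double area = 0.5 * std::fabs(s);
    double u = tri_disc_union_area(v, sigma);
    double a = area - u;
    if (a < 0.0) a = 0.0;
    if (a > area) a = area;
    out[q] = a;
  }
  return out;
}
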