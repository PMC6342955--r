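#include <Rcpp.h>
#include <vector>
#include <cmath>
#include "rng.h"
#include "cell_list.h"
using namespace Rcpp;

// Dynamic Monte Carlo of hard-disc tracers in a quenched matrix.
// Acceptance rules: (1) no tracer-obstacle overlap at the trial position;
// (2) the move segment must not cross any impassable channel (Delaunay edge
// with gap g <= 0). Edge-crossing queries use a halo grid of periodically
// shifted edge images so segments never need unwrapping logic.

namespace {

struct Seg { double ax, ay, bx, by; int id; };

inline double cross2(double ax, double ay, double bx, double by) {
  return ax * by - ay * bx;
}

// Inclusive segment intersection: touching counts as crossing (conservative
// tie rule for moves grazing a tessellation vertex). Returns true and the
// parameter t along p0->p1 of the hit.
inline bool seg_cross(double p0x, double p0y, double p1x, double p1y,
                      double ax, double ay, double bx, double by, double &t) {
  double dx = p1x - p0x, dy = p1y - p0y;
  double ex = bx - ax, ey = by - ay;
  double o1 = cross2(dx, dy, ax - p0x, ay - p0y);
  double o2 = cross2(dx, dy, bx - p0x, by - p0y);
  double o3 = cross2(ex, ey, p0x - ax, p0y - ay);
  double o4 = cross2(ex, ey, p1x - ax, p1y - ay);
  if (o1 * o2 > 0.0 || o3 * o4 > 0.0) return false;
  double denom = cross2(dx, dy, ex, ey);
  if (denom == 0.0) {
    // parallel; collinear overlap only if o1 == 0
    if (o1 != 0.0 || o3 != 0.0) return false;
    // collinear: overlap iff projections intersect
    double lo = std::min(p0x * dx + p0y * dy, p1x * dx + p1y * dy);
    double hi = std::max(p0x * dx + p0y * dy, p1x * dx + p1y * dy);
    double pa = ax * dx + ay * dy, pb = bx * dx + by * dy;
    if (std::max(pa, pb) < lo || std::min(pa, pb) > hi) return false;
    t = 0.0;
    return true;
  }
  t = cross2(ax - p0x, ay - p0y, ex, ey) / denom;
  if (t < 0.0) t = 0.0;
  if (t > 1.0) t = 1.0;
  return true;
}

// Halo grid of shifted edge images over [-pad, L+pad)
struct EdgeGrid {
  double lo, hc;
  int nc;
  std::vector<Seg> entries;
  std::vector<std::vector<int>> cells;
  std::vector<int> stamp;
  int cur_stamp;

  void build(const NumericMatrix &edge_coords, double L, double pad,
             double cell_w) {
    lo = -pad;
    double hi = L + pad;
    nc = std::max(1, (int)std::ceil((hi - lo) / cell_w));
    hc = (hi - lo) / nc;
    cells.assign((size_t)nc * nc, {});
    entries.clear();
    int E = edge_coords.nrow();
    for (int e = 0; e < E; ++e) {
      for (int sy = -1; sy <= 1; ++sy) {
        for (int sx = -1; sx <= 1; ++sx) {
          Seg s;
          s.ax = edge_coords(e, 0) + L * sx;
          s.ay = edge_coords(e, 1) + L * sy;
          s.bx = edge_coords(e, 2) + L * sx;
          s.by = edge_coords(e, 3) + L * sy;
          s.id = e;
          double bx0 = std::min(s.ax, s.bx), bx1 = std::max(s.ax, s.bx);
          double by0 = std::min(s.ay, s.by), by1 = std::max(s.ay, s.by);
          if (bx1 < lo || bx0 >= hi || by1 < lo || by0 >= hi) continue;
          int id = (int)entries.size();
          entries.push_back(s);
          int cx0 = clampc((int)std::floor((bx0 - lo) / hc));
          int cx1 = clampc((int)std::floor((bx1 - lo) / hc));
          int cy0 = clampc((int)std::floor((by0 - lo) / hc));
          int cy1 = clampc((int)std::floor((by1 - lo) / hc));
          for (int cy = cy0; cy <= cy1; ++cy)
            for (int cx = cx0; cx <= cx1; ++cx)
              cells[(size_t)cy * nc + cx].push_back(id);
        }
      }
    }
    stamp.assign(entries.size(), -1);
    cur_stamp = 0;
  }

  inline int clampc(int c) const {
    if (c < 0) return 0;
    if (c >= nc) return nc - 1;
    return c;
  }

  // visit candidate entries for a segment's bbox, deduplicated
  template <class F>
  inline void for_candidates(double x0, double y0, double x1, double y1, F f) {
    ++cur_stamp;
    int cx0 = clampc((int)std::floor((std::min(x0, x1) - lo) / hc));
    int cx1 = clampc((int)std::floor((std::max(x0, x1) - lo) / hc));
    int cy0 = clampc((int)std::floor((std::min(y0, y1) - lo) / hc));
    int cy1 = clampc((int)std::floor((std::max(y0, y1) - lo) / hc));
    for (int cy = cy0; cy <= cy1; ++cy)
      for (int cx = cx0; cx <= cx1; ++cx) {
        const std::vector<int> &v = cells[(size_t)cy * nc + cx];
        for (size_t k = 0; k < v.size(); ++k) {
          int id = v[k];
          if (stamp[id] == cur_stamp) continue;
          stamp[id] = cur_stamp;
          f(entries[id]);
        }
      }
  }
};

inline double wrap01(double x, double L) {
  x -= L * std::floor(x / L);
  if (x >= L) x = 0.0;   // guard the x/L == 1 rounding case
  return x;
}

inline double orientp(double ax, double ay, double bx, double by,
                      double px, double py) {
  return (bx - ax) * (py - ay) - (by - ay) * (px - ax);
}

} // namespace

// Run dynamic MC for tracers; returns unwrapped displacement components for
// every tracer at the requested attempt counts, plus the acceptance count.
// [[Rcpp::export(rng = false)]]
List msd_run_cpp(NumericMatrix obstacles, double L, double sigma,
                 NumericMatrix edge_coords, LogicalVector passable,
                 double delta, NumericMatrix tracer_init,
                 NumericVector sample_attempts, double seed) {
  int N = obstacles.nrow();
  int n_tracers = tracer_init.nrow();
  int n_samples = sample_attempts.size();
  int E = edge_coords.nrow();
  if (delta * 1.4143 > 0.45 * L)
    stop("delta too large for box size (move segments must stay below L/2)");

  Xoshiro rng((uint64_t)seed);
  CellList cl(L, sigma);
  for (int j = 0; j < N; ++j) cl.insert(j, obstacles(j, 0), obstacles(j, 1));

  double pad = std::max(2.0, 1.5 * delta + 0.5);
  EdgeGrid eg;
  std::vector<char> pass(E);
  for (int e = 0; e < E; ++e) pass[e] = passable[e] ? 1 : 0;
  if (E > 0) eg.build(edge_coords, L, pad, std::max(2.0, delta));

  std::vector<double> wx(n_tracers), wy(n_tracers),
                      ux(n_tracers, 0.0), uy(n_tracers, 0.0);
  for (int k = 0; k < n_tracers; ++k) {
    wx[k] = tracer_init(k, 0);
    wy[k] = tracer_init(k, 1);
  }

  NumericMatrix disp(n_samples, 2 * n_tracers);
  const double s2 = sigma * sigma;
  long long total = (long long)sample_attempts[n_samples - 1];
  int si = 0;
  long long next_sample = (long long)sample_attempts[0];
  long long accepted = 0;

  for (long long a = 1; a <= total; ++a) {
    int k = rng.unif_int(n_tracers);
    double ddx = rng.unif_sym(delta), ddy = rng.unif_sym(delta);
    double x0 = wx[k], y0 = wy[k];
    double x1 = x0 + ddx, y1 = y0 + ddy;

    bool ok = true;
    if (N > 0) {
      double xq = wrap01(x1, L), yq = wrap01(y1, L);
      cl.for_neighbours(xq, yq, [&](int j) {
        if (!ok) return;
        double dx = min_image(xq - obstacles(j, 0), L);
        double dy = min_image(yq - obstacles(j, 1), L);
        if (dx * dx + dy * dy < s2) ok = false;
      });
    }
    if (ok && E > 0) {
      eg.for_candidates(x0, y0, x1, y1, [&](const Seg &s) {
        if (!ok) return;
        double t;
        if (!pass[s.id] &&
            seg_cross(x0, y0, x1, y1, s.ax, s.ay, s.bx, s.by, t))
          ok = false;
      });
    }
    if (ok) {
      wx[k] = wrap01(x1, L);
      wy[k] = wrap01(y1, L);
      ux[k] += ddx;
      uy[k] += ddy;
      ++accepted;
    }
    while (si < n_samples && a == next_sample) {
      for (int kk = 0; kk < n_tracers; ++kk) {
        disp(si, 2 * kk) = ux[kk];
        disp(si, 2 * kk + 1) = uy[kk];
      }
      ++si;
      if (si < n_samples) next_sample = (long long)sample_attempts[si];
    }
  }
  return List::create(_["disp"] = disp, _["accepted"] = (double)accepted,
                      _["attempts"] = (double)total);
}

// All periodic-edge crossings of one move segment (brute force over shifted
// edge images), in parametric order. For tests and single-move queries.
// [[Rcpp::export(rng = false)]]
DataFrame crossing_check_cpp(NumericVector p0, NumericVector p1,
                             NumericMatrix edge_coords, LogicalVector passable,
                             double L) {
  double segl = std::hypot(p1[0] - p0[0], p1[1] - p0[1]);
  if (segl > 0.5 * L)
    stop("segment longer than L/2: periodic image ambiguous");
  int E = edge_coords.nrow();
  std::vector<int> ids;
  std::vector<double> ts;
  std::vector<int> pas;
  for (int e = 0; e < E; ++e) {
    double best_t = -1.0;
    for (int sy = -1; sy <= 1; ++sy)
      for (int sx = -1; sx <= 1; ++sx) {
        double t;
        if (seg_cross(p0[0], p0[1], p1[0], p1[1],
                      edge_coords(e, 0) + L * sx, edge_coords(e, 1) + L * sy,
                      edge_coords(e, 2) + L * sx, edge_coords(e, 3) + L * sy,
                      t)) {
          if (best_t < 0.0 || t < best_t) best_t = t;
        }
      }
    if (best_t >= 0.0) {
      ids.push_back(e + 1);
      ts.push_back(best_t);
      pas.push_back(passable[e] ? 1 : 0);
    }
  }
  // sort by t
  std::vector<int> ord(ids.size());
  for (size_t i = 0; i < ord.size(); ++i) ord[i] = (int)i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return ts[a] < ts[b]; });
  IntegerVector out_id(ids.size());
  NumericVector out_t(ids.size());
  LogicalVector out_p(ids.size());
  for (size_t i = 0; i < ord.size(); ++i) {
    out_id[i] = ids[ord[i]];
    out_t[i] = ts[ord[i]];
    out_p[i] = pas[ord[i]] == 1;
  }
  return DataFrame::create(_["edge"] = out_id, _["t"] = out_t,
                           _["passable"] = out_p);
}

// Mean first-passage sampling: tracers start uniformly over the accessible
// region of chosen pores and evolve under the same MC rules until the first
// accepted move whose endpoint leaves the starting triangle. Returns per
// pore: mean escape time (MC time units), exit-side counts, censored count.
// [[Rcpp::export(rng = false)]]
NumericMatrix first_passage_cpp(NumericMatrix obstacles, double L, double sigma,
                                NumericMatrix tri_coords,
                                NumericMatrix edge_coords,
                                LogicalVector passable,
                                IntegerVector pore_ids, double delta,
                                int n_trials, double step_cap, double seed) {
  int N = obstacles.nrow();
  int E = edge_coords.nrow();
  int n_pores = pore_ids.size();
  NumericMatrix out(n_pores, 6);
  colnames(out) = CharacterVector::create("tau_mean", "n1", "n2", "n3",
                                          "censored", "n_escaped");
  const double s2 = sigma * sigma;

  // precompute edge midpoints / half-lengths for locality tests
  std::vector<double> emx(E), emy(E), ehl(E);
  for (int e = 0; e < E; ++e) {
    emx[e] = 0.5 * (edge_coords(e, 0) + edge_coords(e, 2));
    emy[e] = 0.5 * (edge_coords(e, 1) + edge_coords(e, 3));
    ehl[e] = 0.5 * std::hypot(edge_coords(e, 2) - edge_coords(e, 0),
                              edge_coords(e, 3) - edge_coords(e, 1));
  }

  for (int q = 0; q < n_pores; ++q) {
    int tq = pore_ids[q] - 1;
    double vx[3] = { tri_coords(tq, 0), tri_coords(tq, 2), tri_coords(tq, 4) };
    double vy[3] = { tri_coords(tq, 1), tri_coords(tq, 3), tri_coords(tq, 5) };
    // sides BEFORE any orientation swap: side k = (v[(k+1)%3], v[(k+2)%3]),
    // matching the network's edge/side indexing
    double sx0[3], sy0[3], sx1[3], sy1[3];
    for (int k = 0; k < 3; ++k) {
      sx0[k] = vx[(k + 1) % 3]; sy0[k] = vy[(k + 1) % 3];
      sx1[k] = vx[(k + 2) % 3]; sy1[k] = vy[(k + 2) % 3];
    }
    bool ccw = orientp(vx[0], vy[0], vx[1], vy[1], vx[2], vy[2]) > 0.0;
    if (!ccw) { std::swap(vx[1], vx[2]); std::swap(vy[1], vy[2]); }

    double cx = (vx[0] + vx[1] + vx[2]) / 3.0;
    double cy = (vy[0] + vy[1] + vy[2]) / 3.0;
    double r_tri = 0.0;
    for (int k = 0; k < 3; ++k)
      r_tri = std::max(r_tri, std::hypot(vx[k] - cx, vy[k] - cy));
    double R_loc = r_tri + 1.5 * delta + sigma + 0.5;

    // local obstacles (minimum-image representatives near the centroid)
    std::vector<double> ox, oy;
    for (int j = 0; j < N; ++j) {
      double dx = min_image(obstacles(j, 0) - cx, L);
      double dy = min_image(obstacles(j, 1) - cy, L);
      if (dx * dx + dy * dy <= R_loc * R_loc) {
        ox.push_back(cx + dx);
        oy.push_back(cy + dy);
      }
    }
    // small uniform grid (CSR layout) over the local box; cells are padded
    // by one ring so 3x3 neighbourhoods never need bound checks, and each
    // obstacle is registered in every cell whose 3x3 block it can affect,
    // so a query touches exactly one cell
    int ng = std::max(1, (int)std::floor(2.0 * R_loc / sigma)) + 2;
    double gw = 2.0 * R_loc / (ng - 2);   // >= sigma, so one-cell queries suffice
    double g0x = cx - R_loc - gw, g0y = cy - R_loc - gw;
    double inv_gw = 1.0 / gw;
    int ncell = ng * ng;
    std::vector<int> counts(ncell + 1, 0);
    std::vector<std::pair<int,int>> reg;
    for (size_t j = 0; j < ox.size(); ++j) {
      int gx = (int)((ox[j] - g0x) * inv_gw);
      int gy = (int)((oy[j] - g0y) * inv_gw);
      for (int iy = gy - 1; iy <= gy + 1; ++iy)
        for (int ix = gx - 1; ix <= gx + 1; ++ix)
          if (ix >= 0 && ix < ng && iy >= 0 && iy < ng)
            reg.push_back(std::make_pair(iy * ng + ix, (int)j));
    }
    for (size_t r = 0; r < reg.size(); ++r) counts[reg[r].first + 1]++;
    for (int c = 0; c < ncell; ++c) counts[c + 1] += counts[c];
    std::vector<double> gx_flat(reg.size()), gy_flat(reg.size());
    {
      std::vector<int> fill(counts.begin(), counts.end() - 1);
      for (size_t r = 0; r < reg.size(); ++r) {
        int at = fill[reg[r].first]++;
        gx_flat[at] = ox[reg[r].second];
        gy_flat[at] = oy[reg[r].second];
      }
    }
    auto overlaps = [&](double x, double y) -> bool {
      int gx = (int)((x - g0x) * inv_gw);
      int gy = (int)((y - g0y) * inv_gw);
      if (gx < 0 || gx >= ng || gy < 0 || gy >= ng) return false;
      int c = gy * ng + gx;
      for (int m = counts[c]; m < counts[c + 1]; ++m) {
        double dx = x - gx_flat[m], dy = y - gy_flat[m];
        if (dx * dx + dy * dy < s2) return true;
      }
      return false;
    };

    // local impassable edges shifted to the centroid frame (only they can
    // block a move; passable crossings are always allowed), with bounding
    // boxes for cheap rejection in the per-move loop
    std::vector<double> lex0, ley0, lex1, ley1, lbx0, lby0, lbx1, lby1;
    for (int e = 0; e < E; ++e) {
      if (passable[e]) continue;
      double dx = min_image(emx[e] - cx, L);
      double dy = min_image(emy[e] - cy, L);
      if (std::hypot(dx, dy) <= R_loc + ehl[e]) {
        double shx = (cx + dx) - emx[e], shy = (cy + dy) - emy[e];
        double ax = edge_coords(e, 0) + shx, ay = edge_coords(e, 1) + shy;
        double bx = edge_coords(e, 2) + shx, by = edge_coords(e, 3) + shy;
        lex0.push_back(ax); ley0.push_back(ay);
        lex1.push_back(bx); ley1.push_back(by);
        lbx0.push_back(std::min(ax, bx)); lby0.push_back(std::min(ay, by));
        lbx1.push_back(std::max(ax, bx)); lby1.push_back(std::max(ay, by));
      }
    }

    Xoshiro rng((uint64_t)seed * 2654435761ULL + (uint64_t)(pore_ids[q]) * 1000003ULL);
    double tau_sum = 0.0;
    int n_side[3] = { 0, 0, 0 };
    int censored = 0, escaped = 0;
    bool degenerate = false;

    for (int trial = 0; trial < n_trials && !degenerate; ++trial) {
      // start uniform over the accessible part of the triangle
      double px = 0.0, py = 0.0;
      bool placed = false;
      for (int attempt = 0; attempt < 20000; ++attempt) {
        double r1 = std::sqrt(rng.unif()), r2 = rng.unif();
        double b0 = 1.0 - r1, b1 = r1 * (1.0 - r2), b2 = r1 * r2;
        double x = b0 * vx[0] + b1 * vx[1] + b2 * vx[2];
        double y = b0 * vy[0] + b1 * vy[1] + b2 * vy[2];
        if (!overlaps(x, y)) { px = x; py = y; placed = true; break; }
      }
      if (!placed) { degenerate = true; break; }

      bool done = false;
      for (double step = 1.0; step <= step_cap; ++step) {
        double ddx = rng.unif_sym(delta), ddy = rng.unif_sym(delta);
        double qx = px + ddx, qy = py + ddy;
        if (overlaps(qx, qy)) continue;
        bool inside = orientp(vx[0], vy[0], vx[1], vy[1], qx, qy) >= 0.0 &&
                      orientp(vx[1], vy[1], vx[2], vy[2], qx, qy) >= 0.0 &&
                      orientp(vx[2], vy[2], vx[0], vy[0], qx, qy) >= 0.0;
        if (inside) { px = qx; py = qy; continue; }
        // leaving the triangle: check the impassable local edges
        bool blocked = false;
        double mbx0 = std::min(px, qx), mby0 = std::min(py, qy);
        double mbx1 = std::max(px, qx), mby1 = std::max(py, qy);
        for (size_t e = 0; e < lex0.size() && !blocked; ++e) {
          if (lbx1[e] < mbx0 || lbx0[e] > mbx1 || lby1[e] < mby0 || lby0[e] > mby1)
            continue;
          double t;
          if (seg_cross(px, py, qx, qy, lex0[e], ley0[e], lex1[e], ley1[e], t))
            blocked = true;
        }
        if (blocked) continue;
        // accepted escape: attribute the first starting-triangle side crossed
        double best_t = 2.0;
        int best_side = -1;
        for (int k = 0; k < 3; ++k) {
          double t;
          if (seg_cross(px, py, qx, qy, sx0[k], sy0[k], sx1[k], sy1[k], t)) {
            if (t < best_t) { best_t = t; best_side = k; }
          }
        }
        if (best_side < 0) continue;  // numerically grazing: retry
        ++n_side[best_side];
        tau_sum += step;
        ++escaped;
        done = true;
        break;
      }
      if (!done) ++censored;
    }

    if (degenerate) {
      out(q, 0) = NA_REAL;
      out(q, 1) = out(q, 2) = out(q, 3) = NA_REAL;
      out(q, 4) = n_trials;
      out(q, 5) = 0;
    } else {
      out(q, 0) = escaped > 0 ? tau_sum / escaped : NA_REAL;
      out(q, 1) = n_side[0];
      out(q, 2) = n_side[1];
      out(q, 3) = n_side[2];
      out(q, 4) = censored;
      out(q, 5) = escaped;
    }
    if (q % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Brute-force point location on the periodic tessellation: index (1-based)
// of a triangle whose (possibly shifted) image contains each query point,
// or 0 if none. Validation / test helper.
// [[Rcpp::export(rng = false)]]
IntegerVector locate_triangle_cpp(NumericMatrix pts, NumericMatrix tri_coords,
                                  double L) {
  int Q = pts.nrow(), T = tri_coords.nrow();
  IntegerVector out(Q);
  for (int i = 0; i < Q; ++i) {
    double x = wrap01(pts(i, 0), L), y = wrap01(pts(i, 1), L);
    int found = 0;
    for (int q = 0; q < T && !found; ++q) {
      double vx[3] = { tri_coords(q, 0), tri_coords(q, 2), tri_coords(q, 4) };
      double vy[3] = { tri_coords(q, 1), tri_coords(q, 3), tri_coords(q, 5) };
      if (orientp(vx[0], vy[0], vx[1], vy[1], vx[2], vy[2]) < 0.0) {
        std::swap(vx[1], vx[2]);
        std::swap(vy[1], vy[2]);
      }
      for (int sy = -1; sy <= 1 && !found; ++sy)
        for (int sx = -1; sx <= 1 && !found; ++sx) {
          double qx = x + L * sx, qy = y + L * sy;
          if (orientp(vx[0], vy[0], vx[1], vy[1], qx, qy) >= 0.0 &&
              orientp(vx[1], vy[1], vx[2], vy[2], qx, qy) >= 0.0 &&
              orientp(vx[2], vy[2], vx[0], vy[0], qx, qy) >= 0.0)
            found = q + 1;
        }
    }
    out[i] = found;
  }
  return out;
}
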