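#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include "rng.h"
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Planar Bowyer-Watson Delaunay triangulation, then a periodic (torus)
// triangulation extracted from a margin-tiled copy of the point set:
// every periodic Delaunay triangle has exactly one image whose circumcentre
// falls in the central cell [0,L)^2, so those images form the torus
// tessellation. Correctness is verified structurally (Euler relation
// T = 2N, every periodic edge shared by exactly two triangles, circumdiscs
// contained in the tiled domain); on failure the margin is enlarged.
// ---------------------------------------------------------------------------

namespace {

struct Tri {
  int v[3];    // vertex indices, CCW
  int adj[3];  // adj[k] shares the edge opposite v[k]; -1 if none
  bool alive;
};

inline double orient2d(double ax, double ay, double bx, double by,
                       double cx, double cy) {
  return (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
}

// > 0 iff d lies inside the circumcircle of CCW triangle (a, b, c)
inline double incircle(double ax, double ay, double bx, double by,
                       double cx, double cy, double dx, double dy) {
  double adx = ax - dx, ady = ay - dy;
  double bdx = bx - dx, bdy = by - dy;
  double cdx = cx - dx, cdy = cy - dy;
  double ad = adx * adx + ady * ady;
  double bd = bdx * bdx + bdy * bdy;
  double cd = cdx * cdx + cdy * cdy;
  return adx * (bdy * cd - bd * cdy)
       - ady * (bdx * cd - bd * cdx)
       + ad  * (bdx * cdy - bdy * cdx);
}

class Delaunay {
public:
  std::vector<double> px, py;
  std::vector<Tri> tris;
  int n_real;
  int last_tri;
  std::vector<int> mark;   // conflict-cavity stamps, grown lazily
  int stamp_val;

  // pts are already scaled to O(1) coordinates by the caller
  void build(const std::vector<double> &x, const std::vector<double> &y) {
    n_real = (int)x.size();
    px = x; py = y;
    double lo = 1e300, hi = -1e300;
    for (int i = 0; i < n_real; ++i) {
      lo = std::min(lo, std::min(px[i], py[i]));
      hi = std::max(hi, std::max(px[i], py[i]));
    }
    double span = std::max(hi - lo, 1.0), cx = 0.5 * (lo + hi);
    // super-triangle well outside all points
    double R = 40.0 * span;
    px.push_back(cx - 2.0 * R); py.push_back(cx - R);
    px.push_back(cx + 2.0 * R); py.push_back(cx - R);
    px.push_back(cx);           py.push_back(cx + 2.0 * R);
    int s0 = n_real, s1 = n_real + 1, s2 = n_real + 2;
    tris.clear();
    tris.reserve(2 * n_real + 16);
    Tri t0; t0.v[0] = s0; t0.v[1] = s1; t0.v[2] = s2;
    t0.adj[0] = t0.adj[1] = t0.adj[2] = -1; t0.alive = true;
    tris.push_back(t0);
    last_tri = 0;
    mark.assign(2 * n_real + 16, 0);
    stamp_val = 0;

    // deterministic pseudo-shuffled insertion order for balanced walks
    std::vector<int> order(n_real);
    for (int i = 0; i < n_real; ++i) order[i] = i;
    Xoshiro rng(0x5bd1e995u);
    for (int i = n_real - 1; i > 0; --i) {
      int j = rng.unif_int(i + 1);
      std::swap(order[i], order[j]);
    }
    for (int i = 0; i < n_real; ++i) insert_point(order[i]);
  }

  bool tri_is_real(const Tri &t) const {
    return t.v[0] < n_real && t.v[1] < n_real && t.v[2] < n_real;
  }

private:
  int locate(double x, double y) {
    int cur = last_tri, prev = -1;
    for (int guard = 0; guard < (int)tris.size() * 4 + 64; ++guard) {
      const Tri &t = tris[cur];
      int next = -1;
      for (int k = 0; k < 3; ++k) {
        int a = t.v[(k + 1) % 3], b = t.v[(k + 2) % 3];
        if (orient2d(px[a], py[a], px[b], py[b], x, y) < 0.0) {
          if (t.adj[k] != -1 && t.adj[k] != prev) { next = t.adj[k]; break; }
          if (t.adj[k] != -1) next = t.adj[k];
        }
      }
      if (next == -1) return cur;
      prev = cur; cur = next;
    }
    Rcpp::stop("Delaunay point location failed to converge");
  }

  inline bool in_circum(int ti, double x, double y) const {
    const Tri &t = tris[ti];
    return incircle(px[t.v[0]], py[t.v[0]], px[t.v[1]], py[t.v[1]],
                    px[t.v[2]], py[t.v[2]], x, y) > 0.0;
  }

  void insert_point(int p) {
    double x = px[p], y = py[p];
    int t0 = locate(x, y);

    // grow the conflict cavity by BFS (timestamped marks, no reallocation)
    ++stamp_val;
    if (mark.size() < tris.size() + 8) mark.resize(tris.size() * 2 + 16, 0);
    std::vector<int> bad;
    std::vector<int> stack = { t0 };
    mark[t0] = stamp_val;
    while (!stack.empty()) {
      int ti = stack.back(); stack.pop_back();
      bad.push_back(ti);
      for (int k = 0; k < 3; ++k) {
        int nb = tris[ti].adj[k];
        if (nb != -1 && mark[nb] != stamp_val && in_circum(nb, x, y)) {
          mark[nb] = stamp_val;
          stack.push_back(nb);
        }
      }
    }

    // cavity boundary: directed edges (a -> b), interior on the left
    struct BEdge { int a, b, outer; };
    std::vector<BEdge> boundary;
    for (size_t bi = 0; bi < bad.size(); ++bi) {
      const Tri &t = tris[bad[bi]];
      for (int k = 0; k < 3; ++k) {
        int nb = t.adj[k];
        if (nb == -1 || mark[nb] != stamp_val) {
          BEdge e;
          e.a = t.v[(k + 1) % 3];
          e.b = t.v[(k + 2) % 3];
          e.outer = nb;
          boundary.push_back(e);
        }
      }
    }
    for (size_t bi = 0; bi < bad.size(); ++bi) tris[bad[bi]].alive = false;

    // fan of new triangles (p, a, b)
    std::unordered_map<int, int> by_first;  // boundary edge start vertex -> new tri
    std::unordered_map<int, int> by_second;
    std::vector<int> fresh(boundary.size());
    for (size_t bi = 0; bi < boundary.size(); ++bi) {
      Tri nt;
      nt.v[0] = p; nt.v[1] = boundary[bi].a; nt.v[2] = boundary[bi].b;
      nt.adj[0] = boundary[bi].outer;  // opposite p: the boundary edge itself
      nt.adj[1] = nt.adj[2] = -1;
      nt.alive = true;
      int id;
      id = (int)tris.size(); tris.push_back(nt);
      fresh[bi] = id;
      by_first[boundary[bi].a] = id;
      by_second[boundary[bi].b] = id;
      // fix the outer triangle's adjacency to point at the new triangle
      int outer = boundary[bi].outer;
      if (outer != -1) {
        Tri &ot = tris[outer];
        for (int k = 0; k < 3; ++k) {
          int a = ot.v[(k + 1) % 3], b = ot.v[(k + 2) % 3];
          if ((a == boundary[bi].b && b == boundary[bi].a)) ot.adj[k] = id;
        }
      }
    }
    // internal adjacency around the fan: edge (p, a) of tri (p,a,b) pairs
    // with the fan triangle whose boundary edge ends at a
    for (size_t bi = 0; bi < boundary.size(); ++bi) {
      int id = fresh[bi];
      Tri &t = tris[id];
      // edge opposite v[2]=b is (p, a): neighbour has second vertex == a
      std::unordered_map<int, int>::iterator it = by_second.find(boundary[bi].a);
      if (it != by_second.end()) t.adj[2] = it->second;
      // edge opposite v[1]=a is (b, p): neighbour has first vertex == b
      it = by_first.find(boundary[bi].b);
      if (it != by_first.end()) t.adj[1] = it->second;
    }
    last_tri = fresh.empty() ? last_tri : fresh[0];
  }
};

inline void circumcentre(double ax, double ay, double bx, double by,
                         double cx, double cy, double &ox, double &oy) {
  double d = 2.0 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by));
  double a2 = ax * ax + ay * ay, b2 = bx * bx + by * by, c2 = cx * cx + cy * cy;
  ox = (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d;
  oy = (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d;
}

// pack a canonical periodic edge key: point indices < 2^24, shifts in [-4,4]
inline uint64_t edge_key(int i, int j, int dx, int dy) {
  return ((uint64_t)(uint32_t)i << 40) | ((uint64_t)(uint32_t)j << 16)
       | ((uint64_t)(uint32_t)(dx + 8) << 8) | (uint64_t)(uint32_t)(dy + 8);
}

} // namespace

// Periodic Delaunay tessellation of points in [0, L)^2.
// Returns triangles (1-based original indices), their image coordinates,
// and the periodic edge list with wrap offsets.
// [[Rcpp::export(rng = false)]]
List periodic_delaunay_cpp(NumericMatrix pts, double L, double margin0,
                           double jitter_scale, double jitter_seed) {
  int N = pts.nrow();
  if (N < 3) stop("need at least 3 points to tessellate");

  // deterministic symbolic jitter per original point (same for all images)
  // to break co-circular degeneracies
  std::vector<double> jx(N), jy(N);
  for (int i = 0; i < N; ++i) {
    Xoshiro r((uint64_t)jitter_seed * 2654435761ULL + (uint64_t)i + 1ULL);
    jx[i] = pts(i, 0) + jitter_scale * (2.0 * r.unif() - 1.0);
    jy[i] = pts(i, 1) + jitter_scale * (2.0 * r.unif() - 1.0);
  }

  double margin = margin0;
  const double margin_cap = 2.0 * L;
  std::string fail = "";

  for (int attempt = 0; attempt < 8; ++attempt) {
    if (margin > margin_cap) margin = margin_cap;
    int smax = (int)std::ceil(margin / L);
    double lo = -margin, hi = L + margin;

    std::vector<double> tx, ty;
    std::vector<int> orig, shx, shy;
    for (int i = 0; i < N; ++i) {
      for (int sy = -smax; sy <= smax; ++sy) {
        for (int sx = -smax; sx <= smax; ++sx) {
          double x = jx[i] + L * sx, y = jy[i] + L * sy;
          if (x >= lo && x < hi && y >= lo && y < hi) {
            tx.push_back(x); ty.push_back(y);
            orig.push_back(i); shx.push_back(sx); shy.push_back(sy);
          }
        }
      }
    }

    Delaunay dt;
    dt.build(tx, ty);

    // collect triangles whose circumcentre lies in the central cell
    std::vector<int> keep;
    std::vector<double> ccx, ccy, ccr;
    bool margin_ok = true;
    for (size_t ti = 0; ti < dt.tris.size(); ++ti) {
      const Tri &t = dt.tris[ti];
      if (!t.alive || !dt.tri_is_real(t)) continue;
      double ox, oy;
      circumcentre(tx[t.v[0]], ty[t.v[0]], tx[t.v[1]], ty[t.v[1]],
                   tx[t.v[2]], ty[t.v[2]], ox, oy);
      if (ox >= 0.0 && ox < L && oy >= 0.0 && oy < L) {
        double dx = tx[t.v[0]] - ox, dy = ty[t.v[0]] - oy;
        double r = std::sqrt(dx * dx + dy * dy);
        keep.push_back((int)ti);
        ccx.push_back(ox); ccy.push_back(oy); ccr.push_back(r);
        // the whole circumdisc must lie inside the tiled domain, else a
        // conflicting image point may be missing
        if (margin < margin_cap &&
            (ox - r < lo || ox + r >= hi || oy - r < lo || oy + r >= hi))
          margin_ok = false;
      }
    }

    if (!margin_ok) { fail = "circumdisc outside tiled domain"; margin *= 1.6; continue; }
    if ((int)keep.size() != 2 * N) {
      fail = "triangle count != 2N";
      margin *= 1.6;
      continue;
    }
    int T = (int)keep.size();

    // periodic edge pairing
    struct Half { int tri, side, sa_x, sa_y; };
    std::unordered_map<uint64_t, std::vector<Half>> emap;
    emap.reserve(3 * T);
    for (int q = 0; q < T; ++q) {
      const Tri &t = dt.tris[keep[q]];
      for (int k = 0; k < 3; ++k) {
        int u = t.v[(k + 1) % 3], v = t.v[(k + 2) % 3];
        int iu = orig[u], iv = orig[v];
        int dx = shx[v] - shx[u], dy = shy[v] - shy[u];
        // canonical: smaller original index first; ties by offset sign
        int ci, cj, cdx, cdy, sa_x, sa_y;
        bool flip;
        if (iu < iv) flip = false;
        else if (iu > iv) flip = true;
        else flip = (dx < 0) || (dx == 0 && dy < 0);
        if (!flip) { ci = iu; cj = iv; cdx = dx;  cdy = dy;  sa_x = shx[u]; sa_y = shy[u]; }
        else       { ci = iv; cj = iu; cdx = -dx; cdy = -dy; sa_x = shx[v]; sa_y = shy[v]; }
        Half h; h.tri = q; h.side = k; h.sa_x = sa_x; h.sa_y = sa_y;
        emap[edge_key(ci, cj, cdx, cdy)].push_back(h);
      }
    }
    bool pair_ok = true;
    for (std::unordered_map<uint64_t, std::vector<Half>>::iterator it = emap.begin();
         it != emap.end(); ++it)
      if (it->second.size() != 2) { pair_ok = false; break; }
    if (!pair_ok) { fail = "periodic edge not shared by exactly 2 triangles"; margin *= 1.6; continue; }

    // assemble outputs
    IntegerMatrix tri_idx(T, 3);
    NumericMatrix tri_coords(T, 6);
    NumericVector tri_area(T);
    for (int q = 0; q < T; ++q) {
      const Tri &t = dt.tris[keep[q]];
      for (int k = 0; k < 3; ++k) {
        tri_idx(q, k) = orig[t.v[k]] + 1;
        tri_coords(q, 2 * k)     = tx[t.v[k]];
        tri_coords(q, 2 * k + 1) = ty[t.v[k]];
      }
      tri_area[q] = 0.5 * std::fabs(orient2d(tri_coords(q,0), tri_coords(q,1),
                                             tri_coords(q,2), tri_coords(q,3),
                                             tri_coords(q,4), tri_coords(q,5)));
    }

    int E = (int)emap.size();
    IntegerMatrix e_tri(E, 4);   // tri1, side1, tri2, side2 (1-based)
    IntegerMatrix e_off(E, 2);   // wrap offset: pi(tri2) - pi(tri1)
    NumericVector e_len(E);
    NumericMatrix e_coords(E, 4);
    int ei = 0;
    for (std::unordered_map<uint64_t, std::vector<Half>>::iterator it = emap.begin();
         it != emap.end(); ++it, ++ei) {
      const Half &h1 = it->second[0], &h2 = it->second[1];
      e_tri(ei, 0) = h1.tri + 1; e_tri(ei, 1) = h1.side + 1;
      e_tri(ei, 2) = h2.tri + 1; e_tri(ei, 3) = h2.side + 1;
      e_off(ei, 0) = h1.sa_x - h2.sa_x;
      e_off(ei, 1) = h1.sa_y - h2.sa_y;
      const Tri &t = dt.tris[keep[h1.tri]];
      int u = t.v[(h1.side + 1) % 3], v = t.v[(h1.side + 2) % 3];
      double ax = tx[u], ay = ty[u], bx = tx[v], by = ty[v];
      e_coords(ei, 0) = ax; e_coords(ei, 1) = ay;
      e_coords(ei, 2) = bx; e_coords(ei, 3) = by;
      e_len[ei] = std::sqrt((ax - bx) * (ax - bx) + (ay - by) * (ay - by));
    }

    return List::create(_["tri"] = tri_idx,
                        _["tri_coords"] = tri_coords,
                        _["tri_area"] = tri_area,
                        _["edge_tri"] = e_tri,
                        _["edge_offset"] = e_off,
                        _["edge_length"] = e_len,
                        _["edge_coords"] = e_coords,
                        _["margin"] = margin);
  }
  stop("periodic Delaunay failed (%s) even at margin cap; degenerate input?",
       fail.c_str());
  return List::create(); // not reached
}

// Wrapping-cluster detection: union-find over triangles joined by passable
// edges, with integer displacement bookkeeping; a constraint violation in
// axis k means some cluster wraps the torus in that axis.
// [[Rcpp::export(rng = false)]]
LogicalVector wrap_clusters_cpp(int n_tri, IntegerVector tri1, IntegerVector tri2,
                                IntegerMatrix offset, LogicalVector passable) {
  // weighted union-find: d[x] = pi(x) - pi(parent(x)) in units of L per axis
  std::vector<int> parent(n_tri), dx(n_tri, 0), dy(n_tri, 0);
  for (int i = 0; i < n_tri; ++i) parent[i] = i;
  bool wrap_x = false, wrap_y = false;

  // find root of x; on return dax/day hold pi(x) - pi(root); compresses path
  auto find = [&](int x, int &dax, int &day) -> int {
    int root = x;
    while (parent[root] != root) root = parent[root];
    int cx = 0, cy = 0, cur = x;
    while (parent[cur] != cur) { cx += dx[cur]; cy += dy[cur]; cur = parent[cur]; }
    dax = cx; day = cy;
    cur = x;
    while (parent[cur] != cur) {
      int nxt = parent[cur], odx = dx[cur], ody = dy[cur];
      parent[cur] = root; dx[cur] = cx; dy[cur] = cy;
      cx -= odx; cy -= ody;
      cur = nxt;
    }
    return root;
  };

  for (int e = 0; e < tri1.size(); ++e) {
    if (!passable[e]) continue;
    int a = tri1[e] - 1, b = tri2[e] - 1;
    int ox = offset(e, 0), oy = offset(e, 1);
    int dax, day, dbx, dby;
    int ra = find(a, dax, day);
    int rb = find(b, dbx, dby);
    if (ra == rb) {
      // constraint pi(b) - pi(a) = (ox, oy); a violation closes a loop
      // around the torus in that axis
      if (dbx - dax != ox) wrap_x = true;
      if (dby - day != oy) wrap_y = true;
    } else {
      // attach ra under rb such that the constraint holds:
      // pi(ra) - pi(rb) = (pi(b) - dbx) ... rearranged below
      parent[ra] = rb;
      dx[ra] = dbx - ox - dax;
      dy[ra] = dby - oy - day;
    }
  }
  return LogicalVector::create(wrap_x, wrap_y);
}
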