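#include <Rcpp.h>
#include <vector>
#include <cmath>
#include "cell_list.h"
using namespace Rcpp;

// Independent validation oracle for percolation: rasterise the
// tracer-accessible void space (points >= sigma from every obstacle centre)
// on an h-spaced grid and detect torus-wrapping connected components by
// BFS with unwrapped integer coordinates. Shares no code path with the
// Delaunay/union-find detector.
// [[Rcpp::export(rng = false)]]
LogicalVector grid_wrap_cpp(NumericMatrix obstacles, double L, double sigma,
                            double h) {
  int n = (int)std::round(L / h);
  if (n < 4) stop("grid too coarse");
  double cw = L / n;
  int N = obstacles.nrow();
  CellList cl(L, sigma);
  for (int j = 0; j < N; ++j) cl.insert(j, obstacles(j, 0), obstacles(j, 1));
  std::vector<char> acc((size_t)n * n, 0);
  double s2 = sigma * sigma;
  for (int iy = 0; iy < n; ++iy) {
    double y = (iy + 0.5) * cw;
    for (int ix = 0; ix < n; ++ix) {
      double x = (ix + 0.5) * cw;
      bool ok = true;
      cl.for_neighbours(x, y, [&](int j) {
        if (!ok) return;
        double dx = min_image(x - obstacles(j, 0), L);
        double dy = min_image(y - obstacles(j, 1), L);
        if (dx * dx + dy * dy < s2) ok = false;
      });
      acc[(size_t)iy * n + ix] = ok ? 1 : 0;
    }
  }

  // BFS over accessible cells; store unwrapped (ux, uy); a neighbour already
  // visited with a different unwrapped coordinate reveals a wrap
  std::vector<int> ux((size_t)n * n, INT_MIN), uy((size_t)n * n, INT_MIN);
  std::vector<int> queue;
  bool wrap_x = false, wrap_y = false;
  const int ddx[4] = { 1, -1, 0, 0 }, ddy[4] = { 0, 0, 1, -1 };
  for (int start = 0; start < n * n; ++start) {
    if (!acc[start] || ux[start] != INT_MIN) continue;
    queue.clear();
    queue.push_back(start);
    ux[start] = start % n; uy[start] = start / n;
    size_t head = 0;
    while (head < queue.size()) {
      int cur = queue[head++];
      int cx = cur % n, cy = cur / n;
      for (int d = 0; d < 4; ++d) {
        int nx = cx + ddx[d], ny = cy + ddy[d];
        int wxs = 0, wys = 0;
        if (nx < 0) { nx += n; wxs = -1; } else if (nx >= n) { nx -= n; wxs = 1; }
        if (ny < 0) { ny += n; wys = -1; } else if (ny >= n) { ny -= n; wys = 1; }
        int id = ny * n + nx;
        if (!acc[id]) continue;
        int eux = ux[cur] + ddx[d], euy = uy[cur] + ddy[d];
        if (ux[id] == INT_MIN) {
          ux[id] = eux; uy[id] = euy;
          queue.push_back(id);
        } else {
          if (ux[id] != eux) wrap_x = true;
          if (uy[id] != euy) wrap_y = true;
        }
        (void)wxs; (void)wys;
      }
    }
    if (wrap_x && wrap_y) break;
  }
  return LogicalVector::create(wrap_x, wrap_y);
}
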