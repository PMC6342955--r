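#ifndef CROWDPERC_CELL_LIST_H
#define CROWDPERC_CELL_LIST_H

#include <vector>
#include <cmath>

// Periodic cell list over [0, L)^2 for neighbour queries among disc centres.
// Cell width >= w_min so that any centre within w_min of a query point lies
// in the 3x3 block of cells around it.
struct CellList {
  double L, cell_w;
  int n_cells;                       // per axis
  std::vector<std::vector<int>> cells;

  CellList(double L_, double w_min) : L(L_) {
    n_cells = (int)std::floor(L / w_min);
    if (n_cells < 1) n_cells = 1;
    if (n_cells > 3) {
      // fine; 3x3 block query is valid because cell_w >= w_min
    }
    cell_w = L / n_cells;
    cells.assign((size_t)n_cells * n_cells, {});
  }

  inline int cell_index(double x, double y) const {
    int cx = (int)std::floor(x / cell_w);
    int cy = (int)std::floor(y / cell_w);
    if (cx >= n_cells) cx = n_cells - 1;
    if (cy >= n_cells) cy = n_cells - 1;
    if (cx < 0) cx = 0;
    if (cy < 0) cy = 0;
    return cy * n_cells + cx;
  }

  inline void insert(int id, double x, double y) {
    cells[cell_index(x, y)].push_back(id);
  }

  // visit ids in the 3x3 periodic block around (x, y); x, y in [0, L)
  template <class F>
  inline void for_neighbours(double x, double y, F f) const {
    int cx = (int)std::floor(x / cell_w);
    int cy = (int)std::floor(y / cell_w);
    if (cx >= n_cells) cx = n_cells - 1;
    if (cy >= n_cells) cy = n_cells - 1;
    if (cx < 0) cx = 0;
    if (cy < 0) cy = 0;
    for (int dy = -1; dy <= 1; ++dy) {
      for (int dx = -1; dx <= 1; ++dx) {
        int ix = cx + dx, iy = cy + dy;
        if (ix < 0) ix += n_cells; else if (ix >= n_cells) ix -= n_cells;
        if (iy < 0) iy += n_cells; else if (iy >= n_cells) iy -= n_cells;
        const std::vector<int> &v = cells[(size_t)iy * n_cells + ix];
        for (size_t k = 0; k < v.size(); ++k) f(v[k]);
      }
    }
  }
};

// minimum-image displacement component on a torus of size L
inline double min_image(double d, double L) {
  if (d > 0.5 * L) d -= L;
  else if (d < -0.5 * L) d += L;
  return d;
}

#endif
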