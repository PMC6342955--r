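#include <Rcpp.h>
#include "rng.h"
#include "cell_list.h"
using namespace Rcpp;

// Random sequential adsorption of N non-overlapping discs of diameter sigma
// in a periodic box [0, L)^2. Returns an N x 2 matrix of centres.
// [[Rcpp::export(rng = false)]]
NumericMatrix rsa_generate_cpp(int N, double L, double sigma, double seed,
                               double max_attempts) {
  Xoshiro rng((uint64_t)seed);
  NumericMatrix out(N, 2);
  if (N == 0) return out;
  CellList cl(L, sigma);
  std::vector<double> px(N), py(N);
  const double s2 = sigma * sigma;
  for (int i = 0; i < N; ++i) {
    double attempts = 0;
    for (;;) {
      if (attempts >= max_attempts)
        stop("RSA saturation: failed to place disc %d of %d after %.0f attempts (phi too high?)",
             i + 1, N, max_attempts);
      ++attempts;
      double x = rng.unif() * L, y = rng.unif() * L;
      bool ok = true;
      cl.for_neighbours(x, y, [&](int j) {
        if (!ok) return;
        double dx = min_image(x - px[j], L);
        double dy = min_image(y - py[j], L);
        if (dx * dx + dy * dy < s2) ok = false;
      });
      if (ok) {
        px[i] = x; py[i] = y;
        cl.insert(i, x, y);
        break;
      }
    }
  }
  for (int i = 0; i < N; ++i) { out(i, 0) = px[i]; out(i, 1) = py[i]; }
  return out;
}

// Place n tracers of diameter sigma so that they overlap neither the matrix
// discs nor (at placement only) each other.
// [[Rcpp::export(rng = false)]]
NumericMatrix place_tracers_cpp(NumericMatrix obstacles, int n_tracers,
                                double L, double sigma, double seed,
                                double max_attempts) {
  Xoshiro rng((uint64_t)seed);
  int N = obstacles.nrow();
  NumericMatrix out(n_tracers, 2);
  const double s2 = sigma * sigma;
  CellList cl(L, sigma);
  for (int j = 0; j < N; ++j) cl.insert(j, obstacles(j, 0), obstacles(j, 1));
  std::vector<double> tx, ty;
  for (int i = 0; i < n_tracers; ++i) {
    double attempts = 0;
    for (;;) {
      if (attempts >= max_attempts)
        stop("tracer placement failed after %.0f attempts (no accessible void space?)",
             max_attempts);
      ++attempts;
      double x = rng.unif() * L, y = rng.unif() * L;
      bool ok = true;
      cl.for_neighbours(x, y, [&](int j) {
        if (!ok) return;
        double dx = min_image(x - obstacles(j, 0), L);
        double dy = min_image(y - obstacles(j, 1), L);
        if (dx * dx + dy * dy < s2) ok = false;
      });
      if (ok) {
        for (size_t j = 0; j < tx.size() && ok; ++j) {
          double dx = min_image(x - tx[j], L);
          double dy = min_image(y - ty[j], L);
          if (dx * dx + dy * dy < s2) ok = false;
        }
      }
      if (ok) {
        tx.push_back(x); ty.push_back(y);
        out(i, 0) = x; out(i, 1) = y;
        break;
      }
    }
  }
  return out;
}

// Raw pair-distance histogram (counts of ordered pairs per bin) for g(r);
// normalisation is done in R. Brute-force minimum-image pair scan.
// [[Rcpp::export(rng = false)]]
NumericVector pair_histogram_cpp(NumericMatrix pts, double L, double dr,
                                 double r_max) {
  int N = pts.nrow();
  int nb = (int)std::ceil(r_max / dr);
  NumericVector h(nb);
  for (int i = 0; i < N; ++i) {
    for (int j = i + 1; j < N; ++j) {
      double dx = min_image(pts(i, 0) - pts(j, 0), L);
      double dy = min_image(pts(i, 1) - pts(j, 1), L);
      double r = std::sqrt(dx * dx + dy * dy);
      if (r < r_max) {
        int b = (int)(r / dr);
        if (b >= 0 && b < nb) h[b] += 2.0; // ordered pairs
      }
    }
  }
  return h;
}

// O(N^2) minimum-image nearest pair distance (validation helper).
// [[Rcpp::export(rng = false)]]
double min_pair_distance_cpp(NumericMatrix pts, double L) {
  int N = pts.nrow();
  double best = R_PosInf;
  for (int i = 0; i < N; ++i)
    for (int j = i + 1; j < N; ++j) {
      double dx = min_image(pts(i, 0) - pts(j, 0), L);
      double dy = min_image(pts(i, 1) - pts(j, 1), L);
      double d2 = dx * dx + dy * dy;
      if (d2 < best) best = d2;
    }
  return std::sqrt(best);
}
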