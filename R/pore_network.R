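#' Channel gap of a Delaunay edge
#'
#' The clearance available to the tracer centre across a channel whose
#' Delaunay edge has centre-to-centre length `l`: `g = l - 2 * sigma`, where
#' `2 * sigma` is the sum of the obstacle and tracer diameters. A channel is
#' passable only when `g > 0`.
#'
#' @param l edge length (centre-to-centre distance of the two obstacles).
#' @param sigma disc diameter.
#' @return the gap `g`; negative values mean the channel is impassable.
#' @export
#' @examples
#' channel_gap(2.5, 1)  # 0.5
channel_gap <- function(l, sigma = 1) {
  stopifnot(all(l > 0))
  l - 2 * sigma
}

#' Tessellate the void space into a periodic pore network
#'
#' Builds the Delaunay triangulation of the obstacle centres on the torus.
#' Each triangle is a pore; each edge is a channel whose gap
#' `g = l - 2 * sigma` decides passability. Internally the point set is
#' tiled with periodic images inside an adaptive margin, triangulated with a
#' Bowyer-Watson kernel, and the torus tessellation is extracted as the
#' triangles whose circumcentre falls in the central cell; the result is
#' verified structurally (Euler relation `T = 2N`, `E = 3T/2`, every
#' periodic edge shared by exactly two triangles). Co-circular degeneracies
#' (e.g. lattice configurations) are broken by a deterministic jitter of
#' `1e-10 * sigma` keyed on the matrix seed.
#'
#' @param matrix an [obstacle_matrix][generate_matrix] with `N >= 3`.
#' @return an object of class `pore_network`: a list with
#'   \describe{
#'     \item{triangles}{T x 3 matrix of obstacle indices per pore.}
#'     \item{tri_coords}{T x 6 matrix of the image coordinates actually
#'       used for each pore's vertices (x1,y1,x2,y2,x3,y3).}
#'     \item{tri_area}{pore (triangle) areas; they sum to `L^2`.}
#'     \item{A}{accessible area per pore (see [accessible_area()]).}
#'     \item{edges}{data frame of channels: the two incident pores
#'       (`tri1`, `side1`, `tri2`, `side2`), the edge `length`, the `gap`,
#'       logical `passable`, and the integer wrap offsets `ox`, `oy` used by
#'       the percolation detector.}
#'     \item{edge_coords}{E x 4 matrix of one periodic image of each edge.}
#'     \item{L, sigma, N}{geometry of the underlying matrix.}
#'   }
#' @export
tessellate <- function(matrix) {
  if (matrix$N < 3) stop("need at least 3 obstacles to tessellate")
  L <- matrix$L
  rho <- matrix$N / L^2
  margin0 <- min(max(8 * matrix$sigma, 4 / sqrt(rho)), 2 * L)
  seed <- if (is.null(matrix$seed) || is.na(matrix$seed)) 0 else matrix$seed
  raw <- periodic_delaunay_cpp(matrix$positions, L, margin0,
                               1e-10 * matrix$sigma, as.double(seed))
  gap <- channel_gap(raw$edge_length, matrix$sigma)
  edges <- data.frame(
    tri1 = raw$edge_tri[, 1], side1 = raw$edge_tri[, 2],
    tri2 = raw$edge_tri[, 3], side2 = raw$edge_tri[, 4],
    length = raw$edge_length, gap = gap, passable = gap > 0,
    ox = raw$edge_offset[, 1], oy = raw$edge_offset[, 2])
  structure(
    list(triangles = raw$tri, tri_coords = raw$tri_coords,
         tri_area = as.numeric(raw$tri_area),
         A = as.numeric(accessible_area_cpp(raw$tri_coords, matrix$sigma)),
         edges = edges, edge_coords = raw$edge_coords,
         L = L, sigma = matrix$sigma, N = matrix$N),
    class = "pore_network")
}

#' @export
print.pore_network <- function(x, ...) {
  cat(sprintf(
    "<pore_network> %d pores, %d channels (%.1f%% passable), L = %g\n",
    nrow(x$triangles), nrow(x$edges), 100 * mean(x$edges$passable), x$L))
  invisible(x)
}

#' Accessible area of a pore
#'
#' The area of a Delaunay triangle that the tracer centre can occupy: the
#' triangle minus its intersection with the three exclusion discs of radius
#' `sigma` centred at the vertices (obstacle centres). Computed exactly by
#' Green's theorem over the clipped boundary, so overlapping exclusion discs
#' and discs reaching past the opposite edge are handled; when each disc
#' meets the triangle only in the corner sector the result reduces to
#' `area - pi * sigma^2 / 2`. Clamped at zero.
#'
#' @param vertices either a 3 x 2 matrix (one triangle) or a T x 6 matrix of
#'   row-wise vertex coordinates.
#' @param sigma exclusion radius (disc diameter; tracer and obstacle radii
#'   sum to `sigma`).
#' @return accessible area(s), in units of `sigma^2`.
#' @export
#' @examples
#' eq <- 3 * rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
#' accessible_area(eq, 1)  # (sqrt(3)/4)*9 - pi/2
accessible_area <- function(vertices, sigma = 1) {
  if (is.matrix(vertices) && ncol(vertices) == 2 && nrow(vertices) == 3)
    vertices <- matrix(as.vector(t(vertices)), nrow = 1)
  stopifnot(is.matrix(vertices), ncol(vertices) == 6)
  as.numeric(accessible_area_cpp(vertices, sigma))
}

#' Distribution of channel gaps
#'
#' Normalised density of the gap `g` over passable channels (`g > 0`);
#' impassable channels are reported separately as an attribute. The gap
#' distribution is a property of the matrix ensemble alone: it does not
#' depend on any dynamical parameter.
#'
#' @param network a [pore_network][tessellate] (or list of them, pooled).
#' @param bin_width histogram bin width in units of sigma.
#' @return a data frame with bin centres `g`, `density` (integrating to 1
#'   over `g > 0`), and `count`; attribute `impassable_fraction` gives the
#'   fraction of channels with `g <= 0`.
#' @export
gap_distribution <- function(network, bin_width = 0.02) {
  gaps <- if (inherits(network, "pore_network")) network$edges$gap
          else unlist(lapply(network, function(n) n$edges$gap))
  if (length(gaps) == 0) stop("empty network: no channels")
  pos <- gaps[gaps > 0]
  if (length(pos) == 0) stop("no passable channels")
  breaks <- seq(0, max(pos) + bin_width, by = bin_width)
  h <- graphics::hist(pos, breaks = breaks, plot = FALSE)
  out <- data.frame(g = h$mids, density = h$density, count = h$counts)
  attr(out, "impassable_fraction") <- mean(gaps <= 0)
  out
}

#' Does the pore network wrap the torus?
#'
#' Union-find over pores joined by passable channels, with integer
#' displacement bookkeeping per periodic edge: a cluster that closes on
#' itself with a non-zero net boundary crossing wraps the torus in that
#' axis. A configuration is called percolating when some cluster wraps in
#' at least one axis.
#'
#' @param network a [pore_network][tessellate].
#' @return named logical vector `c(x = , y = )`.
#' @seealso [percolates()]
#' @export
has_wrapping_cluster <- function(network) {
  e <- network$edges
  w <- wrap_clusters_cpp(nrow(network$triangles), e$tri1, e$tri2,
                         cbind(e$ox, e$oy), e$passable)
  setNames(as.logical(w), c("x", "y"))
}

#' @rdname has_wrapping_cluster
#' @export
percolates <- function(network) any(has_wrapping_cluster(network))

#' Monte Carlo estimate of the percolation probability
#'
#' Generates `n_configs` independent matrices at `(phi, L)`, tessellates
#' each, and reports the fraction with a wrapping pore cluster, with its
#' binomial standard error.
#'
#' @param phi area fraction.
#' @param L box edge length.
#' @param n_configs number of independent configurations.
#' @param seed integer seed (each configuration derives its own sub-seed).
#' @param sigma disc diameter.
#' @return one-row data frame `(L, phi, P, se, n_configs)`.
#' @export
percolation_probability <- function(phi, L, n_configs, seed, sigma = 1) {
  stopifnot(n_configs >= 1)
  hits <- 0L
  for (i in seq_len(n_configs)) {
    m <- generate_matrix(phi, L, seed = seed + 1000003 * i, sigma = sigma)
    if (m$N < 3) { hits <- hits + 1L; next }  # dilute: trivially percolating
    if (percolates(tessellate(m))) hits <- hits + 1L
  }
  P <- hits / n_configs
  data.frame(L = L, phi = phi, P = P,
             se = sqrt(P * (1 - P) / n_configs), n_configs = n_configs)
}

#' Percolation probability curve over an area-fraction grid
#'
#' @param phi_values grid of area fractions.
#' @inheritParams percolation_probability
#' @return data frame of class `percolation_curve`, one row per phi.
#' @export
percolation_curve <- function(phi_values, L, n_configs, seed, sigma = 1) {
  rows <- lapply(seq_along(phi_values), function(i)
    percolation_probability(phi_values[i], L, n_configs,
                            seed = seed + 7919 * i, sigma = sigma))
  out <- do.call(rbind, rows)
  class(out) <- c("percolation_curve", class(out))
  out
}

#' Fit the finite-size percolation curve
#'
#' Least-squares fit of `P(phi, L) = (1/2) * (1 + tanh((phi_c(L) - phi) / dphi))`
#' to a measured [percolation_curve()]; by construction the fitted curve has
#' `P(phi_c(L)) = 1/2`.
#'
#' @param curve a `percolation_curve` data frame (single `L`), with at least
#'   4 points bracketing the transition (max P > 0.8, min P < 0.2).
#' @return an object of class `exponent_fit` with `name = "phi_c_L"`,
#'   `value`, `stderr`, the `fit_window` in phi, and metadata (`L`, `dphi`).
#' @export
fit_percolation_curve <- function(curve) {
  stopifnot(length(unique(curve$L)) == 1)
  if (nrow(curve) < 4)
    stop("need at least 4 phi points to fit the transition")
  if (max(curve$P) <= 0.8 || min(curve$P) >= 0.2)
    stop("curve does not bracket the transition (need P > 0.8 and P < 0.2)")
  start_phic <- stats::approx(curve$P, curve$phi, xout = 0.5, ties = mean)$y
  if (is.na(start_phic)) start_phic <- mean(range(curve$phi))
  start_dphi <- max(diff(range(curve$phi)) / 6, 1e-4)
  fit <- minpack.lm::nlsLM(
    P ~ 0.5 * (1 + tanh((phic - phi) / dphi)),
    data = curve,
    start = list(phic = start_phic, dphi = start_dphi),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- summary(fit)$coefficients
  exponent_fit("phi_c_L", est["phic", 1], est["phic", 2],
               fit_window = range(curve$phi),
               metadata = list(L = curve$L[1], dphi = est["dphi", 1],
                               n_configs = curve$n_configs[1]))
}

#' Extrapolate the percolation threshold to infinite size
#'
#' Finite-size thresholds obey `phi_c - phi_c(L) ~ L^(-1/nu)` with
#' `nu = 4/3` in 2D; a linear fit of `phi_c(L)` against `L^(-1/nu)` gives
#' the infinite-system threshold as the intercept.
#'
#' @param fits either a list of `exponent_fit` objects from
#'   [fit_percolation_curve()] or a data frame with columns `L`, `phi_c_L`
#'   and optionally `se`.
#' @param nu correlation-length exponent (default `4/3`).
#' @return an `exponent_fit` with `name = "phi_c"`.
#' @export
extrapolate_phi_c <- function(fits, nu = 4 / 3) {
  if (!is.data.frame(fits)) {
    fits <- data.frame(
      L = vapply(fits, function(f) f$metadata$L, numeric(1)),
      phi_c_L = vapply(fits, function(f) f$value, numeric(1)),
      se = vapply(fits, function(f) f$stderr, numeric(1)))
  }
  if (length(unique(fits$L)) < 3)
    stop("need at least 3 distinct system sizes to extrapolate")
  fits$x <- fits$L^(-1 / nu)
  fit <- lm(phi_c_L ~ x, data = fits)
  est <- summary(fit)$coefficients
  exponent_fit("phi_c", est["(Intercept)", 1], est["(Intercept)", 2],
               fit_window = range(fits$L),
               metadata = list(nu = nu, slope = est["x", 1],
                               L_values = fits$L))
}

#' Estimate the percolation threshold end-to-end
#'
#' Convenience pipeline: measure `P(phi)` on a grid for each system size,
#' fit the tanh form per size, and extrapolate `phi_c(L)` to `L = Inf`.
#'
#' @param L_values system sizes (at least 3).
#' @param n_configs configurations per `(phi, L)` point.
#' @param seed integer seed.
#' @param phi_grids optional named list (names = L values) of phi grids; by
#'   default a grid spanning the finite-size transition window for each L.
#' @param sigma disc diameter.
#' @return a list with the pooled `curves` data frame, per-size `fits`, and
#'   the extrapolated `phi_c` (an `exponent_fit`).
#' @export
estimate_phi_c <- function(L_values, n_configs, seed, phi_grids = NULL,
                           sigma = 1) {
  stopifnot(length(L_values) >= 3)
  curves <- list()
  fits <- list()
  for (i in seq_along(L_values)) {
    L <- L_values[i]
    grid <- if (!is.null(phi_grids)) phi_grids[[as.character(L)]]
            else default_phi_grid(L)
    cur <- percolation_curve(grid, L, n_configs, seed = seed + 104729 * i,
                             sigma = sigma)
    curves[[i]] <- cur
    fits[[i]] <- fit_percolation_curve(cur)
  }
  list(curves = do.call(rbind, curves), fits = fits,
       phi_c = extrapolate_phi_c(fits))
}

# Transition window for the wrapping probability at finite L. The window
# tracks the finite-size transition, whose centre sits slightly above the
# infinite-size threshold for the wrapping criterion and approaches it as
# L^(-1/nu) = L^(-3/4), with a width of a few tanh half-widths so the curve
# brackets P from ~0.99 down to ~0.01.
default_phi_grid <- function(L) {
  centre <- 0.2125 + 0.09 * L^(-3 / 4)
  half_width <- 0.6 * L^(-3 / 4)
  seq(centre - half_width, centre + half_width, length.out = 9)
}
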