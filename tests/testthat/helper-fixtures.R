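# Shared fixtures and independent oracles. Heavy objects are memoised in
# `.fixture_cache` so several test files can reuse one computation.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, compute) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, compute(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# a dense matrix + network near the threshold used by several files
dense_fixture <- function() {
  memo("dense_30", function() {
    m <- generate_matrix(0.21, 30, seed = 9)
    list(matrix = m, network = tessellate(m))
  })
}

# hand-built obstacle matrix from explicit positions
manual_matrix <- function(positions, L, sigma = 1, seed = 0) {
  structure(
    list(positions = positions, L = L, sigma = sigma,
         N = nrow(positions),
         phi = area_fraction(nrow(positions), L, sigma), seed = seed),
    class = "obstacle_matrix")
}

# three obstacles forming an equilateral triangle of side s, far from the
# periodic boundary of a 20-sigma box; the central pore is symmetric
equilateral_fixture <- function(s = 3) {
  pos <- rbind(c(8, 8), c(8 + s, 8), c(8 + s / 2, 8 + s * sqrt(3) / 2))
  m <- manual_matrix(pos, L = 20, seed = 2)
  net <- tessellate(m)
  central <- which.min(abs(net$tri_area - sqrt(3) / 4 * s^2))
  list(matrix = m, network = net, pore = central)
}

# minimum-image distance from each point in `p` (n x 2) to each centre
min_image_dists <- function(p, centres, L) {
  n <- nrow(p)
  out <- matrix(NA_real_, n, nrow(centres))
  for (j in seq_len(nrow(centres))) {
    dx <- p[, 1] - centres[j, 1]; dx <- dx - L * round(dx / L)
    dy <- p[, 2] - centres[j, 2]; dy <- dy - L * round(dy / L)
    out[, j] <- sqrt(dx^2 + dy^2)
  }
  out
}

# Brute-force periodic Delaunay oracle for tiny point sets: triangulate the
# 3x3 image tiling by the empty-circumcircle definition (all triples, all
# other points tested), keep triangles whose circumcentre is in the central
# cell, and return the sorted multiset of edge lengths.
brute_periodic_delaunay_edges <- function(pts, L, tol = 1e-9) {
  sh <- as.matrix(expand.grid(sx = -1:1, sy = -1:1))
  tiled <- do.call(rbind, lapply(seq_len(nrow(sh)), function(k)
    cbind(pts[, 1] + L * sh[k, 1], pts[, 2] + L * sh[k, 2])))
  n <- nrow(tiled)
  circum <- function(a, b, c) {
    d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) + c[1] * (a[2] - b[2]))
    if (abs(d) < 1e-14) return(NULL)
    a2 <- sum(a^2); b2 <- sum(b^2); c2 <- sum(c^2)
    ox <- (a2 * (b[2] - c[2]) + b2 * (c[2] - a[2]) + c2 * (a[2] - b[2])) / d
    oy <- (a2 * (c[1] - b[1]) + b2 * (a[1] - c[1]) + c2 * (b[1] - a[1])) / d
    c(ox, oy)
  }
  edges <- c()
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    cc <- circum(tiled[i, ], tiled[j, ], tiled[k, ])
    if (is.null(cc)) next
    r2 <- sum((tiled[i, ] - cc)^2)
    d2 <- rowSums((tiled - rep(cc, each = n))^2)
    d2[c(i, j, k)] <- Inf
    if (any(d2 < r2 - tol)) next
    if (cc[1] >= 0 && cc[1] < L && cc[2] >= 0 && cc[2] < L) {
      for (pr in list(c(i, j), c(i, k), c(j, k)))
        edges <- c(edges, sqrt(sum((tiled[pr[1], ] - tiled[pr[2], ])^2)))
    }
  }
  sort(edges)
}

# simple union-find cluster labels over passable channels (test oracle for
# pore-cluster membership; ignores wrap offsets)
cluster_labels <- function(network) {
  n <- nrow(network$triangles)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  e <- network$edges
  for (i in which(e$passable)) {
    ra <- find(e$tri1[i]); rb <- find(e$tri2[i])
    if (ra != rb) parent[ra] <- rb
  }
  vapply(seq_len(n), find, integer(1))
}

# inverse-CDF sampler for rho(W) ~ W^-alpha on [a, b] (alpha < 1)
sample_power_law_rates <- function(n, alpha, a = 1e-6, b = 1) {
  u <- runif(n)
  e <- 1 - alpha
  (u * (b^e - a^e) + a^e)^(1 / e)
}
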