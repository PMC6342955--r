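test_that("periodic square lattice tessellates into 8 equal-celled triangles", {
  m <- manual_matrix(rbind(c(1, 1), c(3, 1), c(1, 3), c(3, 3)), L = 4, seed = 5)
  net <- tessellate(m)
  expect_identical(nrow(net$triangles), 8L)
  expect_identical(nrow(net$edges), 12L)
  lens <- sort(round(net$edges$length, 6))
  expect_equal(lens, sort(c(rep(2, 8), rep(2 * sqrt(2), 4))), tolerance = 1e-6)
})

test_that("tessellation satisfies the torus Euler relations on RSA media", {
  for (phi in c(0.06, 0.21)) {
    m <- generate_matrix(phi, 30, seed = 40 + round(100 * phi))
    net <- tessellate(m)
    T_ <- nrow(net$triangles)
    E_ <- nrow(net$edges)
    expect_identical(T_, 2L * m$N)           # N - E + T = 0 with E = 3T/2
    expect_identical(2L * E_, 3L * T_)
    expect_equal(sum(net$tri_area), m$L^2, tolerance = 1e-8)
    # every (pore, side) carries exactly one channel
    g3 <- crowdperc:::pore_side_gaps(net)
    expect_false(anyNA(g3))
  }
})

test_that("tiny periodic triangulations match the brute-force oracle", {
  set.seed(12)
  for (rep in 1:3) {
    pts <- matrix(runif(6, 0, 30), 3, 2)
    # keep points well separated so the configuration is non-degenerate
    if (min(dist(pts)) < 2) next
    m <- manual_matrix(pts, L = 30, seed = rep)
    net <- tessellate(m)
    oracle <- brute_periodic_delaunay_edges(pts, 30)
    ours <- sort(rep(net$edges$length, 2))  # oracle sees both half-edges
    expect_equal(length(ours), length(oracle))
    expect_equal(ours, oracle, tolerance = 1e-6)
  }
})

test_that("channel gap is l - 2 sigma and passability is g > 0", {
  expect_equal(channel_gap(2.5, 1), 0.5)
  expect_equal(channel_gap(2.0, 1), 0.0)
  expect_equal(channel_gap(3.1, 1), 1.1)
  fx <- dense_fixture()
  e <- fx$network$edges
  expect_equal(e$gap, e$length - 2 * fx$network$sigma)
  expect_identical(e$passable, e$gap > 0)
})

test_that("accessible area matches the sector formula and an MC oracle", {
  eq3 <- 3 * rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  expect_equal(accessible_area(eq3, 1), (sqrt(3) / 4) * 9 - pi / 2,
               tolerance = 1e-10)
  eq2 <- 2 * rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  expect_equal(accessible_area(eq2, 1), sqrt(3) - pi / 2, tolerance = 1e-6)
  tiny <- 1.05 * rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  expect_equal(accessible_area(tiny, 1), 0, tolerance = 1e-12)

  # rejection-sampling oracle on random triangles, including overlapping
  # exclusion discs and discs reaching past the opposite edge
  set.seed(7)
  worst_z <- 0
  for (i in 1:100) {
    v <- matrix(runif(6, 0, 3), 3, 2)
    a_ex <- accessible_area(v, 1)
    n <- 20000
    r1 <- sqrt(runif(n)); r2 <- runif(n)
    p <- cbind((1 - r1) * v[1, 1] + r1 * (1 - r2) * v[2, 1] + r1 * r2 * v[3, 1],
               (1 - r1) * v[1, 2] + r1 * (1 - r2) * v[2, 2] + r1 * r2 * v[3, 2])
    free <- rowSums(sapply(1:3, function(k)
      (p[, 1] - v[k, 1])^2 + (p[, 2] - v[k, 2])^2 < 1)) == 0
    tarea <- abs((v[2, 1] - v[1, 1]) * (v[3, 2] - v[1, 2]) -
                 (v[2, 2] - v[1, 2]) * (v[3, 1] - v[1, 1])) / 2
    frac <- mean(free)
    se <- tarea * sqrt(frac * (1 - frac) / n)
    if (se > 0) worst_z <- max(worst_z, abs(a_ex - frac * tarea) / se)
  }
  expect_lt(worst_z, 4.5)
})

test_that("gap distribution is deterministic, normalised, and delta-free", {
  fx <- dense_fixture()
  d1 <- gap_distribution(fx$network)
  d2 <- gap_distribution(tessellate(fx$matrix))
  expect_identical(d1, d2)
  expect_equal(sum(d1$density) * diff(d1$g)[1], 1, tolerance = 1e-6)
  imp <- attr(d1, "impassable_fraction")
  expect_gte(imp, 0); expect_lte(imp, 1)
  # no dynamical argument exists: the density is a pure matrix property
  expect_false("delta" %in% names(formals(gap_distribution)))
})

test_that("wrapping detection agrees with physical limits", {
  m_dilute <- generate_matrix(0.06, 30, seed = 3)
  expect_true(percolates(tessellate(m_dilute)))
  m_dense <- generate_matrix(0.30, 30, seed = 3)
  expect_false(percolates(tessellate(m_dense)))
  # forcing every channel shut disconnects everything
  net <- tessellate(m_dilute)
  net$edges$passable <- FALSE
  expect_false(percolates(net))
})

test_that("wrapping detection agrees with the grid flood-fill oracle", {
  agree <- 0
  n <- 40
  for (i in seq_len(n)) {
    m <- generate_matrix(0.212, 30, seed = 1000 + i)
    a <- percolates(tessellate(m))
    b <- any(crowdperc:::grid_wrap_cpp(m$positions, m$L, m$sigma, 0.015))
    agree <- agree + (a == b)
  }
  expect_gte(agree / n, 0.95)
})

test_that("tanh fit recovers the finite-size transition", {
  phis <- seq(0.193, 0.217, length.out = 9)
  P_true <- 0.5 * (1 + tanh((0.205 - phis) / 0.004))
  noiseless <- data.frame(L = 100, phi = phis, P = P_true, se = 0.01,
                          n_configs = 500)
  f0 <- fit_percolation_curve(noiseless)
  expect_equal(f0$value, 0.205, tolerance = 1e-6)
  expect_equal(f0$metadata$dphi, 0.004, tolerance = 1e-5)
  # fitted curve passes through P = 1/2 at phi_c(L) by construction
  expect_equal(0.5 * (1 + tanh((f0$value - f0$value) / f0$metadata$dphi)), 0.5)

  set.seed(21)
  noisy <- noiseless
  noisy$P <- rbinom(length(phis), 500, P_true) / 500
  f1 <- fit_percolation_curve(noisy)
  expect_lt(abs(f1$value - 0.205), 0.002)

  flat <- data.frame(L = 100, phi = phis, P = rep(0.9, 9), se = 0.01,
                     n_configs = 500)
  expect_error(fit_percolation_curve(flat), "bracket")
})

test_that("finite-size extrapolation recovers the infinite-system threshold", {
  Ls <- c(50, 100, 200, 400)
  exact <- data.frame(L = Ls, phi_c_L = 0.2125 - 0.3 * Ls^(-3 / 4), se = 1e-4)
  f0 <- suppressWarnings(extrapolate_phi_c(exact))
  expect_equal(f0$value, 0.2125, tolerance = 1e-10)
  set.seed(31)
  noisy <- exact
  noisy$phi_c_L <- noisy$phi_c_L + rnorm(4, 0, 5e-4)
  f1 <- extrapolate_phi_c(noisy)
  expect_lt(abs(f1$value - 0.2125), 2e-3)
  expect_error(extrapolate_phi_c(exact[1:2, ]), "3 distinct")
})
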