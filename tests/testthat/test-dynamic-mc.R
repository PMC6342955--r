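test_that("trial moves are uniform per axis with variance delta^2/3", {
  set.seed(1)
  d <- trial_move(2e5, delta = 0.25)
  expect_true(all(abs(d) <= 0.25))
  expect_equal(mean(d[, 1]), 0, tolerance = 3 * 0.25 / sqrt(3 * 2e5))
  expect_equal(var(d[, 1]), 0.25^2 / 3, tolerance = 0.02)
})

test_that("crossing_check finds constructed crossings in parametric order", {
  m <- manual_matrix(rbind(c(1, 1), c(3, 1), c(1, 3), c(3, 3)), L = 4, seed = 5)
  net <- tessellate(m)
  # zero-length move: no crossings
  expect_identical(nrow(crossing_check(c(2, 0.5), c(2, 0.5), net)), 0L)
  # crossing the horizontal lattice edge y = 1 between x = 1 and 3
  cr <- crossing_check(c(2, 0.6), c(2, 1.4), net)
  expect_gte(nrow(cr), 1)
  hit <- net$edges[cr$edge, ]
  expect_true(any(abs(hit$length - 2) < 1e-6))
  expect_true(all(diff(cr$t) >= 0))
  expect_error(crossing_check(c(0, 0), c(2.5, 0), net), "L/2")
})

test_that("crossing counts agree with a sub-stepping point-location oracle", {
  m <- generate_matrix(0.2, 20, seed = 14)
  net <- tessellate(m)
  set.seed(3)
  checked <- 0
  for (i in 1:300) {
    p0 <- runif(2, 2, 18)
    p1 <- p0 + runif(2, -0.8, 0.8)
    cr <- crossing_check(p0, p1, net)
    tt <- seq(0, 1, length.out = 101)
    sub <- cbind(p0[1] + tt * (p1[1] - p0[1]), p0[2] + tt * (p1[2] - p0[2]))
    tri <- crowdperc:::locate_triangle_cpp(sub, net$tri_coords, net$L)
    transitions <- sum(diff(tri[tri > 0]) != 0)
    # each triangle change requires at least one edge crossing
    expect_lte(transitions, nrow(cr))
    if (nrow(cr) == 0) expect_identical(transitions, 0L)
    checked <- checked + 1
  }
  expect_gte(checked, 300)
})

test_that("acceptance rules reject overlaps and geometrically forbidden jumps", {
  # free space: everything is accepted
  m0 <- generate_matrix(0, 50, seed = 1)
  expect_true(accept_move(c(5, 5), c(6, 6), m0, NULL))

  fx <- dense_fixture()
  # a trial position inside an exclusion disc is rejected
  ob <- fx$matrix$positions[1, ]
  expect_false(accept_move(ob + c(2, 0), ob + c(0.3, 0), fx$matrix, fx$network))

  # narrow-channel fixture: all sides have l = 1.9 < 2 sigma, so the pore
  # is sealed; a jump across a side to an overlap-free position is the
  # forbidden move
  s <- 1.9
  pos <- rbind(c(10, 10), c(10 + s, 10), c(10 + s / 2, 10 + s * sqrt(3) / 2))
  m <- manual_matrix(pos, L = 20, seed = 3)
  net <- tessellate(m)
  centroid <- colMeans(pos)
  target <- c(centroid[1], 8.6)   # below the bottom edge, overlap-free
  expect_true(all(min_image_dists(rbind(target), pos, 20) >= 1))
  expect_false(accept_move(centroid, target, m, net))   # rule 2 fires
  # without the channel rule the same move would pass
  expect_true(accept_move(centroid, target, m, NULL))
})

test_that("free-space diffusion recovers D0 = delta^2/6", {
  m0 <- generate_matrix(0, 50, seed = 1)
  p <- sim_params(delta = 2, t_max = 1000, n_tracers = 400, seed = 11)
  run <- run_simulation(m0, NULL, p)
  expect_equal(run$acceptance, 1)
  fit <- diffusion_coefficient(msd(run))
  expect_lt(abs(fit$value - 2^2 / 6), 3 * fit$stderr)
})

test_that("a tracer sealed in a closed pore stays confined", {
  s <- 1.9
  pos <- rbind(c(10, 10), c(10 + s, 10), c(10 + s / 2, 10 + s * sqrt(3) / 2))
  m <- manual_matrix(pos, L = 20, seed = 3)
  net <- tessellate(m)
  centroid <- matrix(colMeans(pos), 1)
  p <- sim_params(delta = 0.5, t_max = 2000, n_tracers = 1, seed = 8)
  run <- run_simulation(m, net, p, tracers = centroid)
  cu <- msd(run)
  # confinement scale: the accessible pocket is well inside the triangle
  expect_lt(max(cu$msd), 1.0)
  expect_lt(cu$msd[nrow(cu)] / cu$t[nrow(cu)], 1e-3)
})

test_that("runs are deterministic in the seed", {
  fx <- dense_fixture()
  p <- sim_params(delta = 0.3, t_max = 500, n_tracers = 5, seed = 17)
  r1 <- run_simulation(fx$matrix, fx$network, p)
  r2 <- run_simulation(fx$matrix, fx$network, p)
  expect_identical(r1$disp, r2$disp)
  p3 <- sim_params(delta = 0.3, t_max = 500, n_tracers = 5, seed = 18)
  r3 <- run_simulation(fx$matrix, fx$network, p3)
  expect_false(identical(r1$disp, r3$disp))
})

test_that("small steps are equivalent to plain hard-disc MC", {
  # with delta below every positive gap, the channel rule can never fire:
  # forcing all channels open must reproduce the identical trajectory
  m <- generate_matrix(0.18, 20, seed = 23)
  net <- tessellate(m)
  dmin <- min(net$edges$gap[net$edges$gap > 0])
  p <- sim_params(delta = 0.9 * dmin, t_max = 2000, n_tracers = 5, seed = 4)
  open_net <- net
  open_net$edges$passable <- rep(TRUE, nrow(net$edges))
  r1 <- run_simulation(m, net, p)
  r2 <- run_simulation(m, open_net, p)
  expect_identical(r1$disp, r2$disp)
})

test_that("tracers never leave their initial pore cluster", {
  m <- generate_matrix(0.22, 30, seed = 55)
  net <- tessellate(m)
  labs <- cluster_labels(net)
  p <- sim_params(delta = 2, t_max = 3000, n_tracers = 10,
                  sampling_times = seq(50, 3000, by = 50), seed = 6)
  r <- run_simulation(m, net, p)
  start <- crowdperc:::locate_triangle_cpp(r$tracers, net$tri_coords, net$L)
  for (si in seq_along(r$times)) {
    pos <- r$tracers + matrix(r$disp[si, ], ncol = 2, byrow = TRUE)
    tri <- crowdperc:::locate_triangle_cpp(pos, net$tri_coords, net$L)
    ok <- tri > 0 & start > 0
    expect_true(all(labs[tri[ok]] == labs[start[ok]]))
  }
})

test_that("obstruction slows diffusion monotonically in phi", {
  cases <- list(c(0.05, 2e4), c(0.12, 5e4), c(0.18, 3e5))
  D <- vapply(cases, function(cs) {
    cu <- msd_curve(cs[1], 50, delta = 0.5, t_max = cs[2], n_configs = 6,
                    n_tracers = 10, seed = 800 + round(cs[1] * 100),
                    time_average = TRUE)
    diffusion_coefficient(cu, estimator = "linear", conv_tol = 0.35)$value
  }, numeric(1))
  expect_true(all(diff(D) < 0))
})

test_that("sub-diffusive curves raise a no-diffusive-window error", {
  s <- 1.9
  pos <- rbind(c(10, 10), c(10 + s, 10), c(10 + s / 2, 10 + s * sqrt(3) / 2))
  m <- manual_matrix(pos, L = 20, seed = 3)
  net <- tessellate(m)
  p <- sim_params(delta = 0.5, t_max = 2000, n_tracers = 1, seed = 8)
  run <- run_simulation(m, net, p, tracers = matrix(colMeans(pos), 1))
  expect_error(diffusion_coefficient(msd(run)),
               class = "crowdperc_no_diffusive_window")
})
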