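test_that("TST rate and side probabilities follow the gap geometry", {
  expect_equal(tst_rate(0.5, (sqrt(3) / 4) * 9 - pi / 2),
               0.5 / ((sqrt(3) / 4) * 9 - pi / 2), tolerance = 1e-12)
  expect_equal(tst_rate(0.5, (sqrt(3) / 4) * 9 - pi / 2), 0.2149,
               tolerance = 1e-3)
  expect_identical(tst_rate(-0.3, 2), 0)
  expect_identical(tst_rate(0, 2), 0)
  expect_equal(tst_rate(0.8, 4), tst_rate(0.8, 2) / 2)  # homogeneity in A
  expect_error(tst_rate(0.5, 0), "positive")

  expect_equal(p_tst(c(1, 1, 1)), rep(1 / 3, 3))
  expect_equal(p_tst(c(1.0, 0.5, 0.5)), c(0.5, 0.25, 0.25))
  expect_equal(p_tst(c(1.0, -0.2, 0.5)), c(2 / 3, 0, 1 / 3))
  expect_error(p_tst(c(-1, 0, -0.5)), "closed")
  pm <- p_tst(rbind(c(1, 1, 1), c(2, 1, 1)))
  expect_equal(rowSums(pm), c(1, 1))
})

test_that("numerical rate is P / (2 tau)", {
  expect_equal(numerical_rate(0.5, 10), 0.025)
  expect_equal(numerical_rate(1 / 3, 5), 1 / 30)
  expect_identical(numerical_rate(0, 7), 0)
  expect_error(numerical_rate(0.5, 0), "positive")
})

test_that("first passage from a symmetric pore exits each side equally", {
  fx <- equilateral_fixture(s = 3)
  fp <- first_passage(fx$network, fx$matrix, delta = 0.05, n_trials = 2000,
                      seed = 77, pores = fx$pore)
  expect_identical(fp$censored, 0)
  counts <- unlist(fp[, c("n1", "n2", "n3")])
  expect_equal(sum(counts), 2000)
  se <- sqrt(2 / 9 / 2000)
  for (p in counts / 2000) expect_lt(abs(p - 1 / 3), 3.5 * se)
  # deterministic under the seed, independent of pore subsetting
  fp2 <- first_passage(fx$network, fx$matrix, delta = 0.05, n_trials = 2000,
                       seed = 77, pores = fx$pore)
  expect_identical(fp, fp2)
})

test_that("a pore with one passable side always exits through it", {
  # isoceles obstacle triangle: two sealed channels (l = 1.9), one open
  pos <- rbind(c(8, 10), c(10.6, 10), c(9.3, 10 + sqrt(1.9^2 - 1.3^2)))
  m <- manual_matrix(pos, L = 20, seed = 4)
  net <- tessellate(m)
  central <- which(apply(net$triangles, 1, function(tr) all(sort(tr) == 1:3)))
  central <- central[which.min(abs(net$tri_area[central] -
    abs(0.5 * ((pos[2,1]-pos[1,1])*(pos[3,2]-pos[1,2]) -
               (pos[2,2]-pos[1,2])*(pos[3,1]-pos[1,1])))))]
  g3 <- crowdperc:::pore_side_gaps(net)[central, ]
  expect_identical(sum(g3 > 0), 1L)
  open_side <- which(g3 > 0)
  fp <- first_passage(net, m, delta = 0.2, n_trials = 300, seed = 5,
                      pores = central)
  counts <- unlist(fp[, c("n1", "n2", "n3")])
  expect_equal(unname(counts[open_side]), fp$n_escaped)
  expect_true(all(counts[-open_side] == 0))
})

test_that("requesting a closed pore is an error", {
  s <- 1.9
  pos <- rbind(c(10, 10), c(10 + s, 10), c(10 + s / 2, 10 + s * sqrt(3) / 2))
  m <- manual_matrix(pos, L = 20, seed = 3)
  net <- tessellate(m)
  closed <- which(crowdperc:::open_sides_per_pore(net) == 0)
  expect_gt(length(closed), 0)
  expect_error(first_passage(net, m, 0.1, 10, seed = 1, pores = closed[1]),
               "closed")
})

test_that("log-binned rate density is normalised and recovers planted laws", {
  set.seed(4)
  for (alpha_true in c(0, 0.2, 0.4, 0.6)) {
    W <- sample_power_law_rates(1e5, alpha_true)
    rho <- rate_distribution(W)
    expect_equal(sum(rho$density * rho$width), 1, tolerance = 1e-9)
    f <- fit_alpha(rho)
    expect_lt(abs(f$value - alpha_true), max(2 * f$stderr, 0.06))
  }
  expect_error(rate_distribution(rep(0, 200)), "positive")
  expect_error(rate_distribution(runif(50)), "100")
})

test_that("alpha fitting ignores Poisson-thinned and bulk-peak bins", {
  # a density that rises into a bulk peak must be fitted below the mode:
  # the small-rate limit has no singularity here, so alpha <= 0
  set.seed(9)
  W <- exp(rnorm(5e4, log(1e-4), 1))   # lognormal bump, no singularity
  f <- fit_alpha(rate_distribution(W))
  expect_lt(f$value, 0.15)
  # w_min excludes unreliable bins from the window
  f2 <- fit_alpha(rate_distribution(W), w_min = 1e-5)
  expect_gte(f2$fit_window[1], 1e-5)
})

test_that("rate tables tie together geometry and first-passage statistics", {
  fx <- equilateral_fixture(s = 3)
  rt <- rate_table(fx$network, fx$matrix, delta = 0.05, n_trials = 400,
                   seed = 12, pores = fx$pore)
  expect_identical(nrow(rt), 3L)
  expect_equal(rt$g, rep(1, 3), tolerance = 1e-9)       # l = 3, sigma = 1
  expect_equal(rt$A, rep((sqrt(3) / 4) * 9 - pi / 2, 3), tolerance = 1e-9)
  expect_equal(rt$P_TST, rep(1 / 3, 3))
  expect_equal(sum(rt$P_num), 1)
  expect_equal(rt$W_num, rt$P_num / (2 * rt$tau_MFPT))
  expect_equal(rt$W_TST, rt$g / rt$A)
})

test_that("probability-ratio distribution is a point mass for perfect TST", {
  r <- ratio_distribution(rep(1 / 3, 300), rep(1 / 3, 300))
  expect_equal(attr(r, "outside_fraction"), 0)
  expect_equal(sum(r$density * diff(r$ratio)[1]), 1, tolerance = 1e-9)
  expect_equal(sum(r$count[r$ratio > 0.9 & r$ratio < 1.1]), 300)
  # asymmetric pairs put mass outside the TST band
  r2 <- ratio_distribution(c(rep(0.1, 100), rep(0.9, 100)),
                           rep(0.45, 200))
  expect_gt(attr(r2, "outside_fraction"), 0.9)
})
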