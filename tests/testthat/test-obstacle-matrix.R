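test_that("area fraction follows phi = pi N / (4 L^2)", {
  expect_identical(area_fraction(0, 100), 0)
  expect_equal(area_fraction(400, 50), pi * 400 / 10000)
  expect_equal(area_fraction(400, 50), 0.125664, tolerance = 1e-5)
  expect_equal(area_fraction(10695, 200), 0.20999, tolerance = 1e-4)
})

test_that("RSA generator hits the target count and never overlaps", {
  m <- generate_matrix(0.21, 200, seed = 1)
  expect_identical(m$N, as.integer(round(4 * 0.21 * 200^2 / pi)))
  expect_identical(m$N, 10695L)
  expect_true(all(m$positions >= 0 & m$positions < m$L))
  # brute-force O(N^2) minimum-image pair scan
  expect_gte(crowdperc:::min_pair_distance_cpp(m$positions, m$L), m$sigma)

  m2 <- generate_matrix(0.12566, 50, seed = 4)
  expect_identical(m2$N, 400L)
  expect_equal(m2$phi, area_fraction(400, 50))

  m0 <- generate_matrix(0, 50, seed = 1)
  expect_identical(m0$N, 0L)
  expect_identical(nrow(m0$positions), 0L)
})

test_that("RSA is deterministic in the seed and saturates with an error", {
  a <- generate_matrix(0.15, 40, seed = 123)
  b <- generate_matrix(0.15, 40, seed = 123)
  expect_identical(a$positions, b$positions)
  c <- generate_matrix(0.15, 40, seed = 124)
  expect_false(isTRUE(all.equal(a$positions, c$positions)))
  expect_error(generate_matrix(0.54, 12, seed = 1, max_attempts = 200),
               "saturation")
})

test_that("g(r) shows hard-core exclusion, contact pileup, and decorrelation", {
  mats <- lapply(1:50, function(i) generate_matrix(0.21, 25, seed = 600 + i))
  dr <- 0.05
  gs <- lapply(mats, radial_distribution, dr = dr, r_max = 12)
  g_mean <- Reduce(`+`, lapply(gs, function(g) g$g)) / length(gs)
  r <- gs[[1]]$r
  expect_true(all(g_mean[r < 1 - dr] == 0))            # hard core
  expect_gt(mean(g_mean[r > 1 & r < 1.05]), 1)          # contact region
  expect_equal(mean(g_mean[r > 5]), 1, tolerance = 0.02)  # decorrelated
  # low density: g ~ 1 beyond contact almost immediately
  m_dilute <- generate_matrix(0.06, 30, seed = 3)
  g_d <- radial_distribution(m_dilute, dr = 0.1, r_max = 10)
  expect_equal(mean(g_d$g[g_d$r > 5]), 1, tolerance = 0.1)
  expect_error(radial_distribution(mats[[1]], dr = 0.05, r_max = 20),
               "L/2")
})

test_that("pair histogram counting matches an R minimum-image oracle", {
  m <- generate_matrix(0.15, 15, seed = 77)
  g <- radial_distribution(m, dr = 0.25, r_max = 6)
  d <- min_image_dists(m$positions, m$positions, m$L)
  pair_count <- (sum(d < 6) - m$N) # ordered pairs, self excluded
  expect_equal(sum(g$count), pair_count)
})

test_that("tracers avoid all obstacles and respect determinism", {
  fx <- dense_fixture()
  tr <- place_tracers(fx$matrix, 10, seed = 5)
  d <- min_image_dists(tr, fx$matrix$positions, fx$matrix$L)
  expect_true(all(d >= fx$matrix$sigma))
  expect_identical(tr, place_tracers(fx$matrix, 10, seed = 5))

  # single obstacle at the box centre: tracer outside its exclusion disc
  m1 <- manual_matrix(rbind(c(5, 5)), L = 10)
  t1 <- place_tracers(m1, 1, seed = 9)
  expect_gte(min(min_image_dists(t1, m1$positions, 10)), 1)

  # phi = 0: positions uniform over the box
  m0 <- generate_matrix(0, 50, seed = 1)
  t0 <- place_tracers(m0, 500, seed = 11)
  expect_true(all(t0 >= 0 & t0 < 50))
  expect_equal(mean(t0), 25, tolerance = 1.5)
})

test_that("matrix CSV round-trip is lossless", {
  m <- generate_matrix(0.18, 20, seed = 31)
  path <- tempfile(fileext = ".csv")
  write_matrix(m, path)
  m2 <- read_matrix(path)
  expect_identical(m2$positions[, 1], m$positions[, 1])
  expect_identical(m2$positions[, 2], m$positions[, 2])
  expect_equal(m2$L, m$L)
  expect_equal(m2$sigma, m$sigma)
  expect_equal(m2$N, m$N)
  expect_equal(m2$phi, m$phi)
  unlink(path)
})
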