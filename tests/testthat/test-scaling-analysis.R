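test_that("fit_mu recovers planted conductivity exponents", {
  phi <- seq(0.18, 0.2075, by = 0.005)
  D <- 7 * (0.2125 - phi)^1.31
  f <- suppressWarnings(fit_mu(D, phi, phi_c = 0.2125))
  expect_equal(f$value, 1.31, tolerance = 1e-10)
  expect_equal(f$metadata$prefactor, 7, tolerance = 1e-8)

  # noisy recovery across the physically relevant exponent range
  set.seed(19)
  phi2 <- seq(0.10, 0.2075, by = 0.01)
  for (mu_true in c(1, 1.31, 2.06, 3)) {
    D2 <- 5 * (0.2125 - phi2)^mu_true * exp(rnorm(length(phi2), 0, 0.05))
    f2 <- fit_mu(D2, phi2, phi_c = 0.2125)
    expect_lt(abs(f2$value - mu_true), max(2 * f2$stderr, 0.1))
  }

  expect_error(fit_mu(c(1, 1, 1, 1), c(0.1, 0.15, 0.2, 0.22), phi_c = 0.2125),
               "below phi_c")
  expect_error(fit_mu(c(1, 1, 1), c(0.1, 0.12, 0.14), phi_c = 0.2125),
               "4 points")
})

test_that("dynamic exponent z follows the scaling relation", {
  cc <- critical_constants()
  z_direct <- function(mu) (2 * cc$nu - cc$beta + mu) / (cc$nu - cc$beta / 2)
  expect_equal(dynamic_z(1.31), z_direct(1.31))
  expect_equal(dynamic_z(1.31), 3.0365, tolerance = 1e-4)
  expect_equal(dynamic_z(2.06), 3.6299, tolerance = 1e-4)
  mus <- seq(0.5, 3, by = 0.25)
  expect_true(all(diff(dynamic_z(mus)) > 0))
})

test_that("RG prediction for mu switches branches at the right alpha", {
  expect_equal(mu_rg(0), 1.31)
  expect_equal(mu_rg(0.2), 1.31)       # lattice branch still dominates
  expect_equal(mu_rg(0.5), 2.0)        # 1/(1 - alpha) branch
  expect_error(mu_rg(1), "alpha")
  a <- seq(0, 0.9, by = 0.05)
  v <- mu_rg(a)
  expect_true(all(v >= 1.31))
  expect_true(all(diff(v) >= 0))
})

test_that("exact self-similar MSD curves collapse perfectly", {
  cc <- critical_constants()
  mu <- 1.8
  z <- dynamic_z(mu, cc)
  bexp <- 2 * cc$nu + mu - cc$beta
  f_scal <- function(x) (1 + x^2)^(mu / 2)   # const at 0, x^mu at infinity
  phis <- c(0.14, 0.17, 0.19, 0.20)
  t <- 10^seq(1, 6, length.out = 80)
  curves <- lapply(phis, function(phi) {
    x <- (0.2125 - phi) * t^(1 / bexp)
    cu <- data.frame(t = t, msd = t^(2 / z) * f_scal(x))
    attr(cu, "phi") <- phi
    attr(cu, "delta") <- 1
    cu
  })
  col <- scaling_collapse(curves, phi_c = 0.2125, mu = mu)
  expect_lt(col$spread, 1e-10)
  # a wrong exponent must collapse strictly worse
  col_bad <- scaling_collapse(curves, phi_c = 0.2125, mu = mu + 0.5)
  expect_gt(col_bad$spread, 10 * max(col$spread, 1e-12))
  # the beta-sign convention is exposed and changes the rescaling
  col_plus <- scaling_collapse(curves, phi_c = 0.2125, mu = mu,
                               beta_sign = "plus")
  expect_gt(col_plus$spread, col$spread)

  attr(curves[[1]], "delta") <- 2
  expect_error(scaling_collapse(curves, phi_c = 0.2125, mu = mu),
               "same delta")
})

test_that("collapse quality with the fitted mu beats the lattice value for fast dynamics", {
  # curves synthesised with a non-universal exponent are collapsed better
  # by that exponent than by mu_latt (the large-delta argument, as a scalar)
  cc <- critical_constants()
  mu_true <- 2.06
  z <- dynamic_z(mu_true, cc)
  bexp <- 2 * cc$nu + mu_true - cc$beta
  f_scal <- function(x) (1 + x^1.9)^(mu_true / 1.9)
  phis <- c(0.15, 0.18, 0.20)
  t <- 10^seq(2, 7, length.out = 60)
  curves <- lapply(phis, function(phi) {
    x <- (0.2125 - phi) * t^(1 / bexp)
    cu <- data.frame(t = t, msd = t^(2 / z) * f_scal(x))
    attr(cu, "phi") <- phi
    attr(cu, "delta") <- 2
    cu
  })
  s_fit <- scaling_collapse(curves, 0.2125, mu_true)$spread
  s_latt <- scaling_collapse(curves, 0.2125, 1.31)$spread
  expect_lt(s_fit, s_latt)
})

test_that("exponent_fit validates its fields", {
  expect_error(exponent_fit("mu", 1, stderr = -1), "stderr")
  expect_error(exponent_fit("mu", 1, fit_window = c(2, 1)), "fit_window")
  f <- exponent_fit("mu", 1.5, 0.1, c(0.1, 0.2), list(note = "x"))
  expect_s3_class(f, "exponent_fit")
  expect_output(print(f), "mu = 1.5")
})
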