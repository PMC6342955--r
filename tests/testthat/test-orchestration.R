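# a micro-scale configuration so the orchestration layer runs in seconds
micro_config <- function(seed = 1, out_dir = NULL) {
  cfg <- run_config(seed = seed, out_dir = out_dir)
  cfg$diffusion <- list(L = 40, deltas = c(0.5, 2), t_max = 5e3,
                        n_configs = 2, n_tracers = 5,
                        phi_values = c(0.06, 0.10, 0.14, 0.17))
  cfg$rates <- list(phi = 0.21, L = 25, deltas = c(0.5, 2), n_trials = 150,
                    n_pores = 150, step_cap = 1e6)
  cfg
}

test_that("the experiment report assembles exponents with consistent RG values", {
  cfg <- micro_config(seed = 3)
  rep <- run_experiment(cfg, stages = c("diffusion", "rates"))
  expect_s3_class(rep, "experiment_report")
  expect_equal(rep$phi_c_used, 0.2125)
  expect_named(rep$diffusion, c("delta_0.5", "delta_2"))
  for (r in rep$rates) {
    if (!is.na(r$alpha) && r$alpha < 1)
      expect_equal(r$mu_rg, max(1.31, 1 / (1 - r$alpha)), tolerance = 1e-10)
    expect_gte(r$outside_fraction, 0)
    expect_lte(r$outside_fraction, 1)
  }
  expect_identical(validate_report(rep), character(0))
})

test_that("experiment runs are deterministic and cached", {
  cfg <- micro_config(seed = 11)
  r1 <- run_experiment(cfg, stages = "rates")
  r2 <- run_experiment(cfg, stages = "rates")
  expect_identical(jsonlite::toJSON(r1$rates, auto_unbox = TRUE, digits = NA),
                   jsonlite::toJSON(r2$rates, auto_unbox = TRUE, digits = NA))

  dir <- file.path(tempdir(), "crowdperc-cache-test")
  unlink(dir, recursive = TRUE)
  cfg_c <- micro_config(seed = 11, out_dir = dir)
  t1 <- system.time(run_experiment(cfg_c, stages = "rates"))[3]
  t2 <- system.time(r4 <- run_experiment(cfg_c, stages = "rates"))[3]
  expect_true(file.exists(file.path(dir, "rates_seed11.json")))
  expect_lt(t2, t1 / 2)     # second run is a cache hit
  expect_equal(r4$rates$delta_2$alpha, r1$rates$delta_2$alpha,
               tolerance = 1e-12)
  unlink(dir, recursive = TRUE)
})

test_that("validate_report flags physically impossible entries", {
  rep <- list(phi_c_used = 0.2125,
              rates = list(delta_2 = list(alpha = 1.2, mu_rg = NA_real_,
                                          outside_fraction = 0.2)),
              diffusion = list())
  bad <- validate_report(rep)
  expect_true(any(grepl("alpha", bad)))

  rep2 <- list(phi_c_used = 0.50, rates = list(), diffusion = list())
  expect_true(any(grepl("phi_c", validate_report(rep2))))

  rep3 <- list(phi_c_used = 0.2125, rates = list(),
               diffusion = list(delta_1 = list(D_table = data.frame(
                 phi = c(0.1, 0.15), D = c(1e-3, 5e-3), se = c(1e-5, 1e-5)))))
  expect_true(any(grepl("increases", validate_report(rep3))))
  expect_error(validate_report("not a list"), "malformed")
})

test_that("MSD curves and networks round-trip through their writers", {
  fx <- dense_fixture()
  p <- sim_params(delta = 0.3, t_max = 200, n_tracers = 5, seed = 2)
  cu <- msd(run_simulation(fx$matrix, fx$network, p))
  path <- tempfile(fileext = ".csv")
  write_msd_curve(cu, path)
  cu2 <- read_msd_curve(path)
  expect_identical(cu2$t, cu$t)
  expect_identical(cu2$msd, cu$msd)
  expect_equal(attr(cu2, "phi"), attr(cu, "phi"))
  expect_equal(attr(cu2, "delta"), attr(cu, "delta"))
  unlink(path)

  jpath <- tempfile(fileext = ".json")
  write_network(fx$network, jpath)
  back <- jsonlite::fromJSON(jpath)
  expect_equal(back$L, fx$network$L)
  expect_equal(nrow(back$edges), nrow(fx$network$edges))
  expect_equal(back$edges$gap, fx$network$edges$gap)
  expect_equal(sum(back$tri_area), fx$network$L^2)
  unlink(jpath)
})
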