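#' Desk-scale experiment configuration
#'
#' A configuration runnable on one CPU in minutes, covering the full
#' pipeline at reduced sizes: percolation threshold by finite-size scaling,
#' a diffusion sweep in `phi` per step size `delta` with a conductivity-
#' exponent fit, and a pore-level rate analysis per `delta` with the
#' singularity exponent and its renormalisation-group prediction for `mu`.
#' The `paper` preset records the full-scale study conditions (L up to
#' 2000, 300 configurations, 8000 first-passage trials per pore) for
#' cluster use.
#'
#' @param seed integer master seed; every stochastic stage derives its own
#'   sub-seed from it.
#' @param out_dir directory for cached stage artifacts (created on demand);
#'   `NULL` disables caching.
#' @param scale `"desk"` (default) or `"paper"`.
#' @return a list of class `run_config`.
#' @export
run_config <- function(seed = 1, out_dir = NULL,
                       scale = c("desk", "paper")) {
  scale <- match.arg(scale)
  cfg <- if (scale == "desk") {
    list(
      percolation = list(L_values = c(40, 60, 80), n_configs = 80),
      diffusion = list(
        L = 60, deltas = c(0.1, 2), t_max = 2e4, n_configs = 4,
        n_tracers = 10,
        phi_values = seq(0.08, 0.17, by = 0.015)),
      rates = list(
        phi = 0.21, L = 60, deltas = c(0.01, 2), n_trials = 300,
        n_pores = Inf, step_cap = 1e6))
  } else {
    list(
      percolation = list(L_values = c(200, 500, 1000, 2000), n_configs = 1000),
      diffusion = list(
        L = 2000, deltas = c(0.01, 0.05, 0.1, 0.3, 0.5, 1, 1.5, 2),
        t_max = 1e7, n_configs = 300, n_tracers = 10,
        phi_values = c(seq(0.1, 0.17, by = 0.01),
                       seq(0.18, 0.2075, by = 0.0025))),
      rates = list(
        phi = 0.21, L = 300, deltas = c(0.01, 0.3, 0.5, 1, 2),
        n_trials = 8000, n_pores = Inf, step_cap = 1e8))
  }
  structure(c(list(seed = seed, out_dir = out_dir, scale = scale), cfg),
            class = "run_config")
}

#' Run the end-to-end experiment
#'
#' Executes the requested stages in dependency order and assembles a report
#' with `phi_c`, the per-delta exponents `mu` and `alpha`, and the RG
#' prediction `mu_rg = max(mu_latt, 1/(1 - alpha))`. When `config$out_dir`
#' is set, each stage's result is cached as JSON and re-used on re-runs
#' with the same configuration.
#'
#' @param config a [run_config()] list.
#' @param stages subset of `c("percolation", "diffusion", "rates")`.
#' @return a list of class `experiment_report`.
#' @export
run_experiment <- function(config = run_config(),
                           stages = c("percolation", "diffusion", "rates")) {
  stages <- match.arg(stages, several.ok = TRUE)
  report <- list(seed = config$seed, scale = config$scale,
                 stages = stages, constants = unclass(critical_constants()))

  cache <- function(name, compute) {
    if (is.null(config$out_dir)) return(compute())
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    path <- file.path(config$out_dir,
                      sprintf("%s_seed%s.json", name, format(config$seed)))
    if (file.exists(path))
      return(jsonlite::fromJSON(path, simplifyVector = TRUE))
    val <- compute()
    jsonlite::write_json(val, path, auto_unbox = TRUE, digits = NA)
    val
  }

  phi_c_used <- critical_constants()$phi_c
  if ("percolation" %in% stages) {
    pc <- cache("percolation", function() {
      est <- estimate_phi_c(config$percolation$L_values,
                            config$percolation$n_configs,
                            seed = config$seed + 101)
      list(phi_c = est$phi_c$value, stderr = est$phi_c$stderr,
           phi_c_L = vapply(est$fits, function(f) f$value, numeric(1)),
           L_values = config$percolation$L_values,
           n_configs = config$percolation$n_configs)
    })
    report$percolation <- pc
    phi_c_used <- pc$phi_c
  }
  report$phi_c_used <- phi_c_used

  if ("diffusion" %in% stages) {
    dcfg <- config$diffusion
    report$diffusion <- cache("diffusion", function() {
      per_delta <- lapply(dcfg$deltas, function(delta) {
        dv <- diffusion_vs_phi(dcfg$phi_values, dcfg$L, delta, dcfg$t_max,
                               dcfg$n_configs, dcfg$n_tracers,
                               seed = config$seed + round(1e4 * delta),
                               time_average = TRUE, estimator = "linear")
        ok <- !is.na(dv$D)
        fit <- if (sum(ok) >= 4)
          fit_mu(dv$D[ok], dv$phi[ok], phi_c = phi_c_used, se = dv$se[ok])
        else NULL
        list(delta = delta, D_table = dv,
             mu = if (is.null(fit)) NA_real_ else fit$value,
             mu_stderr = if (is.null(fit)) NA_real_ else fit$stderr,
             z = if (is.null(fit)) NA_real_ else dynamic_z(fit$value))
      })
      names(per_delta) <- paste0("delta_", dcfg$deltas)
      per_delta
    })
  }

  if ("rates" %in% stages) {
    rcfg <- config$rates
    report$rates <- cache("rates", function() {
      m <- generate_matrix(rcfg$phi, rcfg$L, seed = config$seed + 9001)
      net <- tessellate(m)
      open_pores <- which(open_sides_per_pore(net) > 0)
      pores <- head(open_pores, min(rcfg$n_pores, length(open_pores)))
      per_delta <- lapply(rcfg$deltas, function(delta) {
        rt <- rate_table(net, m, delta, rcfg$n_trials,
                         seed = config$seed + round(1e4 * delta) + 7,
                         pores = pores, step_cap = rcfg$step_cap)
        a <- tryCatch(fit_alpha_rates(rt), error = function(e) NULL)
        alpha <- if (is.null(a)) NA_real_ else max(0, a$value)
        list(delta = delta,
             alpha = alpha,
             alpha_stderr = if (is.null(a)) NA_real_ else a$stderr,
             mu_rg = if (is.na(alpha) || alpha >= 1) NA_real_ else mu_rg(alpha),
             outside_fraction =
               attr(ratio_distribution(rt$P_num, rt$P_TST), "outside_fraction"),
             censored_fraction = mean(rt$censored > 0))
      })
      names(per_delta) <- paste0("delta_", rcfg$deltas)
      per_delta
    })
  }

  class(report) <- "experiment_report"
  report
}

#' Validate an experiment report
#'
#' Cross-stage invariant checks: probabilities and thresholds in range, the
#' RG relation `mu_rg = max(mu_latt, 1/(1-alpha))` satisfied, `D(phi)`
#' non-increasing in `phi` at fixed `delta` (within reported noise).
#'
#' @param report an `experiment_report` from [run_experiment()].
#' @return character vector of violated invariants (empty = pass).
#' @export
validate_report <- function(report) {
  if (!is.list(report)) stop("malformed report: not a list")
  bad <- character(0)
  cc <- critical_constants()
  if (!is.null(report$phi_c_used) &&
      (report$phi_c_used < 0.15 || report$phi_c_used > 0.30))
    bad <- c(bad, sprintf("phi_c_used = %.4f outside plausible bounds [0.15, 0.30]",
                          report$phi_c_used))
  for (nm in names(report$rates)) {
    r <- report$rates[[nm]]
    if (!is.null(r$alpha) && !is.na(r$alpha)) {
      if (r$alpha >= 1)
        bad <- c(bad, sprintf("%s: alpha = %.3f >= 1 (outside RG domain)",
                              nm, r$alpha))
      else if (!is.na(r$mu_rg) &&
               abs(r$mu_rg - max(cc$mu_latt, 1 / (1 - r$alpha))) > 1e-8)
        bad <- c(bad, sprintf("%s: mu_rg inconsistent with alpha", nm))
    }
    if (!is.null(r$outside_fraction) &&
        (r$outside_fraction < 0 || r$outside_fraction > 1))
      bad <- c(bad, sprintf("%s: outside_fraction not a probability", nm))
  }
  for (nm in names(report$diffusion)) {
    d <- report$diffusion[[nm]]
    tab <- d$D_table
    if (is.null(tab)) next
    if (is.list(tab) && !is.data.frame(tab)) tab <- as.data.frame(tab)
    ok <- !is.na(tab$D)
    if (sum(ok) >= 2) {
      Dd <- tab$D[ok]
      sed <- tab$se[ok]
      tol <- 3 * sqrt(sed[-1]^2 + sed[-length(sed)]^2)
      if (any(diff(Dd) > pmax(tol, 1e-12)))
        bad <- c(bad, sprintf("%s: D(phi) increases with phi beyond noise", nm))
    }
  }
  bad
}
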