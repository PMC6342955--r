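#' Container for a fitted exponent or constant
#'
#' Light-weight record used for every fitted quantity in the package
#' (thresholds, exponents, diffusion coefficients): the estimate, its
#' standard error, the fit window, and free-form metadata.
#'
#' @param name label, e.g. `"mu"`, `"alpha"`, `"phi_c"`, `"D"`.
#' @param value point estimate.
#' @param stderr standard error (non-negative; may be `NA`).
#' @param fit_window numeric length-2 `(lo, hi)` describing the fitted range.
#' @param metadata free-form list.
#' @return an object of class `exponent_fit`.
#' @export
exponent_fit <- function(name, value, stderr = NA_real_,
                         fit_window = c(NA_real_, NA_real_),
                         metadata = list()) {
  if (!is.na(stderr) && stderr < 0) stop("stderr must be >= 0")
  if (all(!is.na(fit_window)) && fit_window[1] >= fit_window[2])
    stop("fit_window must satisfy lo < hi")
  structure(list(name = name, value = value, stderr = stderr,
                 fit_window = fit_window, metadata = metadata),
            class = "exponent_fit")
}

#' @export
print.exponent_fit <- function(x, ...) {
  cat(sprintf("<exponent_fit> %s = %.5g", x$name, x$value))
  if (!is.na(x$stderr)) cat(sprintf(" +/- %.2g", x$stderr))
  if (all(!is.na(x$fit_window)))
    cat(sprintf("  [window %.4g .. %.4g]", x$fit_window[1], x$fit_window[2]))
  cat("\n")
  invisible(x)
}

#' Universal 2D percolation constants
#'
#' The constants entering the scaling analysis: correlation-length exponent
#' `nu = 4/3`, order-parameter exponent `beta = 5/36`, the lattice value of
#' the conductivity exponent `mu_latt = 1.31`, dimensionality `d = 2`, and
#' the percolation threshold `phi_c` of the hard-disc matrix ensemble
#' (default the finite-size-scaling value 0.2125; supply your own pipeline
#' estimate to propagate it).
#'
#' @param nu,beta,mu_latt,d,phi_c override any constant.
#' @return a list of class `critical_constants`.
#' @export
critical_constants <- function(nu = 4 / 3, beta = 5 / 36, mu_latt = 1.31,
                               d = 2L, phi_c = 0.2125) {
  stopifnot(nu > 0, beta > 0, mu_latt > 0, phi_c > 0, d == 2L)
  structure(list(nu = nu, beta = beta, mu_latt = mu_latt, d = d,
                 phi_c = phi_c),
            class = "critical_constants")
}

#' Fit the dynamic (conductivity) exponent mu
#'
#' Fits `D ~ (phi_c - phi)^mu` by least squares of `log D` on
#' `log(phi_c - phi)`, with `phi_c` held fixed at its independently
#' determined value (co-fitting mu and phi_c is badly conditioned; the
#' threshold is measured by its own finite-size-scaling pipeline).
#'
#' @param D positive diffusion coefficients.
#' @param phi area fractions, all strictly below `phi_c`.
#' @param phi_c percolation threshold to impose.
#' @param se optional standard errors of `D` for weighting
#'   (weights `(D / se)^2`, i.e. inverse variance on the log scale).
#' @return an `exponent_fit` with `name = "mu"`; metadata records `phi_c`
#'   and the number of points.
#' @export
#' @examples
#' phi <- seq(0.18, 0.2075, by = 0.005)
#' D <- 7 * (0.2125 - phi)^1.31
#' fit_mu(D, phi, phi_c = 0.2125)$value  # 1.31
fit_mu <- function(D, phi, phi_c, se = NULL) {
  if (any(phi >= phi_c))
    stop("all phi must lie strictly below phi_c")
  if (length(D) < 4) stop("need at least 4 points to fit mu")
  if (any(D <= 0)) stop("all D must be positive")
  x <- log(phi_c - phi)
  y <- log(D)
  w <- if (is.null(se)) rep(1, length(D)) else (D / se)^2
  fit <- lm(y ~ x, weights = w)
  est <- summary(fit)$coefficients
  exponent_fit("mu", est["x", 1], est["x", 2],
               fit_window = range(phi),
               metadata = list(phi_c = phi_c, n_points = length(D),
                               prefactor = exp(est["(Intercept)", 1])))
}

#' Conductivity-exponent sweep over step sizes
#'
#' Shared protocol for measuring `mu(delta)` at desk scale: for each step
#' size, ensemble diffusion coefficients are measured over a common
#' area-fraction window with run lengths scaled as `1 / D0(delta)` (slower
#' microscopic dynamics need proportionally longer runs to reach the same
#' diffusive length), using time-averaged MSD curves and the trailing
#' linear estimator of [diffusion_coefficient()] (which absorbs the
#' constant crossover offset); `D ~ (phi_c - phi)^mu` is then fitted with
#' `phi_c` held fixed. Because the window sits further
#' from the threshold than an asymptotic fit requires, the fitted values
#' are effective exponents: ordering in `delta` is meaningful, absolute
#' values are biased low relative to the asymptotic critical exponents.
#'
#' @param deltas step sizes to sweep.
#' @param phi_values common area-fraction window (strictly below `phi_c`).
#' @param phi_extra additional near-threshold points used only for step
#'   sizes at or above `delta_extra_min`: their faster microscopic clock
#'   makes the diffusive regime reachable there, mirroring the wider fit
#'   windows used for large step sizes at full scale.
#' @param delta_extra_min smallest delta that receives `phi_extra`.
#' @param L box edge length.
#' @param phi_c percolation threshold to impose in the fits.
#' @param n_configs independent matrices per `(phi, delta)` point.
#' @param n_tracers tracers per matrix.
#' @param base_t_max run length (MC time units) at `delta = 1` for the
#'   lowest phi; scaled by `1 / delta^2` per step size and grown towards
#'   the threshold, with a growing floor for large delta (whose crossover
#'   is set by the pore network, not by `D0`).
#' @param seed integer seed.
#' @return list with `fits` (one `exponent_fit` per delta, named
#'   `delta_<value>`) and `D_tables` (the underlying `(phi, D, se)` tables).
#' @export
mu_sweep <- function(deltas,
                     phi_values = c(0.10, 0.13, 0.155, 0.175),
                     phi_extra = 0.185, delta_extra_min = 0.3,
                     L = 100, phi_c = 0.2125, n_configs = 12, n_tracers = 10,
                     base_t_max = 1e4, seed = 1) {
  fits <- list()
  tables <- list()
  for (d in deltas) {
    phis <- if (d >= delta_extra_min) c(phi_values, phi_extra) else phi_values
    grow <- (max(phi_c - phi_values) / (phi_c - phis))^1.6
    t_max <- round(pmin(pmax(base_t_max * grow / d^2, 2e4 * grow), 2e6))
    # the seed is shared across deltas: identical matrices and tracer
    # starts make mu differences a paired comparison, cancelling most
    # quenched-disorder noise between step sizes
    dv <- diffusion_vs_phi(phis, L, d, t_max,
                           n_configs = n_configs, n_tracers = n_tracers,
                           seed = seed,
                           time_average = TRUE, estimator = "linear")
    ok <- !is.na(dv$D)
    fit <- if (sum(ok) >= 4)
      fit_mu(dv$D[ok], dv$phi[ok], phi_c = phi_c, se = dv$se[ok])
    else NULL
    key <- paste0("delta_", d)
    fits[key] <- list(fit)
    tables[[key]] <- dv
  }
  list(fits = fits, D_tables = tables)
}

#' Dynamic exponent z from mu
#'
#' At the percolation threshold the mean-square displacement grows
#' anomalously, `<dr^2>(t) ~ t^(2/z)`, with
#' `z = (2 nu - beta + mu) / (nu - beta / 2)`.
#'
#' @param mu conductivity exponent (positive).
#' @param constants a [critical_constants()] list.
#' @return the dynamic exponent `z`.
#' @export
dynamic_z <- function(mu, constants = critical_constants()) {
  stopifnot(all(mu > 0))
  (2 * constants$nu - constants$beta + mu) / (constants$nu - constants$beta / 2)
}

#' Renormalisation-group prediction for mu from the rate singularity
#'
#' If the channel transition-rate distribution is singular at small rates,
#' `rho(W) ~ W^-alpha`, the conductivity exponent is
#' `mu = max(mu_latt, (d - 2) nu + 1 / (1 - alpha))`; in 2D this is
#' `max(1.31, 1 / (1 - alpha))`, so a strong singularity (`alpha > 1 - 1/1.31`)
#' lifts mu above its lattice value.
#'
#' @param alpha singularity exponent, in `[0, 1)`.
#' @param constants a [critical_constants()] list.
#' @return the predicted `mu`.
#' @export
mu_rg <- function(alpha, constants = critical_constants()) {
  if (any(alpha < 0) || any(alpha >= 1))
    stop("alpha must lie in [0, 1): the RG expression diverges at alpha = 1")
  pmax(constants$mu_latt,
       (constants$d - 2) * constants$nu + 1 / (1 - alpha))
}

#' Scaling collapse of mean-square-displacement curves
#'
#' Near the threshold the MSD obeys
#' `<dr^2>(t) ~ t^(2/z) f((phi_c - phi) t^(1/(2 nu + mu - beta)))`, so
#' curves for different phi at the same step size collapse when plotted as
#' `y = msd / t^(2/z)` against `x = t (phi_c - phi)^(2 nu + mu - beta)`.
#' The collapse quality is summarised as the mean squared vertical spread
#' of `log y` between curves over their common `log x` support (0 = perfect
#' collapse).
#'
#' @param curves list of [msd_curve][msd] data frames sharing one `delta`,
#'   each with attributes `phi` and `delta`, at `phi < phi_c`.
#' @param phi_c percolation threshold.
#' @param mu conductivity exponent used in the collapse.
#' @param constants a [critical_constants()] list.
#' @param beta_sign sign convention for beta in the collapse exponent
#'   `2 nu + mu -/+ beta`; `"minus"` (the scaling form) is the default,
#'   `"plus"` is exposed for sensitivity checks.
#' @param n_grid number of grid points for the common-support comparison.
#' @return list with `collapsed` (data frame `x`, `y`, `phi`) and `spread`
#'   (mean squared log-spread; lower is better).
#' @export
scaling_collapse <- function(curves, phi_c, mu,
                             constants = critical_constants(),
                             beta_sign = c("minus", "plus"),
                             n_grid = 60) {
  beta_sign <- match.arg(beta_sign)
  stopifnot(length(curves) >= 3)
  deltas <- vapply(curves, function(cu) attr(cu, "delta"), numeric(1))
  if (length(unique(deltas)) != 1)
    stop("all curves must share the same delta")
  phis <- vapply(curves, function(cu) attr(cu, "phi"), numeric(1))
  if (any(phis >= phi_c)) stop("all phi must lie below phi_c")
  bexp <- 2 * constants$nu + mu +
    if (beta_sign == "minus") -constants$beta else constants$beta
  z <- dynamic_z(mu, constants)
  pieces <- lapply(seq_along(curves), function(i) {
    cu <- curves[[i]]
    keep <- cu$t > 0 & cu$msd > 0
    data.frame(x = cu$t[keep] * (phi_c - phis[i])^bexp,
               y = cu$msd[keep] / cu$t[keep]^(2 / z),
               phi = phis[i])
  })
  collapsed <- do.call(rbind, pieces)
  # common support in log x
  lo <- max(vapply(pieces, function(p) min(log(p$x)), numeric(1)))
  hi <- min(vapply(pieces, function(p) max(log(p$x)), numeric(1)))
  if (hi <= lo) {
    spread <- NA_real_
  } else {
    grid <- seq(lo, hi, length.out = n_grid)
    logy <- vapply(pieces, function(p)
      stats::approx(log(p$x), log(p$y), xout = grid, ties = mean)$y,
      numeric(n_grid))
    spread <- mean(apply(logy, 1, function(r) mean((r - mean(r))^2)))
  }
  list(collapsed = collapsed, spread = spread,
       exponents = list(z = z, collapse_exponent = bexp))
}
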