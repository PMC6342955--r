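#' Simulation parameters for dynamic Monte Carlo
#'
#' One Monte Carlo time unit `t` is one sweep: `N_tracer` attempted moves
#' (`t = MCS / N_tracer`). Each attempt displaces one randomly chosen tracer
#' by independent per-axis shifts uniform on `[-delta, delta]`.
#'
#' @param delta maximum per-axis displacement (in sigma), positive.
#' @param t_max run length in MC time units.
#' @param n_tracers number of tracers evolved per matrix.
#' @param sampling_times increasing times at which positions are recorded;
#'   defaults to ~30 log-spaced points per decade from 1 to `t_max`.
#' @param seed integer seed for the move sequence.
#' @return a list of class `sim_params`.
#' @export
sim_params <- function(delta, t_max, n_tracers = 10, sampling_times = NULL,
                       seed = 1) {
  stopifnot(delta > 0, t_max > 0, n_tracers >= 1)
  if (is.null(sampling_times))
    sampling_times <- log_times(t_max)
  stopifnot(all(diff(sampling_times) > 0),
            all(sampling_times > 0), max(sampling_times) <= t_max)
  structure(list(delta = delta, t_max = t_max, n_tracers = n_tracers,
                 sampling_times = sampling_times, seed = seed),
            class = "sim_params")
}

# ~30 log-spaced sampling times per decade, deduplicated on the sweep grid
log_times <- function(t_max, per_decade = 30) {
  n <- max(2, ceiling(log10(t_max) * per_decade))
  tt <- unique(pmax(1, round(10^seq(0, log10(t_max), length.out = n))))
  sort(tt)
}

#' Propose trial displacements
#'
#' Each component is independently uniform on `[-delta, delta]` (so the
#' free-space diffusion coefficient is `D0 = delta^2 / 6` per time unit).
#' Uses R's RNG; the compiled simulation kernel draws the same distribution
#' from its own seeded generator.
#'
#' @param n number of proposals.
#' @param delta maximum per-axis displacement.
#' @return an `n` x 2 matrix of displacement proposals.
#' @export
trial_move <- function(n, delta) {
  stopifnot(delta > 0)
  matrix(runif(2 * n, -delta, delta), ncol = 2,
         dimnames = list(NULL, c("dx", "dy")))
}

#' Channels crossed by a move segment
#'
#' Exact segment-segment intersection of the move `old -> new` against the
#' periodic Delaunay edges, returned in parametric order along the move.
#' Grazing contacts (through a tessellation vertex or an endpoint on an
#' edge) count as crossings, which makes the acceptance rule conservative.
#'
#' @param old,new numeric length-2 positions; the segment must be shorter
#'   than `L / 2`.
#' @param network a [pore_network][tessellate].
#' @return data frame `(edge, t, passable)` sorted by the crossing
#'   parameter `t` in `[0, 1]`.
#' @export
crossing_check <- function(old, new, network) {
  crossing_check_cpp(as.numeric(old), as.numeric(new),
                     network$edge_coords, network$edges$passable, network$L)
}

#' Metropolis acceptance rule for a tracer move
#'
#' A move is accepted iff (1) the trial position overlaps no obstacle
#' (minimum-image centre distance >= sigma) and (2) the move segment
#' crosses no impassable channel (gap `g <= 0`). Crossing several passable
#' channels in one jump is allowed.
#'
#' @param old,new numeric length-2 positions (old must itself be
#'   overlap-free).
#' @param matrix an [obstacle_matrix][generate_matrix].
#' @param network the matrix's [pore_network][tessellate], or `NULL` when
#'   the matrix has fewer than 3 obstacles (rule 2 then does not apply).
#' @return logical.
#' @export
accept_move <- function(old, new, matrix, network = NULL) {
  L <- matrix$L
  if (matrix$N > 0) {
    d <- matrix$positions - rep(wrap_box(new, L), each = matrix$N)
    d <- d - L * round(d / L)
    if (any(d[, 1]^2 + d[, 2]^2 < matrix$sigma^2)) return(FALSE)
  }
  if (!is.null(network)) {
    cr <- crossing_check(old, new, network)
    if (any(!cr$passable)) return(FALSE)
  }
  TRUE
}

wrap_box <- function(p, L) {
  w <- p %% L
  w[w == L] <- 0
  w
}

#' Evolve tracers through a quenched matrix
#'
#' Dynamic Monte Carlo: per attempt a random tracer is displaced by
#' per-axis shifts uniform on `[-delta, delta]` and the move is accepted
#' under the rules of [accept_move()]. Positions are accumulated unwrapped
#' for mean-square-displacement estimation. One time unit elapses per
#' `n_tracers` attempts. Runs are deterministic under a fixed seed.
#'
#' @param matrix an [obstacle_matrix][generate_matrix].
#' @param network the matrix's [pore_network][tessellate] (or `NULL` for
#'   matrices with fewer than 3 obstacles).
#' @param params a [sim_params()] list.
#' @param tracers optional initial positions (from [place_tracers()]); by
#'   default placed with a seed derived from `params$seed`.
#' @return an object of class `trajectory_ensemble`: sampling `times`,
#'   unwrapped displacement array `disp` (time x 2 per tracer), tracer
#'   starts, the acceptance fraction, and the run parameters.
#' @export
run_simulation <- function(matrix, network, params, tracers = NULL) {
  if (is.null(tracers))
    tracers <- if (matrix$N > 0)
      place_tracers(matrix, params$n_tracers, seed = params$seed + 77)
    else
      matrix(runif(2 * params$n_tracers, 0, matrix$L), ncol = 2)
  edge_coords <- if (is.null(network)) matrix(0, 0, 4) else network$edge_coords
  passable <- if (is.null(network)) logical(0) else network$edges$passable
  attempts <- unique(pmax(1, round(params$sampling_times * params$n_tracers)))
  res <- msd_run_cpp(matrix$positions, matrix$L, matrix$sigma,
                     edge_coords, passable, params$delta, tracers,
                     as.double(attempts), as.double(params$seed))
  structure(
    list(times = attempts / params$n_tracers, disp = res$disp,
         tracers = tracers, n_tracers = params$n_tracers,
         acceptance = res$accepted / res$attempts,
         params = params, phi = matrix$phi, L = matrix$L),
    class = "trajectory_ensemble")
}

#' Ensemble mean-square displacement
#'
#' Averages `|r(t) - r(0)|^2` over all tracers of one or more
#' [run_simulation()] ensembles evolved in independent matrices. The default
#' is the fixed-origin average (origin `t = 0` only), matching the
#' ensemble-of-configurations protocol; with `multi_origin = TRUE` a
#' sliding-origin (time-averaged) estimate is computed instead, which is
#' far less noisy at equal cost and requires the runs to have been sampled
#' on an arithmetic time grid.
#'
#' @param ensemble a `trajectory_ensemble` or a list of them sharing the
#'   same sampling times.
#' @param multi_origin logical; average `|r(t0 + lag) - r(t0)|^2` over all
#'   recorded origins `t0` at ~log-spaced lags.
#' @return a data frame of class `msd_curve` with columns `t` (the lag for
#'   `multi_origin = TRUE`), `msd`, `se`, `n_samples`; attributes `phi`,
#'   `delta`, `L`.
#' @export
msd <- function(ensemble, multi_origin = FALSE) {
  if (inherits(ensemble, "trajectory_ensemble")) ensemble <- list(ensemble)
  stopifnot(length(ensemble) >= 1)
  times <- ensemble[[1]]$times
  for (e in ensemble) stopifnot(all(e$times == times))
  if (multi_origin) {
    dt <- diff(times)
    if (max(dt) - min(dt) > 1e-8 * max(dt))
      stop("multi_origin MSD needs an arithmetic sampling grid")
    n <- length(times)
    lags <- unique(round(10^seq(0, log10(n / 2), length.out = 40)))
    per_tracer <- lapply(ensemble, function(e) {
      d <- e$disp
      vapply(lags, function(k) {
        dd <- d[(1 + k):n, , drop = FALSE] - d[1:(n - k), , drop = FALSE]
        sq <- dd[, seq(1, ncol(dd), 2), drop = FALSE]^2 +
              dd[, seq(2, ncol(dd), 2), drop = FALSE]^2
        colMeans(sq)            # time average per tracer
      }, numeric(ncol(d) / 2))
    })
    # rows = tracers (per config), one column per lag
    tra <- do.call(rbind, lapply(per_tracer, function(m)
      if (is.matrix(m)) m else matrix(m, nrow = 1)))
    ns <- nrow(tra)
    out <- data.frame(t = lags * dt[1], msd = colMeans(tra),
                      se = apply(tra, 2, sd) / sqrt(ns),
                      n_samples = ns)
  } else {
    sq <- lapply(ensemble, function(e) {
      dx <- e$disp[, seq(1, ncol(e$disp), by = 2), drop = FALSE]
      dy <- e$disp[, seq(2, ncol(e$disp), by = 2), drop = FALSE]
      dx^2 + dy^2
    })
    all_sq <- do.call(cbind, sq)
    ns <- ncol(all_sq)
    out <- data.frame(t = times, msd = rowMeans(all_sq),
                      se = apply(all_sq, 1, sd) / sqrt(ns),
                      n_samples = ns)
  }
  class(out) <- c("msd_curve", class(out))
  attr(out, "phi") <- ensemble[[1]]$phi
  attr(out, "delta") <- ensemble[[1]]$params$delta
  attr(out, "L") <- ensemble[[1]]$L
  out
}

#' Ensemble-averaged MSD over independent matrices
#'
#' Generates `n_configs` matrices at `(phi, L)`, runs `n_tracers` tracers in
#' each, and averages the squared displacement over the whole ensemble.
#'
#' @inheritParams generate_matrix
#' @param delta maximum per-axis displacement.
#' @param t_max run length in MC time units.
#' @param n_configs number of independent matrices.
#' @param n_tracers tracers per matrix.
#' @param sampling_times optional explicit sampling times.
#' @param time_average logical; sample on an arithmetic grid and compute
#'   the sliding-origin MSD (see [msd()]), which stabilises the long-time
#'   slope at desk-scale ensemble sizes.
#' @param n_record number of recorded frames per run when `time_average`.
#' @return an `msd_curve` data frame (see [msd()]).
#' @export
msd_curve <- function(phi, L, delta, t_max, n_configs = 1, n_tracers = 10,
                      seed = 1, sampling_times = NULL, sigma = 1,
                      time_average = FALSE, n_record = 400) {
  if (time_average && is.null(sampling_times)) {
    # integer attempt stride so the recorded grid is exactly arithmetic
    stride <- max(1, round(t_max * n_tracers / n_record))
    sampling_times <- seq_len(floor(t_max * n_tracers / stride)) *
      (stride / n_tracers)
  }
  runs <- vector("list", n_configs)
  for (i in seq_len(n_configs)) {
    cfg_seed <- seed + 524287 * i
    m <- generate_matrix(phi, L, seed = cfg_seed, sigma = sigma)
    net <- if (m$N >= 3) tessellate(m) else NULL
    p <- sim_params(delta, t_max, n_tracers, sampling_times,
                    seed = cfg_seed + 13)
    runs[[i]] <- run_simulation(m, net, p)
  }
  out <- msd(runs, multi_origin = time_average)
  attr(out, "phi") <- if (n_configs > 0) runs[[1]]$phi else phi
  out
}

#' Long-time diffusion coefficient from an MSD curve
#'
#' Applies the Einstein relation `D = msd / (4 t)` over the final time
#' window in which the local logarithmic slope of the MSD lies in
#' `slope_tol` and which spans at least `min_decades` decades. If no such
#' window exists the curve is not diffusive on the simulated time scale
#' (sub-diffusion near or above the threshold) and an error of class
#' `crowdperc_no_diffusive_window` is raised.
#'
#' @param curve an `msd_curve` data frame.
#' @param slope_tol admissible local log-slope range for "diffusive"
#'   (`estimator = "plateau"`).
#' @param min_decades minimum window width in decades of time
#'   (`estimator = "plateau"`).
#' @param estimator `"plateau"` applies the Einstein relation over the
#'   final window whose log-slope is compatible with 1; `"linear"` fits
#'   `msd = C + 4 D t` over the trailing 70% of the curve, absorbing the
#'   constant crossover offset `C` (which otherwise depresses the log-slope
#'   long after `D` has converged), and gates on agreement between the two
#'   halves of the window instead of on the raw slope.
#' @param conv_tol relative agreement required between the half-window `D`
#'   estimates for `estimator = "linear"`.
#' @return an `exponent_fit` with `name = "D"`; metadata records the local
#'   slope of the fitted window.
#' @export
diffusion_coefficient <- function(curve, slope_tol = c(0.95, 1.05),
                                  min_decades = 0.5,
                                  estimator = c("plateau", "linear"),
                                  conv_tol = 0.2) {
  estimator <- match.arg(estimator)
  if (estimator == "linear")
    return(diffusion_linear_fit(curve, conv_tol))
  keep <- curve$t > 0 & curve$msd > 0
  lt <- log10(curve$t[keep])
  lm_ <- log10(curve$msd[keep])
  n <- length(lt)
  if (n < 5) stop("MSD curve too short to assess diffusive behaviour")
  # regression log-slope over trailing windows of >= min_decades, with the
  # window end allowed to sit anywhere in the final half decade (robust to
  # pointwise ensemble noise)
  found <- NULL
  for (iend in n:1) {
    if (lt[n] - lt[iend] > 0.5) break
    win <- which(lt >= lt[iend] - 1.25 * min_decades & lt <= lt[iend])
    if (length(win) < 4 || lt[iend] - min(lt[win]) < min_decades) next
    s <- coef(lm(lm_[win] ~ lt[win]))[2]
    if (s >= slope_tol[1] && s <= slope_tol[2]) {
      found <- list(win = win, slope = unname(s))
      break
    }
  }
  if (is.null(found)) {
    stop(structure(
      class = c("crowdperc_no_diffusive_window", "error", "condition"),
      list(message = paste0(
             "no diffusive window: trailing MSD log-slope does not settle in [",
             slope_tol[1], ", ", slope_tol[2], "] over ", min_decades,
             " decades (sub-diffusive or under-sampled curve)"),
           call = sys.call(-1))))
  }
  idx <- which(keep)[found$win]
  Dvals <- curve$msd[idx] / (4 * curve$t[idx])
  # window points share trajectories, so their scatter understates the
  # sampling error; use the ensemble standard error of the MSD instead
  se <- if ("se" %in% names(curve)) {
    i_last <- idx[length(idx)]
    curve$se[i_last] / (4 * curve$t[i_last])
  } else {
    sd(Dvals) / sqrt(length(Dvals))
  }
  exponent_fit("D", mean(Dvals), se,
               fit_window = range(curve$t[idx]),
               metadata = list(slope = found$slope,
                               n_points = length(idx)))
}

# trailing linear fit msd = C + 4 D t with a split-window convergence gate
diffusion_linear_fit <- function(curve, conv_tol) {
  keep <- curve$t > 0 & curve$msd > 0
  cu <- curve[keep, ]
  n <- nrow(cu)
  if (n < 8) stop("MSD curve too short for the linear estimator")
  t_hi <- max(cu$t)
  w_full <- cu$t >= 0.3 * t_hi
  w_early <- cu$t >= 0.1 * t_hi & cu$t < 0.3 * t_hi
  if (sum(w_full) < 4 || sum(w_early) < 3)
    stop("MSD curve too sparse for the linear estimator")
  co <- coef(lm(msd ~ t, data = cu[w_full, ]))
  co_e <- coef(lm(msd ~ t, data = cu[w_early, ]))
  D <- co[2] / 4
  D_e <- co_e[2] / 4
  if (!is.finite(D) || D <= 0 || abs(D_e - D) > conv_tol * abs(D)) {
    stop(structure(
      class = c("crowdperc_no_diffusive_window", "error", "condition"),
      list(message = sprintf(
        paste0("no diffusive window: trailing linear MSD fits disagree ",
               "(D = %.3g vs %.3g earlier; tol %.0f%%)"),
        D, D_e, 100 * conv_tol), call = sys.call(-1))))
  }
  i_end <- which.max(cu$t)
  se <- if ("se" %in% names(cu))
    cu$se[i_end] / (4 * (t_hi - 0.3 * t_hi))
  else NA_real_
  lt <- log10(cu$t[w_full]); lmsd <- log10(cu$msd[w_full])
  exponent_fit("D", unname(D), se,
               fit_window = c(0.3 * t_hi, t_hi),
               metadata = list(slope = unname(coef(lm(lmsd ~ lt))[2]),
                               intercept = unname(co[1]),
                               D_early_window = unname(D_e),
                               n_points = sum(w_full)))
}

#' Diffusion coefficient versus area fraction
#'
#' Sweeps `phi`, building an ensemble MSD per point and extracting `D`;
#' points with no diffusive window are reported as `NA`.
#'
#' @inheritParams msd_curve
#' @param phi_values area fractions to sweep.
#' @param slope_tol,estimator passed to [diffusion_coefficient()].
#' @param t_max run length per point, recycled along `phi_values` (points
#'   nearer the threshold need longer runs to reach the diffusive regime).
#' @return data frame `(phi, D, se, slope)`.
#' @export
diffusion_vs_phi <- function(phi_values, L, delta, t_max, n_configs = 1,
                             n_tracers = 10, seed = 1, sigma = 1,
                             time_average = FALSE,
                             slope_tol = c(0.95, 1.05),
                             estimator = c("plateau", "linear")) {
  estimator <- match.arg(estimator)
  t_max <- rep_len(t_max, length(phi_values))
  rows <- lapply(seq_along(phi_values), function(i) {
    cu <- msd_curve(phi_values[i], L, delta, t_max[i], n_configs, n_tracers,
                    seed = seed + 2971 * i, sigma = sigma,
                    time_average = time_average)
    fit <- tryCatch(diffusion_coefficient(cu, slope_tol = slope_tol,
                                          estimator = estimator),
                    crowdperc_no_diffusive_window = function(e) NULL)
    data.frame(phi = phi_values[i],
               D = if (is.null(fit)) NA_real_ else fit$value,
               se = if (is.null(fit)) NA_real_ else fit$stderr,
               slope = if (is.null(fit)) NA_real_ else fit$metadata$slope)
  })
  do.call(rbind, rows)
}
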