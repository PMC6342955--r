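#' Transition-state-theory channel rate
#'
#' Under the local equilibrium approximation the escape rate through a
#' channel is the ratio of the transition-state to reactant partition
#' functions; for hard discs these are proportional to the channel gap `g`
#' and the pore's accessible area `A`, so `W_TST = max(g, 0) / A` (an
#' impassable channel has zero rate). Comparisons with numerically measured
#' rates multiply by the free-space diffusivity `D0 = delta^2 / 6` as the
#' Kramers-type prefactor.
#'
#' @param g channel gap(s).
#' @param A accessible pore area(s), strictly positive.
#' @return rate(s) in units of `1 / sigma` (prefactor not applied).
#' @export
tst_rate <- function(g, A) {
  if (any(A <= 0)) stop("accessible area A must be positive")
  pmax(g, 0) / A
}

#' TST escape-side probabilities of a pore
#'
#' `P_TST(i) = g_i / sum_i g_i` over the pore's three channels, with
#' negative gaps clamped to zero. Equal gaps give 1/3 each.
#'
#' @param gaps numeric length-3 (one pore) or an n x 3 matrix.
#' @return probabilities of the same shape, rows summing to 1.
#' @export
#' @examples
#' p_tst(c(1, 1, 1))         # 1/3 each
#' p_tst(c(1.0, -0.2, 0.5))  # (2/3, 0, 1/3)
p_tst <- function(gaps) {
  m <- if (is.matrix(gaps)) gaps else matrix(gaps, nrow = 1)
  stopifnot(ncol(m) == 3)
  m <- pmax(m, 0)
  tot <- rowSums(m)
  if (any(tot <= 0)) stop("closed pore: all three gaps are non-positive")
  out <- m / tot
  if (is.matrix(gaps)) out else as.numeric(out)
}

#' Numerical transition rate from first-passage statistics
#'
#' `W_num = P_num / (2 * tau_MFPT)`: the measured escape-side probability
#' over twice the pore's mean first-passage time.
#'
#' @param P_num escape probability (or probabilities).
#' @param tau_MFPT mean first-passage time(s), strictly positive.
#' @return rate(s) in inverse MC time units.
#' @export
numerical_rate <- function(P_num, tau_MFPT) {
  if (any(tau_MFPT <= 0)) stop("tau_MFPT must be positive")
  P_num / (2 * tau_MFPT)
}

#' First-passage sampling of pore escapes
#'
#' For each requested pore, tracers start uniformly over the accessible
#' region of the Delaunay triangle and evolve with the dynamic MC rules of
#' [run_simulation()] until the first accepted move whose endpoint leaves
#' the starting triangle; the elapsed time and exit side (first
#' starting-triangle edge crossed, in parametric order) are recorded.
#' Trials that do not escape within `step_cap` attempts are censored and
#' excluded from the mean.
#'
#' @param network a [pore_network][tessellate].
#' @param matrix the underlying [obstacle_matrix][generate_matrix].
#' @param delta maximum per-axis displacement.
#' @param n_trials trials per pore.
#' @param seed integer seed (per-pore streams are derived from it and the
#'   pore index, so subsetting pores does not change their results).
#' @param pores integer indices of pores to sample (default: every pore
#'   with at least one passable side); explicitly requesting a closed pore
#'   is an error.
#' @param step_cap attempted-move cap per trial before censoring.
#' @return data frame `(pore, tau_MFPT, n1, n2, n3, censored, n_escaped)`;
#'   pores whose accessible region could not be sampled (fully covered by
#'   exclusion discs) have `NA` statistics.
#' @export
first_passage <- function(network, matrix, delta, n_trials, seed,
                          pores = NULL, step_cap = 1e8) {
  stopifnot(delta > 0, n_trials >= 1)
  n_open <- open_sides_per_pore(network)
  if (is.null(pores)) {
    pores <- which(n_open > 0)
  } else if (any(n_open[pores] == 0)) {
    stop("closed pore(s) requested (no passable side): ",
         paste(head(pores[n_open[pores] == 0], 5), collapse = ", "),
         if (sum(n_open[pores] == 0) > 5) ", ..." else "")
  }
  res <- first_passage_cpp(matrix$positions, network$L, network$sigma,
                           network$tri_coords, network$edge_coords,
                           network$edges$passable, as.integer(pores),
                           delta, as.integer(n_trials), step_cap,
                           as.double(seed))
  data.frame(pore = pores, tau_MFPT = res[, "tau_mean"],
             n1 = res[, "n1"], n2 = res[, "n2"], n3 = res[, "n3"],
             censored = res[, "censored"], n_escaped = res[, "n_escaped"])
}

# number of passable sides of each pore
open_sides_per_pore <- function(network) {
  g <- pore_side_gaps(network)
  rowSums(g > 0)
}

# gap of each pore's side k (edge opposite vertex k), from the edge table
pore_side_gaps <- function(network) {
  T_ <- nrow(network$triangles)
  g <- matrix(NA_real_, T_, 3)
  e <- network$edges
  g[cbind(e$tri1, e$side1)] <- e$gap
  g[cbind(e$tri2, e$side2)] <- e$gap
  g
}

#' Per-channel rate table: TST versus numerical
#'
#' Combines the network geometry (gap `g`, accessible area `A`, `W_TST`,
#' `P_TST`) with first-passage measurements (`tau_MFPT`, `P_num`, `W_num`)
#' for every sampled pore and each of its three sides.
#'
#' @inheritParams first_passage
#' @return a data frame of class `rate_table` with columns `pore`, `side`,
#'   `g`, `A`, `W_TST`, `P_TST`, `tau_MFPT`, `P_num`, `W_num`, `n_trials`,
#'   `censored`. `P_num = N_i / n_trials`; censored trials are reported so
#'   heavy censoring is visible.
#' @export
rate_table <- function(network, matrix, delta, n_trials, seed,
                       pores = NULL, step_cap = 1e8) {
  if (is.null(pores)) pores <- which(open_sides_per_pore(network) > 0)
  fp <- first_passage(network, matrix, delta, n_trials, seed,
                      pores = pores, step_cap = step_cap)
  g3 <- pore_side_gaps(network)[pores, , drop = FALSE]
  A <- network$A[pores]
  open_pore <- rowSums(pmax(g3, 0)) > 0
  P_T <- matrix(NA_real_, length(pores), 3)
  if (any(open_pore)) P_T[open_pore, ] <- p_tst(g3[open_pore, , drop = FALSE])
  counts <- as.matrix(fp[, c("n1", "n2", "n3")])
  P_n <- counts / n_trials
  out <- data.frame(
    pore = rep(pores, each = 3),
    side = rep(1:3, times = length(pores)),
    g = as.vector(t(g3)),
    A = rep(A, each = 3),
    W_TST = as.vector(t(pmax(g3, 0) / A)),
    P_TST = as.vector(t(P_T)),
    tau_MFPT = rep(fp$tau_MFPT, each = 3),
    P_num = as.vector(t(P_n)),
    n_trials = n_trials,
    censored = rep(fp$censored, each = 3))
  has_tau <- !is.na(out$tau_MFPT) & out$tau_MFPT > 0
  out$W_num <- NA_real_
  out$W_num[has_tau] <- numerical_rate(out$P_num[has_tau],
                                       out$tau_MFPT[has_tau])
  class(out) <- c("rate_table", class(out))
  attr(out, "delta") <- delta
  out
}

#' Logarithmically binned rate distribution
#'
#' Normalised density `rho(W)` of positive rates on logarithmic bins
#' (default 10 per decade); zero rates are excluded from the density and
#' reported as an attribute.
#'
#' @param rates numeric rates (at least 100 positive values).
#' @param bins_per_decade log-bin resolution.
#' @param weights optional per-rate weights (e.g. inverse detection
#'   probabilities for rates estimated from finite trial counts); the
#'   density then estimates the weighted distribution, while `count` stays
#'   the raw occupancy.
#' @return data frame `(W, density, count, width)` with `W` the geometric
#'   bin centre; `sum(density * width) = 1`. Attribute `zero_fraction`.
#' @export
rate_distribution <- function(rates, bins_per_decade = 10, weights = NULL) {
  keep <- !is.na(rates)
  rates <- rates[keep]
  if (!is.null(weights)) weights <- weights[keep]
  if (length(rates) == 0 || all(rates <= 0))
    stop("no positive rates to bin")
  pos_sel <- rates > 0
  pos <- rates[pos_sel]
  w <- if (is.null(weights)) rep(1, length(pos)) else weights[pos_sel]
  if (length(pos) < 100)
    stop("need at least 100 positive rates for a stable log-binned density")
  # exact binning on the log scale (hist() fuzzing is unreliable when bin
  # widths span many orders of magnitude)
  lo <- floor(log10(min(pos)) * bins_per_decade) / bins_per_decade
  idx <- floor((log10(pos) - lo) * bins_per_decade + 1e-9) + 1
  nb <- max(idx)
  counts <- tabulate(idx, nbins = nb)
  wsum <- vapply(seq_len(nb), function(b) sum(w[idx == b]), numeric(1))
  edges <- 10^(lo + (0:nb) / bins_per_decade)
  width <- diff(edges)
  out <- data.frame(W = sqrt(edges[-length(edges)] * edges[-1]),
                    density = wsum / (sum(w) * width),
                    count = counts, width = width)
  attr(out, "zero_fraction") <- mean(rates <= 0)
  out
}

#' Fit the small-rate singularity exponent alpha
#'
#' Weighted least squares of `log rho(W)` on `log W` over the small-W fit
#' window: the lowest `window_decades` decades among bins with at least
#' `min_count` entries. `rho(W) ~ W^-alpha`, so `alpha` is minus the slope;
#' `alpha = 0` means the distribution flattens to a plateau at small rates
#' (the TST expectation), `alpha > 0` a genuine power-law singularity.
#'
#' @param rho a [rate_distribution()] data frame.
#' @param window_decades width of the small-W fit window in decades.
#' @param min_count minimum bin occupancy for a bin to enter the fit.
#' @param w_min reliability floor: bins below this rate are excluded (for
#'   first-passage rates, rates whose expected escape counts are only a few
#'   per pore are Poisson-thinned and bias the density downwards; see
#'   [fit_alpha_rates()]).
#' @param cap_at_mode when the maximum of the (eligible) density sits well
#'   above the smallest eligible rate, restrict the fit to the region below
#'   the mode: `alpha` describes the `W -> 0` limit, and fitting across a
#'   non-monotone bulk peak would measure the bulk's flank instead. A
#'   negative fitted `alpha` then means the density decreases towards small
#'   rates, i.e. no singularity.
#' @return an `exponent_fit` with `name = "alpha"`.
#' @export
fit_alpha <- function(rho, window_decades = 1.5, min_count = 10,
                      w_min = 0, cap_at_mode = TRUE) {
  ok <- rho$count >= min_count & rho$density > 0 & rho$W >= w_min
  if (!any(ok)) stop("no bins reach the minimum occupancy")
  w_lo <- min(rho$W[ok])
  win <- ok & rho$W <= w_lo * 10^window_decades
  if (cap_at_mode) {
    w_mode <- rho$W[ok][which.max(rho$density[ok])]
    if (w_mode > w_lo * 10^0.4)
      win <- win & rho$W < w_mode
  }
  if (sum(win) < 5)
    stop("insufficient small-W support: fewer than 5 occupied bins in the window")
  x <- log(rho$W[win])
  y <- log(rho$density[win])
  fit <- lm(y ~ x, weights = rho$count[win])
  est <- summary(fit)$coefficients
  exponent_fit("alpha", -est["x", 1], est["x", 2],
               fit_window = range(rho$W[win]),
               metadata = list(n_bins = sum(win), min_count = min_count,
                               w_min = w_min))
}

#' Singularity exponent from a rate table
#'
#' Convenience wrapper: log-bins the positive numerical rates of a
#' [rate_table()] and fits `alpha`. Channels are weighted by the inverse
#' of their Poisson detection probability `1 - exp(-N_i)` (a channel whose
#' expected escape count is of order one is seen in only a fraction of
#' tables, which would otherwise thin the small-rate density), and rates
#' below the scale where even the typical pore expects fewer than
#' `detect_factor` escapes are excluded via
#' `w_min = detect_factor / (2 * n_trials * median(tau_MFPT))`. The
#' returned fit may have a negative `value`; as a singularity strength use
#' `max(0, value)` (a density that decreases towards small rates has no
#' singularity).
#'
#' @param rt a [rate_table()].
#' @param detect_factor expected escape count at the smallest trusted rate
#'   for a typical pore.
#' @param ... passed to [fit_alpha()].
#' @return an `exponent_fit` with `name = "alpha"`.
#' @export
fit_alpha_rates <- function(rt, detect_factor = 1, ...) {
  ok <- !is.na(rt$W_num) & rt$W_num > 0
  if (!any(ok)) stop("rate table has no positive numerical rates")
  n_esc <- rt$P_num[ok] * rt$n_trials[ok]
  w_detect <- 1 / (1 - exp(-pmax(n_esc, 1e-9)))
  tau_med <- stats::median(rt$tau_MFPT[ok])
  w_min <- detect_factor / (2 * rt$n_trials[1] * tau_med)
  fit_alpha(rate_distribution(rt$W_num[ok], weights = w_detect),
            w_min = w_min, ...)
}

#' Distribution of the ratio P_num / P_TST
#'
#' Density of the per-channel ratio of measured to TST escape
#' probabilities on a linear grid covering at least `[0, 3]`. A sharp peak
#' at 1 means TST captures the channel choice; mass far from 1 signals its
#' breakdown.
#'
#' @param P_num,P_TST paired probabilities; pairs with `P_TST <= 0` or
#'   missing entries are dropped.
#' @param bin_width linear bin width.
#' @return data frame `(ratio, density, count)`; attribute
#'   `outside_fraction` gives the probability mass with ratio outside
#'   `[0.4, 1.6]`.
#' @export
ratio_distribution <- function(P_num, P_TST, bin_width = 0.05) {
  keep <- !is.na(P_num) & !is.na(P_TST) & P_TST > 0
  r <- P_num[keep] / P_TST[keep]
  if (length(r) == 0) stop("no valid probability pairs")
  top <- max(3, ceiling(max(r) / bin_width) * bin_width)
  edges <- seq(0, top + bin_width / 2, by = bin_width)
  h <- graphics::hist(r, breaks = edges, plot = FALSE)
  out <- data.frame(ratio = h$mids, density = h$density, count = h$counts)
  attr(out, "outside_fraction") <- mean(r < 0.4 | r > 1.6)
  out
}
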