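#' Area fraction of a disc matrix
#'
#' The fraction of the periodic box covered by `N` discs of diameter
#' `sigma`: `phi = pi * N * sigma^2 / (4 * L^2)`.
#'
#' @param N number of discs (non-negative integer).
#' @param L box edge length (in units of sigma).
#' @param sigma disc diameter (default 1, the unit of length).
#' @return the area fraction, a number in `[0, 1)` for valid inputs.
#' @export
#' @examples
#' area_fraction(400, 50)
area_fraction <- function(N, L, sigma = 1) {
  stopifnot(L > 0, N >= 0)
  pi * N * sigma^2 / (4 * L^2)
}

#' Generate a quenched random obstacle matrix (RSA)
#'
#' Places `N = round(4 * phi * L^2 / (pi * sigma^2))` hard discs of diameter
#' `sigma` sequentially at uniform random positions in a periodic square box
#' `[0, L)^2`, rejecting any trial position that overlaps a previously
#' placed disc (random sequential adsorption). The discs are then quenched:
#' they never move again.
#'
#' @param phi target area fraction, in `[0, 1)` and below the RSA jamming
#'   density (~0.547 for discs).
#' @param L box edge length, at least `10 * sigma`.
#' @param seed integer seed; identical `(seed, phi, L)` give identical
#'   matrices.
#' @param sigma disc diameter (default 1).
#' @param max_attempts per-disc insertion attempt cap; exceeding it raises a
#'   saturation error (phi too high for RSA).
#' @return an object of class `obstacle_matrix`: a list with `positions`
#'   (N x 2 matrix of centres in `[0, L)`), `L`, `sigma`, `N`, `phi`
#'   (realised area fraction `pi N / 4 L^2`), and `seed`.
#' @export
#' @examples
#' m <- generate_matrix(0.12566, L = 50, seed = 1)
#' m$N   # 400
generate_matrix <- function(phi, L, seed, sigma = 1, max_attempts = 1e6) {
  stopifnot(phi >= 0, phi < 1, L > 0)
  if (phi >= 0.547)
    stop("phi = ", phi, " is at or above the RSA jamming density (~0.547)")
  if (L < 10 * sigma)
    stop("L must be at least 10 * sigma")
  N <- as.integer(round(4 * phi * L^2 / (pi * sigma^2)))
  pos <- rsa_generate_cpp(N, L, sigma, as.double(seed), max_attempts)
  colnames(pos) <- c("x", "y")
  structure(
    list(positions = pos, L = L, sigma = sigma, N = N,
         phi = area_fraction(N, L, sigma), seed = seed),
    class = "obstacle_matrix")
}

#' @export
print.obstacle_matrix <- function(x, ...) {
  cat(sprintf("<obstacle_matrix> N = %d discs, L = %g, phi = %.5f, seed = %s\n",
              x$N, x$L, x$phi, format(x$seed)))
  invisible(x)
}

#' Radial distribution function of the matrix discs
#'
#' Standard pair-correlation estimator `g(r)` from a minimum-image pair
#' histogram, normalised by ideal-gas shell counts, so `g(r) -> 1` at large
#' separations.
#'
#' @param matrix an [obstacle_matrix][generate_matrix].
#' @param dr radial bin width.
#' @param r_max maximum separation; must not exceed `L / 2` (minimum-image
#'   validity).
#' @return a data frame with bin centres `r`, the estimate `g`, and raw pair
#'   `count`s.
#' @export
radial_distribution <- function(matrix, dr = 0.05, r_max = matrix$L / 2) {
  if (r_max > matrix$L / 2)
    stop("r_max must not exceed L/2: periodic images become ambiguous")
  N <- matrix$N
  if (N < 2) stop("need at least 2 discs for g(r)")
  h <- pair_histogram_cpp(matrix$positions, matrix$L, dr, r_max)
  nb <- length(h)
  r_lo <- (seq_len(nb) - 1) * dr
  r_hi <- r_lo + dr
  shell <- pi * (r_hi^2 - r_lo^2)
  rho <- N / matrix$L^2
  data.frame(r = r_lo + dr / 2, g = h / (N * rho * shell), count = h)
}

#' Place non-overlapping tracers in the void space
#'
#' Tracers (hard discs of the same diameter `sigma`) are inserted at uniform
#' random positions subject to no overlap with any matrix disc and, at
#' placement only, no overlap with each other. During the subsequent
#' dynamics tracer-tracer interactions are switched off.
#'
#' @param matrix an [obstacle_matrix][generate_matrix].
#' @param n_tracers number of tracers.
#' @param seed integer seed.
#' @param max_attempts per-tracer attempt cap before an error.
#' @return an `n_tracers` x 2 matrix of initial positions.
#' @export
place_tracers <- function(matrix, n_tracers, seed, max_attempts = 1e6) {
  stopifnot(n_tracers >= 1)
  pos <- place_tracers_cpp(matrix$positions, n_tracers, matrix$L,
                           matrix$sigma, as.double(seed), max_attempts)
  colnames(pos) <- c("x", "y")
  pos
}

#' Write / read an obstacle matrix as delimited text
#'
#' The format is a plain CSV with `x,y` columns preceded by comment lines
#' `# L=... sigma=... phi=... seed=...`; coordinates are written at full
#' double precision so the round-trip is lossless.
#'
#' @param matrix an [obstacle_matrix][generate_matrix].
#' @param path file path.
#' @return `write_matrix` returns `path` invisibly; `read_matrix` returns
#'   the reconstructed `obstacle_matrix`.
#' @export
write_matrix <- function(matrix, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# L=%.17g sigma=%.17g phi=%.17g seed=%s",
            matrix$L, matrix$sigma, matrix$phi, format(matrix$seed, digits = 17)),
    "x,y"), con)
  if (matrix$N > 0)
    writeLines(sprintf("%.17g,%.17g",
                       matrix$positions[, 1], matrix$positions[, 2]), con)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  header <- readLines(path, n = 1)
  fields <- regmatches(header, gregexpr("[A-Za-z]+=[-0-9.eE+]+", header))[[1]]
  kv <- do.call(rbind, strsplit(fields, "="))
  meta <- setNames(as.numeric(kv[, 2]), kv[, 1])
  df <- read.csv(path, comment.char = "#")
  pos <- as.matrix(df)
  colnames(pos) <- c("x", "y")
  structure(
    list(positions = pos, L = meta[["L"]], sigma = meta[["sigma"]],
         N = nrow(pos), phi = area_fraction(nrow(pos), meta[["L"]], meta[["sigma"]]),
         seed = meta[["seed"]]),
    class = "obstacle_matrix")
}
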