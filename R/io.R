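#' Write / read an MSD curve as delimited text
#'
#' Plain CSV with columns `t,msd,se,n_samples` preceded by a comment
#' header carrying the ensemble metadata (`phi`, `delta`, `L`); numeric
#' values are written at full double precision so the round-trip is
#' lossless.
#'
#' @param curve an `msd_curve` data frame (see [msd()]).
#' @param path file path.
#' @return `write_msd_curve` returns `path` invisibly; `read_msd_curve`
#'   returns the reconstructed `msd_curve`.
#' @export
write_msd_curve <- function(curve, path) {
  con <- file(path, "w")
  on.exit(close(con))
  meta <- function(x) if (is.null(x)) NA_real_ else x
  writeLines(c(
    sprintf("# phi=%.17g delta=%.17g L=%.17g",
            meta(attr(curve, "phi")), meta(attr(curve, "delta")),
            meta(attr(curve, "L"))),
    "t,msd,se,n_samples"), con)
  se <- if ("se" %in% names(curve)) curve$se else rep(NA_real_, nrow(curve))
  writeLines(sprintf("%.17g,%.17g,%.17g,%d",
                     curve$t, curve$msd, se, curve$n_samples), con)
  invisible(path)
}

#' @rdname write_msd_curve
#' @export
read_msd_curve <- function(path) {
  header <- readLines(path, n = 1)
  fields <- regmatches(header, gregexpr("[A-Za-z]+=[-0-9.eE+]+", header))[[1]]
  kv <- do.call(rbind, strsplit(fields, "="))
  meta <- setNames(as.numeric(kv[, 2]), kv[, 1])
  out <- read.csv(path, comment.char = "#",
                  colClasses = c("numeric", "numeric", "numeric", "integer"))
  class(out) <- c("msd_curve", class(out))
  attr(out, "phi") <- meta[["phi"]]
  attr(out, "delta") <- meta[["delta"]]
  attr(out, "L") <- meta[["L"]]
  out
}

#' Write a pore network as JSON
#'
#' Serialises the tessellation: per-pore vertex index triples, areas and
#' accessible areas, and per-channel incidence, gap and passability.
#'
#' @param network a [pore_network][tessellate].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  jsonlite::write_json(list(
    L = network$L, sigma = network$sigma, N = network$N,
    triangles = unclass(network$triangles),
    tri_area = network$tri_area,
    accessible_area = network$A,
    edges = network$edges[, c("tri1", "side1", "tri2", "side2",
                              "length", "gap", "passable")]),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
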