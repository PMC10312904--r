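# Photon statistics of the fan-beam measurement: Poisson counts around a
# Beer-Lambert mean, and the quadratic (penalized weighted least squares)
# surrogate of the Poisson negative log-likelihood used by the iterative
# reconstructions.

.n0_matrix <- function(n0, geometry) {
  if (any(n0 <= 0)) stop("blank-scan counts n0 must be > 0")
  if (length(n0) == 1L) matrix(n0, geometry$n_views, geometry$n_detectors)
  else {
    n0 <- as.matrix(n0)
    if (nrow(n0) != geometry$n_views || ncol(n0) != geometry$n_detectors)
      stop("per-ray n0 shape does not match the geometry")
    n0
  }
}

#' Expected photon counts from line integrals
#'
#' Beer-Lambert: `ybar = n0 * exp(-p)` elementwise, with `p` the line
#' integrals and `n0` the blank-scan counts.
#'
#' @param line_integrals A `sinogram` tagged `line_integrals`.
#' @param n0 Blank-scan counts per detector element (scalar or per-ray
#'   matrix), > 0.
#' @return A `sinogram` of real-valued expected counts (tagged
#'   `photon_counts` is reserved for integer draws; the expectation keeps
#'   the line-integral container semantics via the `"expected_counts"`
#'   attribute).
#' @export
expected_counts <- function(line_integrals, n0) {
  .check_domain(line_integrals, "line_integrals")
  n0 <- .n0_matrix(n0, line_integrals$geometry)
  out <- sinogram(n0 * exp(-line_integrals$values), "line_integrals",
                  line_integrals$geometry)
  out$domain <- "expected_counts"
  out
}

#' Poisson measurement simulation
#'
#' Independent Poisson draws per ray around the expected counts;
#' deterministic given the seed (the global RNG state is preserved).
#'
#' @param expected A sinogram of expected counts (from [expected_counts()])
#'   or a non-negative numeric matrix.
#' @param seed Integer seed.
#' @return A `sinogram` tagged `photon_counts`.
#' @export
sample_counts <- function(expected, seed) {
  if (inherits(expected, "sinogram")) {
    geometry <- expected$geometry
    ev <- expected$values
  } else stop("expected must be a sinogram of expected counts")
  if (any(ev < 0)) stop("expected counts must be non-negative")
  y <- .with_seed(seed, stats::rpois(length(ev), as.vector(ev)))
  sinogram(matrix(y, nrow(ev), ncol(ev)), "photon_counts", geometry)
}

#' Weighted sinogram system for quadratic reconstruction
#'
#' Second-order surrogate of the Poisson likelihood around the measured
#' counts: line-integral estimates `b_i = log(n0_i / max(y_i, y_floor))` and
#' statistical weights `D_ii = max(y_i, y_floor)` (the measured counts, as
#' in the diagonal weighting of the quadratic objective). The floor (default
#' one count) keeps the log and the weights defined on zero-count rays.
#'
#' @param counts A `sinogram` tagged `photon_counts`.
#' @param n0 Blank-scan counts (scalar or per-ray), > 0.
#' @param y_floor Count floor applied before the log and in D (default 1).
#' @return An object of class `wls_system` with elements `b`, `D`
#'   (matrices `n_views x n_detectors`) and `geometry`.
#' @export
linearize <- function(counts, n0, y_floor = 1) {
  .check_domain(counts, "photon_counts")
  n0 <- .n0_matrix(n0, counts$geometry)
  if (y_floor <= 0) stop("y_floor must be > 0")
  y <- pmax(counts$values, y_floor)
  structure(list(b = log(n0 / y), D = y, geometry = counts$geometry),
            class = "wls_system")
}

#' @export
print.wls_system <- function(x, ...) {
  cat(sprintf("Weighted sinogram system: %d x %d rays, b in [%.3g, %.3g], D in [%.3g, %.3g]\n",
              nrow(x$b), ncol(x$b), min(x$b), max(x$b), min(x$D), max(x$D)))
  invisible(x)
}

#' Poisson negative log-likelihood of an image (prior term excluded)
#'
#' `sum_i [ybar_i - y_i * log(ybar_i)]` with `ybar = n0 * exp(-A mu)`.
#' Used to monitor the data-fidelity of iterates and to validate the
#' quadratic surrogate of [linearize()].
#'
#' @param mu An `image_grid` or matrix matching the projector grid.
#' @param counts A `sinogram` tagged `photon_counts`.
#' @param n0 Blank-scan counts, > 0.
#' @param proj A `ct_projector`.
#' @return A scalar.
#' @export
neg_log_likelihood <- function(mu, counts, n0, proj) {
  .check_domain(counts, "photon_counts")
  p <- forward_project(mu, proj)
  ybar <- .n0_matrix(n0, counts$geometry) * exp(-p$values)
  y <- counts$values
  if (any(ybar == 0 & y > 0))
    stop("zero expected counts on a ray with observed photons: likelihood undefined")
  term <- ybar - ifelse(y > 0, y * log(ybar), 0)
  sum(term)
}
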