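#' Fan-beam projector
#'
#' Builds the discrete system operator A for a geometry/grid pairing.
#' The implementation is ray-driven with Joseph-style linear interpolation,
#' and the backprojector scatters through the identical weights, so
#' [forward_project()] and [back_project()] are an exact adjoint pair --
#' the same sparse matrix and its transpose. Matrix-free in production;
#' [materialize_system_matrix()] builds the explicit (dense) A for small
#' grids where exact oracles are wanted.
#'
#' @param geometry A `scan_geometry`.
#' @param n Image grid size (pixels per side).
#' @param pixel_size Pixel size in mm; defaults to a grid inscribed in the
#'   scan circle ([default_pixel_size()]).
#' @return An object of class `ct_projector`.
#' @export
projector <- function(geometry, n, pixel_size = NULL) {
  stopifnot(inherits(geometry, "scan_geometry"))
  n <- as.integer(n)
  if (is.null(pixel_size)) pixel_size <- default_pixel_size(geometry, n)
  structure(list(geometry = geometry, n = n,
                 pixel_size = as.numeric(pixel_size),
                 method = "joseph-ray-driven"),
            class = "ct_projector")
}

#' @export
print.ct_projector <- function(x, ...) {
  cat(sprintf("Fan-beam projector (%s): %d x %d grid at %.4g mm, %d views x %d detectors\n",
              x$method, x$n, x$n, x$pixel_size,
              x$geometry$n_views, x$geometry$n_detectors))
  invisible(x)
}

.proj_args <- function(proj) {
  g <- proj$geometry
  list(angles = g$view_angles, ndet = g$n_detectors,
       dgamma = detector_angular_pitch(g), rs = g$source_to_center,
       h = proj$pixel_size, n = proj$n)
}

#' Forward projection (line integrals)
#'
#' Applies the system operator A: each sinogram entry is the weighted sum of
#' pixel values along the ray from the source at that view to that detector
#' element, approximating the Beer-Lambert path integral of the attenuation.
#'
#' @param image An `image_grid` or numeric matrix matching the projector grid.
#' @param proj A `ct_projector`.
#' @return A `sinogram` in the line-integral domain (dimensionless).
#' @export
forward_project <- function(image, proj) {
  stopifnot(inherits(proj, "ct_projector"))
  v <- if (inherits(image, "image_grid")) image$values else as.matrix(image)
  if (nrow(v) != proj$n || ncol(v) != proj$n)
    stop(sprintf("image is %d x %d but the projector grid is %d x %d",
                 nrow(v), ncol(v), proj$n, proj$n))
  a <- .proj_args(proj)
  s <- fan_forward_cpp(v, a$angles, a$ndet, a$dgamma, a$rs, a$h)
  sinogram(s, "line_integrals", proj$geometry)
}

#' Backprojection (exact transpose of the forward projector)
#'
#' Applies t(A) as a linear map; this is the adjoint used inside the
#' iterative reconstructions, not the filtered/weighted backprojection of
#' FBP.
#'
#' @param sino A `sinogram` (line integrals or residuals) or numeric matrix.
#' @param proj A `ct_projector`.
#' @return An `image_grid` (units: accumulated weight, not attenuation).
#' @export
back_project <- function(sino, proj) {
  stopifnot(inherits(proj, "ct_projector"))
  v <- if (inherits(sino, "sinogram")) {
    if (sino$domain == "photon_counts")
      stop("backprojection operates on line integrals / residuals, not photon counts")
    sino$values
  } else as.matrix(sino)
  g <- proj$geometry
  if (nrow(v) != g$n_views || ncol(v) != g$n_detectors)
    stop("sinogram shape does not match the projector geometry")
  a <- .proj_args(proj)
  img <- fan_back_cpp(v, a$angles, a$ndet, a$dgamma, a$rs, a$h, a$n)
  image_grid(img, proj$pixel_size)
}

#' Materialize the system matrix
#'
#' Builds the explicit m x n^2 matrix of the projector by forward-projecting
#' unit pixels; intended for grids up to about 64 x 64 where exact linear
#' algebra oracles (dense solves, eigendecompositions) are affordable.
#' Columns are ordered like `as.vector(image)` (column-major).
#'
#' @param proj A `ct_projector`.
#' @return A dense matrix with `n_views * n_detectors` rows.
#' @export
materialize_system_matrix <- function(proj) {
  n <- proj$n
  if (n > 64L) warning("materializing the system matrix for a grid > 64 x 64")
  a <- .proj_args(proj)
  m <- a$ndet * length(a$angles)
  A <- matrix(0, m, n * n)
  e <- matrix(0, n, n)
  for (j in seq_len(n * n)) {
    e[j] <- 1
    A[, j] <- as.vector(fan_forward_cpp(e, a$angles, a$ndet, a$dgamma, a$rs, a$h))
    e[j] <- 0
  }
  A
}

#' Extreme eigenvalues of a symmetric positive semi-definite operator
#'
#' Power iteration for the largest eigenvalue, then power iteration on
#' `lambda_max * I - M` for the smallest. `op` must implement a symmetric
#' PSD matrix-vector product.
#'
#' @param op Function mapping a numeric vector of length `n` to another.
#' @param n Dimension.
#' @param n_iters Power iterations per extreme (default 200).
#' @param seed Seed for the random start vectors.
#' @return Named numeric vector `c(lambda_min, lambda_max)`.
#' @export
extreme_eigs <- function(op, n, n_iters = 200L, seed = 1L) {
  .with_seed(seed, {
    pow <- function(f) {
      v <- stats::rnorm(n)
      v <- v / sqrt(sum(v^2))
      lam <- 0
      for (i in seq_len(n_iters)) {
        w <- f(v)
        lam <- sum(v * w)
        nw <- sqrt(sum(w * w))
        if (nw == 0) return(0)
        v <- w / nw
      }
      lam
    }
    lmax <- pow(op)
    lmin <- lmax - pow(function(v) lmax * v - op(v))
    c(lambda_min = lmin, lambda_max = lmax)
  })
}

#' Spectral extremes of the weighted normal operator t(A) D A
#'
#' Estimates the smallest and largest eigenvalues of `t(A) %*% D %*% A`
#' (A the projector, D the diagonal statistical weights) by matrix-free
#' power iteration; these bound the admissible step sizes of the iterative
#' reconstructions.
#'
#' @param proj A `ct_projector`.
#' @param D Per-ray weights: matrix `n_views x n_detectors` (or scalar),
#'   strictly positive.
#' @param n_iters Power iterations (default 200, relative accuracy about
#'   1e-3 on well-separated spectra).
#' @param seed Seed for the start vectors.
#' @return Named numeric vector `c(lambda_min, lambda_max)`.
#' @export
estimate_extreme_eigs <- function(proj, D = 1, n_iters = 200L, seed = 1L) {
  stopifnot(inherits(proj, "ct_projector"))
  g <- proj$geometry
  if (length(D) == 1L) D <- matrix(D, g$n_views, g$n_detectors)
  if (any(D <= 0)) stop("weights D must be strictly positive")
  if (nrow(D) != g$n_views || ncol(D) != g$n_detectors)
    stop("D shape does not match the geometry")
  a <- .proj_args(proj)
  op <- function(v) {
    img <- matrix(v, proj$n, proj$n)
    s <- fan_forward_cpp(img, a$angles, a$ndet, a$dgamma, a$rs, a$h)
    as.vector(fan_back_cpp(D * s, a$angles, a$ndet, a$dgamma, a$rs, a$h, a$n))
  }
  extreme_eigs(op, proj$n^2, n_iters = n_iters, seed = seed)
}
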