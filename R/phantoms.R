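# Synthetic piecewise-constant ellipse phantoms: the package's stand-in for
# a clinical training corpus. Rendering samples each pixel centre (no
# anti-aliasing), so a pixel's value is exactly the sum of the deltas of the
# ellipses containing it -- which keeps the indicator-sum oracle exact.

.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Ellipse phantom specification
#'
#' @param center_x,center_y Ellipse centres (mm), grid-centred coordinates.
#' @param a,b Semi-axes (mm), > 0.
#' @param rot Rotation of the a-axis from +x, radians, counter-clockwise.
#' @param delta Attenuation increment inside the ellipse (mm^-1); overlapping
#'   ellipses add.
#' @return A data frame of class `ellipse_spec`.
#' @export
ellipse_spec <- function(center_x, center_y, a, b, rot, delta) {
  if (any(a <= 0) || any(b <= 0)) stop("semi-axes must be > 0")
  structure(data.frame(center_x = center_x, center_y = center_y,
                       a = a, b = b, rot = rot, delta = delta),
            class = c("ellipse_spec", "data.frame"))
}

.pixel_coords <- function(n, pixel_size) ((seq_len(n) - 1) - (n - 1) / 2) * pixel_size

#' Render an ellipse phantom onto a grid
#'
#' Pixel value = sum of `delta` over the ellipses whose interior contains the
#' pixel centre. Deterministic; no anti-aliasing.
#'
#' @param spec An `ellipse_spec`.
#' @param n Grid size (>= 8).
#' @param pixel_size Pixel size in mm.
#' @return An `image_grid`.
#' @export
render_phantom <- function(spec, n, pixel_size) {
  n <- as.integer(n)
  if (n < 8L) stop("grid size must be >= 8")
  half <- n * pixel_size / 2
  v <- matrix(0, n, n)
  xs <- .pixel_coords(n, pixel_size)
  for (k in seq_len(nrow(spec))) {
    e <- spec[k, ]
    # bounding box of the rotated ellipse must fit inside the grid square
    bw <- sqrt((e$a * cos(e$rot))^2 + (e$b * sin(e$rot))^2)
    bh <- sqrt((e$a * sin(e$rot))^2 + (e$b * cos(e$rot))^2)
    if (abs(e$center_x) + bw > half || abs(e$center_y) + bh > half)
      stop(sprintf("ellipse %d extends outside the %g mm field of view", k, 2 * half))
    dx <- outer(xs - e$center_x, rep(1, n))
    dy <- outer(rep(1, n), xs - e$center_y)
    u <- (dx * cos(e$rot) + dy * sin(e$rot)) / e$a
    w <- (-dx * sin(e$rot) + dy * cos(e$rot)) / e$b
    v <- v + e$delta * (u * u + w * w <= 1)
  }
  image_grid(v, pixel_size)
}

#' Ellipse table of the built-in head phantom
#'
#' A left-right symmetrised variant of the classic modified Shepp-Logan
#' head phantom (the two inner voids are given mirror-identical shapes so
#' the rendered image equals its own mirror). Coordinates and semi-axes are
#' fractions of the grid half-extent; deltas are scaled so the outer skull
#' ellipse contributes 0.04 mm^-1.
#'
#' @return An `ellipse_spec` in fractional units (delta in mm^-1).
#' @export
shepp_logan_ellipses <- function() {
  s <- 0.04
  ellipse_spec(
    center_x = c(0, 0, 0.22, -0.22, 0, 0, 0, -0.06, 0, 0.06),
    center_y = c(0, -0.0184, 0, 0, 0.35, 0.1, -0.1, -0.605, -0.606, -0.605),
    a = c(0.69, 0.6624, 0.11, 0.11, 0.21, 0.046, 0.046, 0.046, 0.023, 0.046),
    b = c(0.92, 0.874, 0.31, 0.31, 0.25, 0.046, 0.046, 0.023, 0.023, 0.023),
    rot = c(0, 0, -18, 18, 0, 0, 0, 0, 0, 0) * pi / 180,
    delta = c(1, -0.8, -0.2, -0.2, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1) * s)
}

#' Head phantom
#'
#' Renders the built-in symmetrised head phantom (see
#' [shepp_logan_ellipses()]) at grid size `n`.
#'
#' @param n Grid size (>= 32).
#' @param pixel_size Pixel size in mm; default spans a 220 mm field of view.
#' @return An `image_grid` with skull attenuation about 0.04 mm^-1 and zero
#'   background.
#' @export
shepp_logan <- function(n, pixel_size = 220 / n) {
  n <- as.integer(n)
  if (n < 32L) stop("grid size must be >= 32")
  half <- n * pixel_size / 2
  e <- shepp_logan_ellipses()
  e[c("center_x", "center_y", "a", "b")] <-
    lapply(e[c("center_x", "center_y", "a", "b")], function(z) z * half)
  render_phantom(e, n, pixel_size)
}

#' Random piecewise-constant anatomy phantom
#'
#' A large soft-tissue "body" ellipse plus a random number of internal
#' ellipses with attenuation increments drawn from `attenuation_range`.
#' A pure function of the seed: the global RNG state is left untouched.
#'
#' @param seed Integer seed.
#' @param n Grid size.
#' @param pixel_size Pixel size (mm); default spans 360 mm.
#' @param n_ellipses_range Integer range for the number of internal ellipses.
#' @param attenuation_range Range of internal deltas (mm^-1), non-negative so
#'   the rendered image is non-negative.
#' @return An `image_grid`.
#' @export
random_phantom <- function(seed, n = 128, pixel_size = 360 / n,
                           n_ellipses_range = c(3L, 8L),
                           attenuation_range = c(0.001, 0.008)) {
  if (any(attenuation_range < 0)) stop("attenuation_range must be non-negative")
  half <- n * pixel_size / 2
  .with_seed(seed, {
    body_a <- stats::runif(1, 0.55, 0.8) * half
    body_b <- stats::runif(1, 0.55, 0.8) * half
    body_rot <- stats::runif(1, -0.3, 0.3)
    body_mu <- stats::runif(1, 0.018, 0.022)  # soft tissue
    k <- sample(seq(n_ellipses_range[1], n_ellipses_range[2]), 1)
    cx <- cy <- a <- b <- rot <- dl <- numeric(k)
    for (i in seq_len(k)) {
      a[i] <- stats::runif(1, 0.03, 0.22) * half
      b[i] <- stats::runif(1, 0.03, 0.22) * half
      rot[i] <- stats::runif(1, 0, pi)
      # keep the insert well inside the body ellipse
      r <- stats::runif(1, 0, 0.6)
      th <- stats::runif(1, 0, 2 * pi)
      cx[i] <- r * body_a * cos(th)
      cy[i] <- r * body_b * sin(th)
      dl[i] <- stats::runif(1, attenuation_range[1], attenuation_range[2])
    }
    spec <- ellipse_spec(center_x = c(0, cx), center_y = c(0, cy),
                         a = c(body_a, a), b = c(body_b, b),
                         rot = c(body_rot, rot), delta = c(body_mu, dl))
    render_phantom(spec, n, pixel_size)
  })
}

#' Extract random training patches from an image
#'
#' Axis-aligned square patches fully inside the image, positions uniform at
#' random, deterministic given the seed.
#'
#' @param image An `image_grid` or numeric matrix.
#' @param patch_size Patch side length (default 32).
#' @param n_patches Number of patches.
#' @param seed Integer seed.
#' @return A 3-D array `patch_size x patch_size x n_patches`; the patch
#'   corner coordinates are attached as attribute `"corners"`.
#' @export
extract_patches <- function(image, patch_size = 32L, n_patches, seed) {
  v <- if (inherits(image, "image_grid")) image$values else as.matrix(image)
  patch_size <- as.integer(patch_size)
  if (patch_size > nrow(v) || patch_size > ncol(v))
    stop("patch_size exceeds the image size")
  .with_seed(seed, {
    i0 <- sample.int(nrow(v) - patch_size + 1L, n_patches, replace = TRUE)
    j0 <- sample.int(ncol(v) - patch_size + 1L, n_patches, replace = TRUE)
    out <- array(0, c(patch_size, patch_size, n_patches))
    for (p in seq_len(n_patches))
      out[, , p] <- v[i0[p]:(i0[p] + patch_size - 1L),
                      j0[p]:(j0[p] + patch_size - 1L)]
    attr(out, "corners") <- cbind(i = i0, j = j0)
    out
  })
}
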