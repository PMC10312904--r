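#' Attenuation image on a square grid
#'
#' A 2-D map of linear attenuation coefficients (mm^-1). The grid is centred
#' on the rotation axis with pixel centres at
#' `((i - (n-1)/2) * pixel_size, (j - (n-1)/2) * pixel_size)`; the first
#' index runs along +x (right), the second along +y (up).
#'
#' @param values Numeric matrix of attenuation values (mm^-1), all finite.
#' @param pixel_size Pixel size in mm (> 0).
#' @return An object of class `image_grid`.
#' @export
image_grid <- function(values, pixel_size) {
  values <- as.matrix(values)
  if (!is.numeric(values) || !all(is.finite(values)))
    stop("image values must be finite numerics")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("pixel_size must be a single positive number")
  structure(list(values = values, pixel_size = as.numeric(pixel_size)),
            class = "image_grid")
}

#' @export
as.matrix.image_grid <- function(x, ...) x$values

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("Attenuation image: %d x %d pixels, %.4g mm/pixel, range [%.4g, %.4g] mm^-1\n",
              nrow(x$values), ncol(x$values), x$pixel_size,
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
plot.image_grid <- function(x, main = "attenuation (mm^-1)", ...) {
  n1 <- nrow(x$values); n2 <- ncol(x$values)
  graphics::image(x = seq_len(n1) * x$pixel_size, y = seq_len(n2) * x$pixel_size,
                  z = x$values, asp = 1, col = grDevices::gray.colors(256),
                  xlab = "x (mm)", ylab = "y (mm)", main = main, ...)
  invisible(x)
}

#' Fan-beam sinogram
#'
#' A views x detectors measurement array, tagged with its domain: raw photon
#' counts (`"photon_counts"`, non-negative integers) or Beer-Lambert line
#' integrals (`"line_integrals"`, finite reals). The tag is checked at every
#' physics/reconstruction boundary because confusing the two domains is the
#' canonical CT bug.
#'
#' @param values Numeric matrix, `n_views` rows x `n_detectors` columns.
#' @param domain Either `"photon_counts"` or `"line_integrals"`.
#' @param geometry The `scan_geometry` the data was acquired with.
#' @return An object of class `sinogram`.
#' @export
sinogram <- function(values, domain = c("line_integrals", "photon_counts"),
                     geometry) {
  domain <- match.arg(domain)
  values <- as.matrix(values)
  if (!inherits(geometry, "scan_geometry")) stop("geometry must be a scan_geometry")
  if (nrow(values) != geometry$n_views || ncol(values) != geometry$n_detectors)
    stop(sprintf("sinogram shape %d x %d does not match geometry (%d views x %d detectors)",
                 nrow(values), ncol(values), geometry$n_views, geometry$n_detectors))
  if (domain == "photon_counts") {
    if (any(values < 0) || any(values != round(values)))
      stop("photon_counts must be non-negative integers")
  } else if (!all(is.finite(values))) {
    stop("line_integrals must be finite")
  }
  structure(list(values = values, domain = domain, geometry = geometry),
            class = "sinogram")
}

#' @export
as.matrix.sinogram <- function(x, ...) x$values

#' @export
print.sinogram <- function(x, ...) {
  cat(sprintf("Sinogram (%s): %d views x %d detectors, range [%.4g, %.4g]\n",
              x$domain, nrow(x$values), ncol(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
plot.sinogram <- function(x, main = NULL, ...) {
  if (is.null(main)) main <- paste0("sinogram (", x$domain, ")")
  graphics::image(z = x$values, col = grDevices::gray.colors(256),
                  xlab = "view", ylab = "detector", main = main, ...)
  invisible(x)
}

.check_domain <- function(sino, expected) {
  if (!inherits(sino, "sinogram")) stop("expected a sinogram object")
  if (sino$domain != expected)
    stop(sprintf("sinogram is in the '%s' domain; '%s' required",
                 sino$domain, expected))
  invisible(sino)
}

#' Convert attenuation values to Hounsfield units
#'
#' `HU = 1000 * (mu - mu_water) / mu_water`, so water maps to 0 HU and air
#' (mu = 0) to -1000 HU. Display convenience only; all reconstruction happens
#' in mm^-1.
#'
#' @param image An `image_grid` or numeric matrix of attenuation (mm^-1).
#' @param mu_water Attenuation of water (mm^-1), default 0.02, a typical
#'   effective value at diagnostic CT energies.
#' @return Numeric matrix of Hounsfield units.
#' @examples
#' hu_convert(matrix(0.02, 2, 2))  # all zeros
#' @export
hu_convert <- function(image, mu_water = 0.02) {
  if (!is.numeric(mu_water) || length(mu_water) != 1L || mu_water <= 0)
    stop("mu_water must be a single positive number")
  v <- if (inherits(image, "image_grid")) image$values else as.matrix(image)
  1000 * (v - mu_water) / mu_water
}
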