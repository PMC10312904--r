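#' Image and sinogram file I/O
#'
#' The native container is a pair of files: `<path>` holding the values as
#' little-endian doubles in column-major order, and `<path>.json`, a plain
#' text sidecar with the dimensions, pixel size and (for sinograms) the full
#' acquisition geometry and domain tag. The round trip is bit-exact.
#' Images may alternatively be written to TIFF (`.tif`/`.tiff`, 32-bit
#' float via the tiff package); TIFF stores pixel values only, so the pixel
#' size must be supplied again on read, values are truncated to single
#' precision, and sinograms cannot be read from TIFF (no geometry metadata).
#'
#' @param path File path. Extension `.tif`/`.tiff` selects TIFF; anything
#'   else selects the native binary + JSON sidecar container.
#' @param image An `image_grid`.
#' @param sino A `sinogram`.
#' @param pixel_size Pixel size in mm, required when reading an image from
#'   TIFF.
#' @return `read_image` returns an `image_grid`; `read_sinogram` a
#'   `sinogram`; the writers return `path` invisibly.
#' @name ct_io
NULL

.is_tiff <- function(path) grepl("\\.tiff?$", path, ignore.case = TRUE)

.write_raw_values <- function(path, values) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(values), con, size = 8L, endian = "little")
}

.read_raw_values <- function(path, n) {
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, what = "double", n = n, size = 8L, endian = "little")
  if (length(v) != n) stop("corrupt data file (expected ", n, " values): ", path)
  v
}

.read_sidecar <- function(path) {
  sc <- paste0(path, ".json")
  if (!file.exists(sc)) stop("missing sidecar metadata file: ", sc)
  meta <- tryCatch(jsonlite::read_json(sc, simplifyVector = TRUE),
                   error = function(e) stop("corrupt sidecar: ", sc))
  meta
}

#' @rdname ct_io
#' @export
write_image <- function(path, image) {
  stopifnot(inherits(image, "image_grid"))
  if (.is_tiff(path)) {
    v <- t(image$values)  # TIFF rows are the y axis
    tiff::writeTIFF(v / 1, path, bits.per.sample = 32L)
  } else {
    .write_raw_values(path, image$values)
    jsonlite::write_json(list(kind = "image", dim = dim(image$values),
                              pixel_size_mm = image$pixel_size),
                         paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname ct_io
#' @export
read_image <- function(path, pixel_size = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (.is_tiff(path)) {
    if (is.null(pixel_size))
      stop("TIFF carries no metadata; supply pixel_size when reading an image from TIFF")
    v <- tiff::readTIFF(path)
    if (length(dim(v)) == 3L) v <- v[, , 1L]
    return(image_grid(t(v), pixel_size))
  }
  meta <- .read_sidecar(path)
  if (is.null(meta$kind) || meta$kind != "image")
    stop("not an image container: ", path)
  v <- matrix(.read_raw_values(path, prod(meta$dim)), meta$dim[1], meta$dim[2])
  image_grid(v, meta$pixel_size_mm)
}

#' @rdname ct_io
#' @export
write_sinogram <- function(path, sino) {
  stopifnot(inherits(sino, "sinogram"))
  if (.is_tiff(path))
    stop("sinograms require geometry metadata; TIFF is image-only. Use the native container.")
  g <- sino$geometry
  .write_raw_values(path, sino$values)
  jsonlite::write_json(list(
    kind = "sinogram", dim = dim(sino$values), domain = sino$domain,
    geometry = list(source_to_center = g$source_to_center,
                    source_to_detector = g$source_to_detector,
                    n_detectors = g$n_detectors,
                    detector_pitch = g$detector_pitch,
                    n_views = g$n_views,
                    angular_range = g$angular_range)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname ct_io
#' @export
read_sinogram <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (.is_tiff(path))
    stop("cannot read a sinogram from TIFF: no geometry metadata")
  meta <- .read_sidecar(path)
  if (is.null(meta$kind) || meta$kind != "sinogram" || is.null(meta$geometry))
    stop("not a sinogram container (missing geometry metadata): ", path)
  gm <- meta$geometry
  g <- scan_geometry(gm$source_to_center, gm$source_to_detector,
                     gm$n_detectors, gm$detector_pitch, gm$n_views,
                     gm$angular_range)
  v <- matrix(.read_raw_values(path, prod(meta$dim)), meta$dim[1], meta$dim[2])
  sinogram(v, meta$domain, g)
}
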