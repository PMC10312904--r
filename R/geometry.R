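#' Fan-beam scan geometry
#'
#' Describes a single-source, equiangular curved-detector fan-beam
#' acquisition: source-to-rotation-axis and source-to-detector distances,
#' the detector array, and the set of view angles. View angle 0 places the
#' source on the +x axis; angles increase counter-clockwise and by default
#' cover a full turn.
#'
#' @param source_to_center Source-to-rotation-axis distance (mm).
#' @param source_to_detector Source-to-detector distance (mm); must exceed
#'   `source_to_center`.
#' @param n_detectors Number of detector elements.
#' @param detector_pitch Element pitch (mm) measured along the curved array;
#'   the angular pitch is `detector_pitch / source_to_detector`.
#' @param n_views Number of projection views.
#' @param angular_range Total angular coverage in radians (default `2*pi`).
#' @return An object of class `scan_geometry`.
#' @export
scan_geometry <- function(source_to_center, source_to_detector, n_detectors,
                          detector_pitch, n_views, angular_range = 2 * pi) {
  stopifnot(is.numeric(source_to_center), is.numeric(source_to_detector))
  if (!(source_to_detector > source_to_center && source_to_center > 0))
    stop("require source_to_detector > source_to_center > 0")
  if (detector_pitch <= 0) stop("detector_pitch must be > 0")
  n_detectors <- as.integer(n_detectors)
  n_views <- as.integer(n_views)
  if (n_detectors < 1L) stop("n_detectors must be >= 1")
  if (n_views < 1L) stop("n_views must be >= 1")
  if (angular_range <= 0) stop("angular_range must be > 0")
  g <- structure(list(
    source_to_center = as.numeric(source_to_center),
    source_to_detector = as.numeric(source_to_detector),
    n_detectors = n_detectors,
    detector_pitch = as.numeric(detector_pitch),
    n_views = n_views,
    angular_range = as.numeric(angular_range),
    view_angles = seq(0, angular_range, length.out = n_views + 1L)[seq_len(n_views)]
  ), class = "scan_geometry")
  g
}

#' @export
print.scan_geometry <- function(x, ...) {
  cat("Fan-beam scan geometry\n")
  cat(sprintf("  source-to-center   : %g mm\n", x$source_to_center))
  cat(sprintf("  source-to-detector : %g mm\n", x$source_to_detector))
  cat(sprintf("  detectors          : %d, pitch %g mm (%.5f mrad)\n",
              x$n_detectors, x$detector_pitch,
              1000 * x$detector_pitch / x$source_to_detector))
  cat(sprintf("  views              : %d over %.1f deg\n",
              x$n_views, x$angular_range * 180 / pi))
  invisible(x)
}

#' Angular detector pitch of a geometry (radians)
#' @param geometry A `scan_geometry`.
#' @return Angular spacing between detector elements.
#' @export
detector_angular_pitch <- function(geometry) {
  geometry$detector_pitch / geometry$source_to_detector
}

#' Fan half-angle covered by the detector array (radians)
#' @param geometry A `scan_geometry`.
#' @return Half of the total fan angle subtended by the array.
#' @export
fan_half_angle <- function(geometry) {
  geometry$n_detectors * detector_angular_pitch(geometry) / 2
}

#' Radius of the fully sampled field of view (mm)
#'
#' The scan circle: points within this radius of the rotation axis are seen
#' by every view.
#' @param geometry A `scan_geometry`.
#' @return Radius in mm.
#' @export
fov_radius <- function(geometry) {
  geometry$source_to_center * sin(fan_half_angle(geometry))
}

#' Default pixel size for a square grid inscribed in the scan circle
#' @param geometry A `scan_geometry`.
#' @param n Grid size (pixels per side).
#' @return Pixel size in mm such that the grid's diagonal fits the scan circle.
#' @export
default_pixel_size <- function(geometry, n) {
  2 * fov_radius(geometry) / (sqrt(2) * n)
}

.geometry_presets <- list(
  # AAPM low-dose simulation setting: 595 mm scan radius, 1085.6 mm
  # source-to-detector, 736 elements of 1.2858 mm pitch, 360 views / 360 deg.
  aapm_sim = function() scan_geometry(595, 1085.6, 736, 1.2858, 360),
  # Siemens SOMATOM-like fan geometry; 768 acquisition views (the full-view
  # reference scan uses 2304, see `n_views_reference`).
  siemens_fan = function() {
    g <- scan_geometry(595, 1085.6, 736, 1.2858, 768)
    g$n_views_reference <- 2304L
    g
  },
  # GE scanner fan geometry: 541 / 949 mm, 888 elements of 1.024 mm pitch,
  # 984 views (few-view subset: 328).
  ge_fan = function() {
    g <- scan_geometry(541, 949, 888, 1.024, 984)
    g$n_views_subset <- 328L
    g
  }
)

#' Scanner geometry presets
#'
#' Returns one of the built-in acquisition geometries: `"aapm_sim"` (the
#' simulated low-dose setting), `"siemens_fan"` (Siemens-like fan rebinning,
#' with the 2304-view reference scan recorded as `n_views_reference`), or
#' `"ge_fan"` (GE-like, with the 328-view few-view subset recorded as
#' `n_views_subset`).
#'
#' @param name Preset identifier.
#' @return A `scan_geometry`.
#' @examples
#' load_preset("aapm_sim")
#' @export
load_preset <- function(name) {
  if (!is.character(name) || length(name) != 1L ||
      !(name %in% names(.geometry_presets)))
    stop("unknown geometry preset ", deparse(name), "; available: ",
         paste(names(.geometry_presets), collapse = ", "))
  .geometry_presets[[name]]()
}
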