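test_that("geometry presets carry the documented scanner constants", {
  g <- load_preset("aapm_sim")
  expect_equal(g$source_to_center, 595)
  expect_equal(g$source_to_detector, 1085.6)
  expect_equal(g$n_detectors, 736L)
  expect_equal(g$detector_pitch, 1.2858)
  expect_equal(g$n_views, 360L)
  expect_equal(length(g$view_angles), 360L)
  expect_true(all(diff(g$view_angles) > 0))

  s <- load_preset("siemens_fan")
  expect_equal(s$n_views, 768L)
  expect_equal(s$n_views_reference, 2304L)

  ge <- load_preset("ge_fan")
  expect_equal(ge$source_to_center, 541)
  expect_equal(ge$source_to_detector, 949)
  expect_equal(ge$n_detectors, 888L)
  expect_equal(ge$detector_pitch, 1.024)
  expect_equal(ge$n_views, 984L)
  expect_equal(ge$n_views_subset, 328L)

  expect_error(load_preset("nonexistent"), "aapm_sim")
})

test_that("geometry constructor enforces its invariants", {
  expect_error(scan_geometry(600, 500, 10, 1, 10), "source_to_detector")
  expect_error(scan_geometry(500, 1000, 10, -1, 10), "detector_pitch")
  expect_error(scan_geometry(500, 1000, 0, 1, 10), "n_detectors")
  expect_error(sinogram(matrix(0, 3, 4), "line_integrals",
                        scan_geometry(500, 1000, 5, 1, 3)), "shape")
  expect_error(sinogram(matrix(-1, 3, 5), "photon_counts",
                        scan_geometry(500, 1000, 5, 1, 3)), "non-negative")
})

test_that("Hounsfield conversion is the water-anchored affine map", {
  mu_w <- 0.02
  expect_equal(hu_convert(matrix(mu_w, 3, 3), mu_w), matrix(0, 3, 3))
  expect_equal(hu_convert(matrix(0, 2, 2), mu_w), matrix(-1000, 2, 2))
  expect_equal(hu_convert(matrix(2 * mu_w, 2, 2), mu_w), matrix(1000, 2, 2))
  # affine and invertible: recover mu from HU
  mu <- matrix(runif(16, 0, 0.05), 4)
  hu <- hu_convert(mu, mu_w)
  expect_equal(hu * mu_w / 1000 + mu_w, mu, tolerance = 1e-12)
  expect_error(hu_convert(mu, -1), "mu_water")
})

test_that("native containers round-trip images and sinograms bit-exactly", {
  d <- withr::local_tempdir()
  img <- image_grid(matrix(rnorm(256), 16), pixel_size = 1.25)
  p <- file.path(d, "img.bin")
  write_image(p, img)
  back <- read_image(p)
  expect_identical(back$values, img$values)
  expect_identical(back$pixel_size, img$pixel_size)

  g <- small_geometry(n_detectors = 8L, n_views = 5L)
  sino <- sinogram(matrix(rpois(40, 50), 5, 8), "photon_counts", g)
  ps <- file.path(d, "sino.bin")
  write_sinogram(ps, sino)
  back <- read_sinogram(ps)
  # the container stores doubles; count values survive exactly
  expect_equal(back$values, sino$values, tolerance = 0)
  expect_true(all(back$values == round(back$values)))
  expect_identical(back$domain, "photon_counts")
  expect_equal(back$geometry$source_to_center, g$source_to_center)
  expect_equal(back$geometry$n_detectors, g$n_detectors)
})

test_that("TIFF stores image values only and cannot hold a sinogram", {
  d <- withr::local_tempdir()
  img <- image_grid(matrix(runif(64), 8), pixel_size = 2)
  p <- file.path(d, "img.tif")
  write_image(p, img)
  expect_error(read_image(p), "pixel_size")
  back <- read_image(p, pixel_size = 2)
  expect_equal(back$values, img$values, tolerance = 1e-7)  # float32
  expect_error(read_sinogram(p), "TIFF")
  g <- small_geometry(8L, 4L)
  expect_error(write_sinogram(file.path(d, "s.tif"),
                              sinogram(matrix(0, 4, 8), "line_integrals", g)),
               "geometry")
})

test_that("corrupt or incomplete containers are rejected", {
  d <- withr::local_tempdir()
  p <- file.path(d, "img.bin")
  write_image(p, image_grid(matrix(1, 4, 4), 1))
  file.remove(paste0(p, ".json"))
  expect_error(read_image(p), "sidecar")
  write_image(p, image_grid(matrix(1, 4, 4), 1))
  writeBin(1.0, p)  # truncate the data file
  expect_error(read_image(p), "corrupt")
  expect_error(read_image(file.path(d, "none.bin")), "no such file")
})
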