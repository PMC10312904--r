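test_that("forward projection is linear and vanishes on the zero image", {
  g <- small_geometry()
  pr <- projector(g, 32)
  zero <- forward_project(matrix(0, 32, 32), pr)
  expect_equal(zero$values, matrix(0, g$n_views, g$n_detectors))
  expect_equal(zero$domain, "line_integrals")
  set.seed(1)
  x <- matrix(rnorm(32^2), 32)
  expect_equal(forward_project(2 * x, pr)$values,
               2 * forward_project(x, pr)$values, tolerance = 1e-14)
  expect_error(forward_project(matrix(0, 16, 16), pr), "grid")
})

test_that("central-ray line integral reproduces the analytic disk chord", {
  # chord of a centred disk: 2 * sqrt(r^2 - t^2) * mu; at the (almost)
  # central detectors t is a fraction of a millimetre
  g <- load_preset("aapm_sim")
  pr <- projector(g, 256, pixel_size = 0.4)
  img <- render_phantom(ellipse_spec(0, 0, 20, 20, 0, 0.02), 256, 0.4)
  s <- forward_project(img, pr)$values
  dg <- detector_angular_pitch(g)
  t_off <- g$source_to_center * sin(0.5 * dg)
  chord <- 2 * sqrt(20^2 - t_off^2) * 0.02
  central <- s[, 368:369]  # the two detectors straddling the central ray
  expect_lt(max(abs(central / chord - 1)), 0.01)
})

test_that("backprojection is the exact adjoint of forward projection", {
  g <- small_geometry(n_detectors = 48L, n_views = 40L)
  pr <- projector(g, 48)
  set.seed(42)
  for (i in 1:5) {
    x <- matrix(rnorm(48^2), 48)
    y <- matrix(rnorm(40 * 48), 40)
    Ax <- forward_project(x, pr)$values
    Aty <- back_project(y, pr)$values
    rel <- abs(sum(Ax * y) - sum(x * Aty)) /
      (sqrt(sum(Ax^2)) * sqrt(sum(y^2)))
    expect_lt(rel, 1e-12)
  }
  expect_equal(back_project(matrix(0, 40, 48), pr)$values, matrix(0, 48, 48))
})

test_that("a one-hot sinogram backprojects onto a single ray footprint", {
  p <- small_wls_problem()
  g <- p$geometry
  onehot <- matrix(0, g$n_views, g$n_detectors)
  onehot[17, 30] <- 1
  img <- back_project(onehot, p$proj)$values
  ray_row <- p$A[(30 - 1) * g$n_views + 17, ]  # column-major (view, det) index
  expect_equal(as.vector(img), ray_row, tolerance = 1e-12)
  # the footprint is sparse: a single ray meets only O(n) pixels
  expect_lt(sum(img != 0), 3 * 32)
  expect_true(all(p$A >= 0))  # nonnegative system coefficients
})

test_that("ray coefficient sums approximate intersection lengths", {
  # forward projection of an all-ones image = per-ray coefficient sum;
  # for the central ray this is the chord of the grid square ~ its side
  g <- small_geometry()
  pr <- projector(g, 32)
  ones <- forward_project(matrix(1, 32, 32), pr)$values
  side <- 32 * pr$pixel_size
  expect_lt(max(ones), sqrt(2) * side * 1.01)   # at most the diagonal
  # at view angle 0 the central rays cross the square horizontally
  ctr <- g$n_detectors / 2 + 0:1
  expect_equal(mean(ones[1, ctr]), side, tolerance = 0.02)
})

test_that("power iteration brackets and recovers known spectra", {
  # identity operator
  expect_equal(unname(extreme_eigs(function(v) v, 4L, seed = 1)), c(1, 1))
  # explicit symmetric 3x3 with spectrum {1, 2, 5}
  Q <- qr.Q(qr(matrix(c(2, 1, 0, 1, 3, 1, 0, 1, 2), 3)))
  M <- Q %*% diag(c(1, 2, 5)) %*% t(Q)
  ee <- extreme_eigs(function(v) as.vector(M %*% v), 3L, n_iters = 500L,
                     seed = 2)
  expect_equal(unname(ee), c(1, 5), tolerance = 1e-3)
  # Rayleigh quotients of random vectors fall inside the bracket
  set.seed(3)
  for (i in 1:10) {
    v <- rnorm(3)
    r <- sum(v * (M %*% v)) / sum(v^2)
    expect_gte(r, ee[["lambda_min"]] - 1e-6)
    expect_lte(r, ee[["lambda_max"]] + 1e-6)
  }
})

test_that("weighted normal operator spectrum scales linearly in D", {
  g <- small_geometry(n_detectors = 32L, n_views = 24L)
  pr <- projector(g, 16)
  D <- matrix(2, 24, 32)
  e1 <- estimate_extreme_eigs(pr, D, n_iters = 60L, seed = 4)
  e2 <- estimate_extreme_eigs(pr, 3 * D, n_iters = 60L, seed = 4)
  expect_equal(unname(e2), unname(3 * e1), tolerance = 1e-10)
  expect_error(estimate_extreme_eigs(pr, 0 * D), "positive")
})
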