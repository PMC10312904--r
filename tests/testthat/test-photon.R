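test_that("expected counts follow the exponential attenuation law", {
  g <- small_geometry(8L, 4L)
  li <- sinogram(matrix(0, 4, 8), "line_integrals", g)
  expect_equal(expected_counts(li, 1e5)$values, matrix(1e5, 4, 8))
  li2 <- sinogram(matrix(log(2), 4, 8), "line_integrals", g)
  expect_equal(expected_counts(li2, 1000)$values, matrix(500, 4, 8))
  # monotone: larger line integral, fewer photons
  p <- sinogram(matrix(seq(0, 3, length.out = 32), 4, 8), "line_integrals", g)
  ec <- expected_counts(p, 1e4)$values
  expect_true(all(diff(ec[order(p$values)]) <= 0))
  cnt <- sinogram(matrix(5, 4, 8), "photon_counts", g)
  expect_error(expected_counts(cnt, 1e5), "domain")
  expect_error(expected_counts(li, -1), "n0")
})

test_that("Poisson sampling is seeded and reproduces the first two moments", {
  g <- scan_geometry(595, 1085.6, 500, 1.2858, 200)
  ec <- sinogram(matrix(0, 200, 500), "line_integrals", g)
  ec <- expected_counts(ec, 100)   # 1e5 rays with expectation 100
  y1 <- sample_counts(ec, seed = 9)
  y2 <- sample_counts(ec, seed = 9)
  y3 <- sample_counts(ec, seed = 10)
  expect_identical(y1$values, y2$values)
  expect_false(identical(y1$values, y3$values))
  expect_equal(y1$domain, "photon_counts")
  n <- length(y1$values)
  # mean 100 +/- 3 * sqrt(100/n); variance 100 +/- 3 * sqrt(2*100^2/n)
  expect_lt(abs(mean(y1$values) - 100), 3 * sqrt(100 / n))
  expect_lt(abs(stats::var(as.vector(y1$values)) - 100),
            3 * sqrt(2 * 100^2 / n))
  # zero expectation draws zero always
  ez <- expected_counts(sinogram(matrix(50, 200, 500), "line_integrals", g), 100)
  ez$values[] <- 0
  expect_true(all(sample_counts(ez, seed = 1)$values == 0))
})

test_that("linearization produces the documented b and D", {
  g <- small_geometry(2L, 1L)
  y <- sinogram(matrix(c(1000, 1000 %/% exp(1)), 1, 2), "photon_counts", g)
  # blank ray: y = n0 gives b = 0
  sys0 <- linearize(sinogram(matrix(c(1000, 1000), 1, 2), "photon_counts", g), 1000)
  expect_equal(sys0$b, matrix(0, 1, 2))
  # y = n0/e gives b = 1 (up to the integer rounding of the count)
  sys1 <- linearize(y, 1000)
  expect_equal(sys1$b[1, 2], log(1000 / floor(1000 / exp(1))))
  # D carries the measured counts
  cnt <- sinogram(matrix(c(3, 7), 1, 2), "photon_counts", g)
  expect_equal(linearize(cnt, 100)$D, matrix(c(3, 7), 1, 2))
  # zero counts are floored before the log and in D
  z <- sinogram(matrix(c(0, 10), 1, 2), "photon_counts", g)
  sysz <- linearize(z, 100)
  expect_equal(sysz$D[1, 1], 1)
  expect_equal(sysz$b[1, 1], log(100))
  expect_error(linearize(z, -5), "n0")
})

test_that("the quadratic surrogate second-orders the Poisson likelihood", {
  # around a high-count operating point the weighted least squares term
  # reproduces the Poisson negative log-likelihood up to a constant
  p <- small_wls_problem()
  n0 <- 1e5
  counts <- sample_counts(expected_counts(forward_project(p$truth, p$proj), n0),
                          seed = 31)
  sys <- linearize(counts, n0)
  nll <- function(mu) neg_log_likelihood(mu, counts, n0, p$proj)
  quad <- function(mu) {
    r <- forward_project(mu, p$proj)$values - sys$b
    0.5 * sum(sys$D * r^2)
  }
  # the quadratic is anchored at the operating point A mu = b (exactly the
  # measured line integrals); compare second differences along a direction
  mu_hat <- p$truth$values
  set.seed(5)
  dir <- matrix(rnorm(1024), 32); dir <- dir / sqrt(sum(dir^2))
  for (eps in c(1e-4, 3e-4)) {
    d2_nll <- nll(mu_hat + eps * dir) - 2 * nll(mu_hat) + nll(mu_hat - eps * dir)
    d2_quad <- quad(mu_hat + eps * dir) - 2 * quad(mu_hat) + quad(mu_hat - eps * dir)
    expect_equal(d2_quad / d2_nll, 1, tolerance = 0.01)
  }
})

test_that("negative log-likelihood evaluates the plug-in expression", {
  p <- small_wls_problem()
  n0 <- 1e4
  li <- forward_project(p$truth, p$proj)
  ybar <- n0 * exp(-li$values)
  y <- sinogram(round(ybar), "photon_counts", p$geometry)
  val <- neg_log_likelihood(p$truth, y, n0, p$proj)
  expect_equal(val, sum(ybar - round(ybar) * log(ybar)), tolerance = 1e-12)
  # scaling all expectations shifts the value predictably: halving n0
  # subtracts sum(ybar)/2 - sum(y) * log(2)
  val2 <- neg_log_likelihood(p$truth, y, n0 / 2, p$proj)
  expect_equal(val2, val - sum(ybar) / 2 + sum(round(ybar)) * log(2),
               tolerance = 1e-9)
})

test_that("linearized estimates concentrate on the true line integrals", {
  p <- small_wls_problem()
  li <- forward_project(p$truth, p$proj)
  err <- sapply(c(1e3, 1e5), function(n0) {
    y <- sample_counts(expected_counts(li, n0), seed = 77)
    mean(abs(linearize(y, n0)$b - li$values))
  })
  expect_lt(err[2], err[1])
})
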