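test_that("the binomial schedule reproduces its printed weights", {
  s <- binomial_noise_schedule()
  expect_equal(s$sigmas, seq(0, 0.10, by = 0.01))
  expect_equal(round(s$probs, 4),
               c(0.0010, 0.0098, 0.0439, 0.1172, 0.2051, 0.2461, 0.2051,
                 0.1172, 0.0439, 0.0098, 0.0010))
  expect_equal(s$probs, rev(s$probs))          # symmetry at p = 1/2
  expect_equal(sum(s$probs), 1)                # exact pmf normalization
  expect_error(noise_schedule(c(0.1, 0.1), c(0.5, 0.5)), "distinct")
  expect_error(noise_schedule(c(0, 0.1), c(0.6, 0.6)), "sum to 1")
})

test_that("perturbation draws levels with the scheduled frequencies", {
  sched <- noise_schedule(c(0, 0.05, 0.1), c(0.2, 0.5, 0.3))
  # sigma = 0 component returns the input unchanged
  x <- matrix(0.5, 4, 4)
  p0 <- perturb(x, noise_schedule(c(0, 0.05), c(1 - 1e-9, 1e-9)), seed = 1)
  expect_identical(p0$x_tilde, x)
  expect_identical(p0$sigma, 0)
  # empirical noise sd at a fixed level over 1e5 scalar draws
  big <- matrix(0.3, 250, 400)
  p <- perturb(big, noise_schedule(0.05, 1), seed = 2)
  se <- 0.05 / sqrt(2 * length(big))
  expect_lt(abs(stats::sd(p$x_tilde - big) - 0.05), 3 * se)
  # drawn-sigma frequencies match the schedule probabilities
  draws <- vapply(1:4000, function(i) perturb(0.5, sched, seed = i)$sigma,
                  numeric(1))
  for (k in seq_along(sched$sigmas)) {
    pk <- sched$probs[k]
    f <- mean(draws == sched$sigmas[k])
    expect_lt(abs(f - pk), 4 * sqrt(pk * (1 - pk) / length(draws)))
  }
})

test_that("responsibility weights normalize and match the closed form", {
  # single level: weight 1 regardless of the perturbation
  expect_equal(lambda_weights(c(1, 2), noise_schedule(0.07, 1)), 1)
  # two equal-probability levels at zero perturbation, d = 2:
  # lambda(0.05) = 0.05^-2 / (0.05^-2 + 0.1^-2) = 0.8
  s2 <- noise_schedule(c(0.05, 0.1), c(0.5, 0.5))
  expect_equal(lambda_weights(c(0, 0), s2), c(0.8, 0.2), tolerance = 1e-12)
  # normalization for arbitrary inputs, stable in log space
  sched <- binomial_noise_schedule()
  set.seed(4)
  for (i in 1:20) {
    d <- rnorm(sample(1:64, 1), sd = 10^runif(1, -4, 0.3))
    w <- lambda_weights(d, sched)
    expect_true(all(is.finite(w)))
    expect_equal(sum(w), 1, tolerance = 1e-12)
  }
  # extreme magnitudes must not overflow (sigma in [1e-4, 1], |diff| <= 10)
  wide <- noise_schedule(c(1e-4, 0.01, 1), c(0.3, 0.4, 0.3))
  w <- lambda_weights(rep(10 / sqrt(4), 4), wide)
  expect_true(all(is.finite(w)))
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_error(lambda_weights(1, noise_schedule(0, 1)), "sigma > 0")
})

test_that("the mixture score is the gradient of the mixture log-density", {
  sched <- binomial_noise_schedule()
  expect_equal(mixture_score(c(0, 0), sched), c(0, 0))
  s1 <- noise_schedule(0.05, 1)
  d <- c(0.02, -0.01)
  expect_equal(mixture_score(d, s1), -d / 0.05^2)
  # central-difference oracle on the explicit log-density, 1-D and 2-D
  for (d0 in list(0.03, c(0.04, -0.06), c(-0.01, 0.02))) {
    an <- mixture_score(d0, sched)
    nd <- num_grad(function(z) mixture_log_density(z, sched), d0, h = 1e-6)
    expect_equal(an, nd, tolerance = 1e-6)
  }
})

test_that("the weighted loss is minimized exactly by the mixture score", {
  sched <- binomial_noise_schedule()
  s1 <- noise_schedule(0.05, 1)
  d <- c(0.01, 0.02)
  expect_equal(adsf_loss(-d / 0.05^2, d, 0.05, s1), 0)
  expect_gte(adsf_loss(c(1, 1), d, 0.05, s1), 0)
  expect_error(adsf_loss(c(0, 0), d, 0, sched), "sigma_drawn")
  # closed-form minimizer of sum_sigma lambda * ||s + diff/sigma^2||^2:
  # the lambda-weighted average of the single-level targets
  set.seed(9)
  for (i in 1:100) {
    d0 <- rnorm(sample(1:8, 1), sd = 10^runif(1, -2, -0.5))
    w <- lambda_weights(d0, sched)
    pos <- sched$sigmas > 0
    s_star <- -d0 * sum(w[pos] / sched$sigmas[pos]^2)
    expect_equal(s_star, mixture_score(d0, sched), tolerance = 1e-12)
  }
  # spot-check against a black-box numeric minimizer of the same quadratic
  d0 <- c(0.03, -0.05)
  obj <- function(s) {
    pos <- which(sched$sigmas > 0)
    sum(vapply(pos, function(k)
      lambda_weights(d0, sched)[k] * sum((s + d0 / sched$sigmas[k]^2)^2),
      numeric(1)))
  }
  fit <- stats::optim(c(0, 0), obj, method = "BFGS",
                      control = list(reltol = 1e-14))
  expect_equal(fit$par, mixture_score(d0, sched), tolerance = 1e-4)
})
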