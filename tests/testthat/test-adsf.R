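test_that("step-size validation substitutes the contraction inequalities", {
  v <- validate_step_params(1, 0.5, 1, 1, 1)
  expect_true(v$valid)
  expect_equal(unname(v$margins), c(0.5, 0.5, 0.5, 0.5))
  expect_false(validate_step_params(1, 0, 1, 1, 1)$valid)      # sigma > 0 fails
  # omega = 2 is inadmissible for every sigma > 0 (needs omega < 2 - sigma)
  for (s in c(1e-6, 0.1, 0.5, 1))
    expect_false(validate_step_params(2, s, 1, 1, 1)$valid)
  expect_error(validate_step_params(1, 0.1, -1, 1, 1), "must be > 0")
  expect_error(validate_step_params(1, 0.1, 2, 1, 1), "lambda_min")
})

test_that("the score Lipschitz estimate recovers analytic Jacobians", {
  tau <- 0.5
  lin <- function(x) -x / tau^2
  probes <- list(matrix(0.2, 6, 6), matrix(runif(36), 6))
  C <- estimate_score_lipschitz(lin, probes, fd_epsilon = 1e-4, n_iters = 50)
  expect_equal(C, 1 / tau^2, tolerance = 0.01)
  expect_equal(estimate_score_lipschitz(function(x) 0 * x, probes), 0)
  # |a|-homogeneous in the score map
  C3 <- estimate_score_lipschitz(function(x) -3 * x, probes,
                                 fd_epsilon = 1e-4, n_iters = 50)
  expect_equal(C3, 3, tolerance = 0.01)
})

test_that("with a zero score the iteration solves weighted least squares", {
  p <- small_wls_problem()
  lam <- estimate_extreme_eigs(p$proj, p$sys$D, n_iters = 100L, seed = 7)
  rec <- adsf_reconstruct(p$sys, p$proj, function(mu) 0 * mu,
                          adsf_config(omega = 1 / lam[["lambda_max"]],
                                      sigma_prior = 1e-20, max_iters = 6000L,
                                      tol = 1e-12, init = "zeros",
                                      validate = FALSE))
  op <- function(v) as.vector(crossprod(p$A, p$D * (p$A %*% v)))
  mu_cg <- cg_solve(op, as.vector(crossprod(p$A, p$D * p$b)), tol = 1e-13)
  err <- sqrt(sum((as.vector(rec$details$image_unclipped) - mu_cg)^2) /
                sum(mu_cg^2))
  expect_lt(err, 1e-5)
})

test_that("a linear Gaussian-prior score reaches the direct-solve fixed point", {
  p <- small_wls_problem()
  lam <- estimate_extreme_eigs(p$proj, p$sys$D, n_iters = 300L, seed = 3)
  tau <- 0.005
  mu0 <- matrix(0.01, 32, 32)
  omega <- 1 / lam[["lambda_max"]]
  sigma <- 0.4 * omega * lam[["lambda_min"]] * tau^2
  expect_true(validate_step_params(omega, sigma, lam[["lambda_min"]],
                                   lam[["lambda_max"]], 1 / tau^2)$valid)
  score <- function(mu) -(mu - mu0) / tau^2
  rec <- adsf_reconstruct(p$sys, p$proj, score,
                          adsf_config(omega = omega, sigma_prior = sigma,
                                      max_iters = 8000L, tol = 5e-10,
                                      init = "zeros", validate = FALSE))
  # oracle: solve (omega A'DA + sigma/tau^2 I) mu = omega A'Db + sigma/tau^2 mu0
  M <- crossprod(p$A, p$D * p$A)
  mu_star <- solve(omega * M + sigma / tau^2 * diag(1024),
                   omega * as.vector(crossprod(p$A, p$D * p$b)) +
                     sigma / tau^2 * as.vector(mu0))
  mu_it <- as.vector(rec$details$image_unclipped)
  expect_lt(sqrt(sum((mu_it - mu_star)^2) / sum(mu_star^2)), 1e-6)
  # geometric decrease of successive differences under validated steps
  expect_lt(contraction_check(rec$details$report), 1)
  # restarting at the fixed point, the first update is numerically zero
  rec0 <- adsf_reconstruct(p$sys, p$proj, score,
                           adsf_config(omega = omega, sigma_prior = sigma,
                                       max_iters = 2L, tol = 1e-16,
                                       init = matrix(mu_star, 32),
                                       validate = FALSE))
  expect_lt(rec0$details$report$diff_norms[1], 1e-10)
})

test_that("the TV baseline is the score iteration with a hand-crafted prior", {
  p <- small_wls_problem()
  beta <- 1e4; eps <- 2e-4
  lam <- estimate_extreme_eigs(p$proj, p$sys$D, n_iters = 60L, seed = 7)
  omega <- 1.5 / (lam[["lambda_max"]] + beta * 8 / eps)
  tv_rec <- mbir_tv(p$sys, p$proj,
                    tv_config(beta = beta, epsilon = eps, omega = omega,
                              n_iters = 15L), init = "zeros")
  sc_rec <- adsf_reconstruct(p$sys, p$proj,
                             function(mu) -beta * tv_gradient(mu, eps),
                             adsf_config(omega = omega, sigma_prior = omega,
                                         max_iters = 15L, tol = 1e-16,
                                         init = "zeros", validate = FALSE))
  expect_equal(sc_rec$details$image_unclipped, tv_rec$details$image_unclipped,
               tolerance = 1e-14)
  expect_equal(coef(sc_rec), coef(tv_rec), tolerance = 1e-14)
})

test_that("divergent steps abort with a convergence report", {
  p <- small_wls_problem()
  lam <- estimate_extreme_eigs(p$proj, p$sys$D, n_iters = 60L, seed = 7)
  err <- tryCatch(
    adsf_reconstruct(p$sys, p$proj, function(mu) 0 * mu,
                     adsf_config(omega = 4 / lam[["lambda_max"]],
                                 sigma_prior = 1e-20, max_iters = 200L,
                                 tol = 1e-16, init = "zeros",
                                 validate = FALSE)),
    scorect_divergence = function(e) e)
  expect_s3_class(err, "scorect_divergence")
  expect_s3_class(err$report, "convergence_report")
  expect_match(conditionMessage(err), "diverging")
})

test_that("contraction summaries behave on degenerate sequences", {
  expect_equal(contraction_check(rep(0, 10)), 0)          # constant iterates
  expect_equal(contraction_check(0.5^(1:20)), 0.5)        # geometric decay
  expect_error(contraction_check(c(1, 0.5)), "at least 3")
  r <- convergence_report(c(4, 2, 1, 0.5))
  expect_equal(r$q, c(0.5, 0.5, 0.5))
  expect_error(convergence_report(c(1, -1)), ">= 0")
})
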