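#' Validate step sizes against the contraction conditions
#'
#' The iteration `mu <- mu - omega * t(A) D (A mu - b) + sigma * score(mu)`
#' contracts (geometric decrease of successive differences) whenever the
#' data-fidelity curvature spectrum `[lambda_min, lambda_max]` of
#' `t(A) D A`, the score Lipschitz bound `C`, and the steps satisfy
#' `0 < sigma < omega * lambda_min / C` and
#' `sigma * C / lambda_min < omega < (2 - sigma * C) / lambda_max`.
#'
#' @param omega Data-fidelity step (> 0).
#' @param sigma_prior Prior step (> 0).
#' @param lambda_min,lambda_max Extreme eigenvalues of `t(A) D A` (> 0).
#' @param C Bound on the spectral norm of the score Jacobian (> 0).
#' @return A list with `valid` (logical) and `margins`, the slack of each
#'   inequality (all must be positive).
#' @export
validate_step_params <- function(omega, sigma_prior, lambda_min, lambda_max, C) {
  if (any(c(lambda_min, lambda_max, C) <= 0))
    stop("lambda_min, lambda_max and C must be > 0")
  if (lambda_min > lambda_max) stop("lambda_min must be <= lambda_max")
  margins <- c(sigma_positive = sigma_prior,
               sigma_upper = omega * lambda_min / C - sigma_prior,
               omega_lower = omega - sigma_prior * C / lambda_min,
               omega_upper = (2 - sigma_prior * C) / lambda_max - omega)
  list(valid = all(margins > 0), margins = margins)
}

#' Estimate the Lipschitz constant of a score map
#'
#' Largest singular value of the Jacobian of the score map, estimated by
#' finite-difference power iteration and maximized over the probe images.
#' Score maps approximate gradients of a log-density, so their Jacobian is
#' (near-)symmetric; the iteration therefore applies J twice per step,
#' converging on the top eigenvalue of J * J, and reports its square root.
#'
#' @param score_fn A `score_prior`, or a function mapping an image matrix to
#'   a same-shaped score field.
#' @param probes List of probe images (matrices) at which to linearize.
#' @param fd_epsilon Finite-difference step (default 1e-3).
#' @param n_iters Power iterations per probe (default 30).
#' @param seed Seed for the random start direction.
#' @return The maximum estimated spectral norm over the probes.
#' @export
estimate_score_lipschitz <- function(score_fn, probes, fd_epsilon = 1e-3,
                                     n_iters = 30L, seed = 1L) {
  f <- .as_score_function(score_fn)
  if (fd_epsilon <= 0) stop("fd_epsilon must be > 0")
  if (!is.list(probes)) probes <- list(probes)
  .with_seed(seed, {
    best <- 0
    for (x in probes) {
      x <- as.matrix(x)
      s0 <- f(x)
      if (!all(is.finite(s0))) stop("score map returned non-finite values")
      jv <- function(d) {
        nd <- sqrt(sum(d^2))
        if (nd == 0) return(d)
        (f(x + fd_epsilon * d / nd) - s0) * (nd / fd_epsilon)
      }
      v <- matrix(stats::rnorm(length(x)), nrow(x))
      v <- v / sqrt(sum(v^2))
      lamB <- 0
      for (i in seq_len(n_iters)) {
        w <- jv(jv(v))
        lamB <- sum(v * w)
        nw <- sqrt(sum(w^2))
        if (nw == 0) { lamB <- 0; break }
        v <- w / nw
      }
      best <- max(best, sqrt(max(lamB, 0)))
    }
    best
  })
}

#' Configuration of the score-prior MAP reconstruction
#'
#' @param omega Data-fidelity step; `NULL` picks `1 / lambda_max` from a
#'   power-iteration estimate.
#' @param sigma_prior Prior step multiplying the score field (> 0).
#' @param max_iters Iteration cap.
#' @param tol Stop when `||mu_{k+1} - mu_k|| / ||mu_k||` falls below this.
#' @param init `"fbp"` (default), `"zeros"`, or an image.
#' @param validate Check the contraction conditions before iterating; when
#'   they fail the reconstruction proceeds with a warning (the bounds are
#'   sufficient, not necessary).
#' @param C Score Lipschitz bound used for validation; `NULL` skips the
#'   estimate and validates with `C = NA` (verdict unavailable).
#' @param spectrum Optional precomputed `c(lambda_min, lambda_max)` of
#'   `t(A) D A`, to avoid re-estimating across repeated solves.
#' @param eig_iters Power iterations for the spectrum estimate.
#' @return An object of class `adsf_config`.
#' @export
adsf_config <- function(omega = NULL, sigma_prior, max_iters = 200L,
                        tol = 1e-6, init = "fbp", validate = TRUE, C = NULL,
                        spectrum = NULL, eig_iters = 50L) {
  if (!is.null(omega) && omega <= 0) stop("omega must be > 0")
  if (sigma_prior <= 0) stop("sigma_prior must be > 0")
  if (tol <= 0) stop("tol must be > 0")
  structure(list(omega = omega, sigma_prior = sigma_prior,
                 max_iters = as.integer(max_iters), tol = tol, init = init,
                 validate = isTRUE(validate), C = C, spectrum = spectrum,
                 eig_iters = as.integer(eig_iters)),
            class = "adsf_config")
}

.as_score_function <- function(score) {
  if (inherits(score, "score_prior")) {
    scale <- score$scale
    function(mu) predict(score, mu / scale) / scale
  } else if (is.function(score)) score
  else stop("score must be a score_prior or a function(image) -> score field")
}

#' MAP reconstruction with a learned score prior
#'
#' Runs the fixed-point iteration
#' `mu <- mu - omega * t(A) D (A mu - b) + sigma * score(mu)`,
#' i.e. gradient descent on the quadratic data surrogate combined with an
#' ascent step along the image prior's score field. With a trained
#' `score_prior` the score is evaluated on the `[0, 1]`-normalized image and
#' rescaled by the chain rule (the prior stores its normalization constant);
#' a plain function is taken to be in attenuation units already. The final
#' image is clipped to non-negative attenuation; iterates are not.
#'
#' @param system A `wls_system` from [linearize()].
#' @param proj A `ct_projector`.
#' @param score A `score_prior` or a function mapping an image matrix to a
#'   same-shaped score field.
#' @param cfg An [adsf_config()].
#' @return A `ct_recon` (subclass `adsf_recon`) whose
#'   `$details$report` is the [convergence_report()]. Aborts with a
#'   diagnostic error if the step ratio exceeds 1 for 20 consecutive
#'   iterations.
#' @export
adsf_reconstruct <- function(system, proj, score, cfg) {
  stopifnot(inherits(system, "wls_system"), inherits(proj, "ct_projector"),
            inherits(cfg, "adsf_config"))
  score_fun <- .as_score_function(score)
  spectrum <- cfg$spectrum
  if (is.null(spectrum) && (is.null(cfg$omega) || cfg$validate))
    spectrum <- estimate_extreme_eigs(proj, system$D, n_iters = cfg$eig_iters,
                                      seed = 11L)
  omega <- if (is.null(cfg$omega)) 1 / spectrum[["lambda_max"]] else cfg$omega
  step_valid <- NULL; margins <- NULL
  if (cfg$validate && !is.null(cfg$C)) {
    v <- validate_step_params(omega, cfg$sigma_prior,
                              spectrum[["lambda_min"]],
                              spectrum[["lambda_max"]], cfg$C)
    step_valid <- v$valid; margins <- v$margins
    if (!v$valid)
      warning("step parameters fall outside the sufficient contraction bounds; proceeding")
  }
  res <- .map_iterate(system, proj, score_fun, omega = omega,
                      sigma = cfg$sigma_prior, max_iters = cfg$max_iters,
                      tol = cfg$tol, init = cfg$init, divergence = "ratio")
  report <- convergence_report(res$diff_norms, step_valid, margins)
  report$omega <- omega
  report$spectrum <- spectrum
  new_ct_recon(image_grid(pmax(res$mu, 0), proj$pixel_size),
               method = "adsf", proj = proj, system = system,
               details = list(config = cfg, omega = omega,
                              n_iters_run = res$n_iters, report = report,
                              image_unclipped = res$mu),
               subclass = "adsf_recon")
}
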