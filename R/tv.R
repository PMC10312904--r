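# Smoothed isotropic total variation and its exact gradient. Forward
# differences with replicated (Neumann) boundary; the gradient is the true
# analytic gradient of tv_value, which the descent-step bound relies on.

.dx <- function(v) rbind(v[-1, , drop = FALSE] - v[-nrow(v), , drop = FALSE], 0)
.dy <- function(v) cbind(v[, -1, drop = FALSE] - v[, -ncol(v), drop = FALSE], 0)
.dxT <- function(u) {  # adjoint of .dx (negative divergence component)
  n <- nrow(u)
  rbind(-u[1, , drop = FALSE],
        u[-c(n - 1, n), , drop = FALSE] - u[-c(1, n), , drop = FALSE],
        u[n - 1, , drop = FALSE])
}
.dyT <- function(u) t(.dxT(t(u)))

#' Smoothed isotropic total variation
#'
#' `TV_eps = sum sqrt(dx^2 + dy^2 + eps^2)` over forward-difference
#' gradients. The `eps` smoothing (a Huber-style rounding of the kink)
#' makes the functional differentiable everywhere; its gradient has
#' Lipschitz constant at most `8 / eps`.
#'
#' @param image An `image_grid` or numeric matrix.
#' @param epsilon Smoothing length in the units of the image values (> 0).
#' @return `tv_value`: a scalar; `tv_gradient`: a matrix, the exact gradient
#'   of `tv_value` with respect to the pixel values.
#' @export
tv_value <- function(image, epsilon) {
  v <- if (inherits(image, "image_grid")) image$values else as.matrix(image)
  if (epsilon <= 0) stop("epsilon must be > 0")
  sum(sqrt(.dx(v)^2 + .dy(v)^2 + epsilon^2))
}

#' @rdname tv_value
#' @export
tv_gradient <- function(image, epsilon) {
  v <- if (inherits(image, "image_grid")) image$values else as.matrix(image)
  if (epsilon <= 0) stop("epsilon must be > 0")
  gx <- .dx(v); gy <- .dy(v)
  phi <- sqrt(gx^2 + gy^2 + epsilon^2)
  .dxT(gx / phi) + .dyT(gy / phi)
}

#' MBIR-TV configuration
#'
#' @param beta Weight of the TV penalty (>= 0).
#' @param epsilon TV smoothing length (mm^-1 gradient units, > 0).
#' @param omega Gradient step size; `NULL` picks
#'   `1.8 / (lambda_max + beta * 8 / epsilon)` from a power-iteration
#'   estimate of the data-term curvature.
#' @param n_iters Number of iterations.
#' @return An object of class `tv_config`.
#' @export
tv_config <- function(beta = 1e5, epsilon = 2e-4, omega = NULL, n_iters = 40L) {
  if (beta < 0) stop("beta must be >= 0")
  if (epsilon <= 0) stop("epsilon must be > 0")
  structure(list(beta = beta, epsilon = epsilon, omega = omega,
                 n_iters = as.integer(n_iters)),
            class = "tv_config")
}

#' Model-based iterative reconstruction with total variation
#'
#' Gradient descent on the penalized weighted least squares objective
#' `0.5 * t(A mu - b) D (A mu - b) + beta * TV_eps(mu)`:
#' `mu <- mu - omega * (t(A) D (A mu - b) + beta * grad TV_eps(mu))`.
#' This is literally the score-prior iteration of [adsf_reconstruct()] with
#' the learned score replaced by the hand-crafted `-beta * grad TV_eps`
#' (both run through the same internal engine).
#'
#' @param system A `wls_system` from [linearize()].
#' @param proj A `ct_projector`.
#' @param cfg A [tv_config()].
#' @param init Initial image: `"zeros"`, `"fbp"`, or an `image_grid`/matrix.
#' @return A `ct_recon` with the per-iteration objective in
#'   `$details$objective`. Errors out advising a smaller `omega` if the
#'   objective increases for 10 consecutive iterations.
#' @export
mbir_tv <- function(system, proj, cfg = tv_config(), init = "zeros") {
  stopifnot(inherits(system, "wls_system"), inherits(proj, "ct_projector"),
            inherits(cfg, "tv_config"))
  omega <- cfg$omega
  if (is.null(omega)) {
    lam <- estimate_extreme_eigs(proj, system$D, n_iters = 50L, seed = 7L)
    omega <- 1.8 / (lam[["lambda_max"]] + cfg$beta * 8 / cfg$epsilon)
  }
  score_fun <- function(mu) -cfg$beta * tv_gradient(mu, cfg$epsilon)
  objective <- function(mu, resid)
    0.5 * sum(system$D * resid^2) + cfg$beta * tv_value(mu, cfg$epsilon)
  res <- .map_iterate(system, proj, score_fun, omega = omega, sigma = omega,
                      max_iters = cfg$n_iters, tol = 0, init = init,
                      objective_fun = objective, divergence = "objective")
  new_ct_recon(image_grid(pmax(res$mu, 0), proj$pixel_size), method = "mbir_tv",
               proj = proj, system = system,
               details = list(config = cfg, omega = omega,
                              objective = res$objective,
                              n_iters_run = res$n_iters,
                              report = res$report,
                              image_unclipped = res$mu))
}
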