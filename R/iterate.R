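# Shared fixed-point engine behind the iterative reconstructions:
#   mu <- mu - omega * t(A) D (A mu - b) + sigma * score(mu)
# The TV baseline and the learned-prior MAP reconstruction differ only in
# the score term and in how divergence is policed.

.init_image <- function(init, system, proj) {
  if (is.character(init)) {
    switch(init,
           zeros = matrix(0, proj$n, proj$n),
           fbp = {
             s <- sinogram(system$b, "line_integrals", system$geometry)
             coef(fbp(s, proj))
           },
           stop("unknown init mode: ", init))
  } else if (inherits(init, "image_grid")) init$values
  else as.matrix(init)
}

.map_iterate <- function(system, proj, score_fun, omega, sigma, max_iters,
                         tol, init, objective_fun = NULL,
                         divergence = c("none", "objective", "ratio")) {
  divergence <- match.arg(divergence)
  a <- .proj_args(proj)
  mu <- .init_image(init, system, proj)
  diff_norms <- numeric(0)
  objective <- numeric(0)
  bad <- 0L
  for (k in seq_len(max_iters)) {
    resid <- fan_forward_cpp(mu, a$angles, a$ndet, a$dgamma, a$rs, a$h) - system$b
    grad <- fan_back_cpp(system$D * resid, a$angles, a$ndet, a$dgamma, a$rs,
                         a$h, a$n)
    mu_new <- mu - omega * grad + sigma * score_fun(mu)
    dn <- sqrt(sum((mu_new - mu)^2))
    diff_norms <- c(diff_norms, dn)
    if (!is.null(objective_fun)) {
      # objective at the pre-update iterate: reuses the residual already
      # computed, avoiding a second forward projection per iteration
      obj <- objective_fun(mu, resid)
      objective <- c(objective, obj)
      if (divergence == "objective") {
        bad <- if (k > 1 && obj > objective[k - 1]) bad + 1L else 0L
        if (bad >= 10L)
          stop("objective increased for 10 consecutive iterations: ",
               "the step size omega is too large, choose a smaller one")
      }
    }
    if (divergence == "ratio" && k > 1) {
      bad <- if (dn > diff_norms[k - 1]) bad + 1L else 0L
      if (bad >= 20L) {
        cond <- structure(class = c("scorect_divergence", "error", "condition"),
                          list(message = paste0(
                            "iteration diverging: contraction ratio > 1 for 20 ",
                            "consecutive iterations (reduce omega/sigma)"),
                            call = NULL,
                            report = convergence_report(diff_norms)))
        stop(cond)
      }
    }
    mu <- mu_new
    denom <- sqrt(sum(mu^2))
    if (tol > 0 && denom > 0 && dn / denom < tol) break
  }
  list(mu = mu, diff_norms = diff_norms, objective = objective, n_iters = k,
       report = convergence_report(diff_norms))
}

#' Convergence report of an iterative run
#'
#' Collects the successive-difference norms `||mu_{k+1} - mu_k||`, their
#' empirical contraction ratios, and (when available) the step-size
#' validation verdict.
#'
#' @param diff_norms Numeric vector of successive-difference norms (>= 0).
#' @param step_valid Logical verdict from [validate_step_params()], or NULL.
#' @param margins Named slack vector from the validation, or NULL.
#' @return An object of class `convergence_report`.
#' @export
convergence_report <- function(diff_norms, step_valid = NULL, margins = NULL) {
  if (any(diff_norms < 0)) stop("difference norms must be >= 0")
  d <- diff_norms
  q <- if (length(d) >= 2) {
    num <- d[-1]; den <- d[-length(d)]
    ifelse(den == 0, 0, num / den)
  } else numeric(0)
  structure(list(diff_norms = d, q = q, step_valid = step_valid,
                 margins = margins),
            class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  cat(sprintf("Convergence report: %d iterations, final step norm %.3g\n",
              length(x$diff_norms),
              if (length(x$diff_norms)) utils::tail(x$diff_norms, 1) else NA))
  if (length(x$diff_norms) >= 3)
    cat(sprintf("  empirical contraction q (tail median): %.4f\n",
                contraction_check(x)))
  if (!is.null(x$step_valid))
    cat(sprintf("  step parameters %s the contraction bounds\n",
                if (isTRUE(x$step_valid)) "satisfy" else "violate"))
  invisible(x)
}

#' @export
as.data.frame.convergence_report <- function(x, ...) {
  data.frame(iteration = seq_along(x$diff_norms), diff_norm = x$diff_norms,
             q = c(NA, x$q))
}

#' Empirical contraction factor
#'
#' Median of the successive-difference ratios `q_k = d_{k+1} / d_k` over the
#' tail half of the run (zero steps contribute q = 0). A value below 1 is
#' the empirical signature of the geometric (Cauchy) convergence the step
#' bounds guarantee.
#'
#' @param report A `convergence_report`, or a numeric vector of
#'   successive-difference norms.
#' @return The median tail contraction ratio.
#' @export
contraction_check <- function(report) {
  if (is.numeric(report)) report <- convergence_report(report)
  if (length(report$diff_norms) < 3)
    stop("need at least 3 recorded iterations to estimate the contraction factor")
  q <- report$q
  tail_q <- q[seq(ceiling(length(q) / 2), length(q))]
  stats::median(tail_q)
}
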