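# Common S3 container for reconstruction results. Every reconstructor
# (FBP, MBIR-TV, score-prior MAP) returns a `ct_recon`, so downstream code
# (metrics, plotting, residual inspection) is method-agnostic.

new_ct_recon <- function(image, method, proj, system = NULL, details = list(),
                         subclass = NULL) {
  structure(list(image = image, method = method, proj = proj,
                 system = system, details = details,
                 call = sys.call(-1)),
            class = c(subclass, "ct_recon"))
}

#' @export
print.ct_recon <- function(x, ...) {
  cat(sprintf("CT reconstruction (method: %s)\n", x$method))
  print(x$image)
  if (!is.null(x$details$n_iters_run))
    cat(sprintf("  iterations run: %d\n", x$details$n_iters_run))
  invisible(x)
}

#' @export
summary.ct_recon <- function(object, ...) {
  v <- object$image$values
  cat(sprintf("CT reconstruction -- %s\n", object$method))
  cat(sprintf("  grid        : %d x %d at %.4g mm\n",
              nrow(v), ncol(v), object$image$pixel_size))
  cat(sprintf("  attenuation : min %.4g, median %.4g, max %.4g mm^-1\n",
              min(v), stats::median(v), max(v)))
  h <- object$details$objective
  if (!is.null(h))
    cat(sprintf("  objective   : %.6g -> %.6g over %d iterations\n",
                h[1], h[length(h)], length(h)))
  r <- object$details$report
  if (!is.null(r)) {
    cat(sprintf("  convergence : final step norm %.3g", utils::tail(r$diff_norms, 1)))
    if (length(r$diff_norms) >= 3)
      cat(sprintf(", empirical contraction q = %.3f", contraction_check(r)))
    cat("\n")
    if (!is.null(r$step_valid))
      cat(sprintf("  step params : %s\n",
                  if (isTRUE(r$step_valid)) "within the contraction bounds"
                  else "outside the contraction bounds (warn-and-proceed)"))
  }
  invisible(object)
}

#' @export
coef.ct_recon <- function(object, ...) object$image$values

#' @export
plot.ct_recon <- function(x, ...) plot(x$image, main = paste("recon:", x$method), ...)

#' @export
fitted.ct_recon <- function(object, ...) {
  forward_project(object$image, object$proj)
}

#' Sinogram-domain residuals of a reconstruction
#'
#' For iterative reconstructions built from a weighted system, returns
#' `b - A mu` (the line-integral misfit); for FBP, the input sinogram must
#' be supplied via `sino`.
#' @param object A `ct_recon`.
#' @param sino Optional `sinogram` of line integrals to difference against.
#' @param ... Unused.
#' @return A `sinogram` of residuals (line-integral domain).
#' @export
residuals.ct_recon <- function(object, sino = NULL, ...) {
  pred <- fitted(object)
  b <- if (!is.null(sino)) {
    .check_domain(sino, "line_integrals")
    sino$values
  } else if (!is.null(object$system)) object$system$b
  else stop("no stored system; supply the measured line-integral sinogram via sino=")
  sinogram(b - pred$values, "line_integrals", object$proj$geometry)
}
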