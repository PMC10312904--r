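# Gaussian-mixture perturbation model and the denoising score-matching
# objective built on it. Data x (normalized to [0, 1]) is corrupted as
# x~ = x + sigma * N(0, I) with sigma drawn from a discrete schedule; the
# posterior responsibilities of the noise levels given the realized
# perturbation (the lambda weights) turn the mixture's conditional score
# into a weighted sum of single-Gaussian scores, and weight the training
# loss so that its pointwise minimizer is exactly that mixture score.

#' Noise-level schedule of the Gaussian mixture
#'
#' @param sigmas Distinct non-negative noise standard deviations (units of
#'   the normalized image intensity), sorted ascending.
#' @param probs Matching mixture probabilities, non-negative, summing to 1.
#' @return An object of class `noise_schedule`.
#' @export
noise_schedule <- function(sigmas, probs) {
  if (length(sigmas) != length(probs)) stop("sigmas and probs must match in length")
  if (any(sigmas < 0)) stop("sigmas must be >= 0")
  if (is.unsorted(sigmas, strictly = TRUE)) stop("sigmas must be distinct and ascending")
  if (any(probs < 0)) stop("probs must be >= 0")
  if (abs(sum(probs) - 1) > 1e-12) stop("probs must sum to 1")
  structure(list(sigmas = as.numeric(sigmas), probs = as.numeric(probs)),
            class = "noise_schedule")
}

#' @export
print.noise_schedule <- function(x, ...) {
  cat("Gaussian-mixture noise schedule:\n")
  print(data.frame(sigma = x$sigmas, prob = signif(x$probs, 4)),
        row.names = FALSE)
  invisible(x)
}

#' Binomial noise schedule
#'
#' The default training schedule: noise levels 0.00, 0.01, ..., 0.10 with
#' mixture weights given by the binomial(10, 0.5) pmf at k = 0..10
#' (0.0010, 0.0098, 0.0439, 0.1172, 0.2051, 0.2461, ... to 4 decimals),
#' stored at full precision.
#'
#' @return A `noise_schedule`.
#' @export
binomial_noise_schedule <- function() {
  noise_schedule(sigmas = seq(0, 0.10, by = 0.01),
                 probs = stats::dbinom(0:10, size = 10, prob = 0.5))
}

#' Perturb a patch with mixture noise
#'
#' Draws one noise level from the schedule and adds an i.i.d. Gaussian
#' field of that standard deviation. A sigma = 0 draw returns the input
#' unchanged (such draws are excluded from the training loss by the caller,
#' where the loss term is undefined).
#'
#' @param x Numeric array/matrix (a patch, normalized intensities).
#' @param schedule A `noise_schedule`.
#' @param seed Integer seed; the draw is a pure function of it.
#' @return List with `x_tilde` (perturbed patch) and `sigma` (the level drawn).
#' @export
perturb <- function(x, schedule, seed) {
  stopifnot(inherits(schedule, "noise_schedule"))
  .with_seed(seed, {
    s <- schedule$sigmas[sample.int(length(schedule$sigmas), 1L,
                                    prob = schedule$probs)]
    xt <- if (s == 0) x else x + s * array(stats::rnorm(length(x)), dim(x) %||% length(x))
    list(x_tilde = xt, sigma = s)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# log N(diff; 0, sigma^2 I) for a d-element diff with squared norm ss
.log_gauss <- function(ss, d, sigma) {
  -0.5 * d * log(2 * pi * sigma^2) - ss / (2 * sigma^2)
}

#' Posterior noise-level responsibilities (lambda weights)
#'
#' `lambda_sigma = p(sigma) G(diff; 0, sigma^2 I) / sum_sigma' p(sigma') G`,
#' computed in log space. A sigma = 0 component carries all the weight only
#' for an exactly zero perturbation; for any nonzero `diff` its density
#' limit is zero and it is excluded.
#'
#' @param diff The realized perturbation `x_tilde - x` (any numeric array).
#' @param schedule A `noise_schedule` with at least one sigma > 0.
#' @return Numeric vector of weights over the schedule levels, summing to 1.
#' @export
lambda_weights <- function(diff, schedule) {
  stopifnot(inherits(schedule, "noise_schedule"))
  if (all(schedule$sigmas == 0)) stop("schedule must contain a sigma > 0")
  d <- length(diff)
  ss <- sum(diff^2)
  lw <- rep(-Inf, length(schedule$sigmas))
  pos <- schedule$sigmas > 0 & schedule$probs > 0
  lw[pos] <- log(schedule$probs[pos]) + .log_gauss(ss, d, schedule$sigmas[pos])
  zero <- which(schedule$sigmas == 0 & schedule$probs > 0)
  if (length(zero) && ss == 0) {
    # the point mass dominates any density: all weight to sigma = 0
    w <- numeric(length(lw)); w[zero] <- 1
    return(w)
  }
  m <- max(lw)
  w <- exp(lw - m)
  w / sum(w)
}

#' Conditional score of the Gaussian-mixture perturbation
#'
#' The gradient of `log p(x_tilde | x)` with respect to the perturbed
#' image: the responsibility-weighted sum of single-Gaussian scores,
#' `sum_sigma lambda_sigma * (-diff) / sigma^2` (the sigma = 0 component
#' carries zero weight for any nonzero diff).
#'
#' @inheritParams lambda_weights
#' @return A score field shaped like `diff`.
#' @export
mixture_score <- function(diff, schedule) {
  w <- lambda_weights(diff, schedule)
  pos <- schedule$sigmas > 0
  fac <- sum(w[pos] / schedule$sigmas[pos]^2)
  -diff * fac
}

#' Log-density of the mixture perturbation (for oracle checks)
#'
#' `log sum_sigma p(sigma) G(x_tilde; x, sigma^2 I)`, evaluated stably in
#' log space; [mixture_score()] is its analytic gradient in `x_tilde`.
#'
#' @inheritParams lambda_weights
#' @return A scalar.
#' @export
mixture_log_density <- function(diff, schedule) {
  stopifnot(inherits(schedule, "noise_schedule"))
  d <- length(diff)
  ss <- sum(diff^2)
  pos <- schedule$sigmas > 0 & schedule$probs > 0
  lw <- log(schedule$probs[pos]) + .log_gauss(ss, d, schedule$sigmas[pos])
  m <- max(lw)
  m + log(sum(exp(lw - m)))
}

#' Denoising score-matching loss of one perturbed sample
#'
#' `lambda(sigma_drawn, diff) * mean((net_output + diff / sigma_drawn^2)^2)`:
#' the scalar responsibility weight multiplies the squared deviation of the
#' network output from the single-level denoising target, averaged over
#' pixels. Over the schedule, the constant output minimizing the expected
#' loss is exactly [mixture_score()], which ties this objective to the
#' mixture's conditional score.
#'
#' @param net_output Network score field, shaped like `diff`.
#' @param diff The realized perturbation `x_tilde - x`.
#' @param sigma_drawn The noise level that generated `diff` (> 0; callers
#'   must filter out sigma = 0 draws).
#' @param schedule The `noise_schedule` used for the perturbation.
#' @return A non-negative scalar.
#' @export
adsf_loss <- function(net_output, diff, sigma_drawn, schedule) {
  if (length(net_output) != length(diff))
    stop("net_output and diff must have the same shape")
  if (sigma_drawn <= 0)
    stop("sigma_drawn must be > 0 (sigma = 0 draws carry no loss term)")
  lam <- lambda_weights(diff, schedule)[match(sigma_drawn, schedule$sigmas)]
  if (is.na(lam)) stop("sigma_drawn is not a level of the schedule")
  lam * mean((net_output + diff / sigma_drawn^2)^2)
}
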