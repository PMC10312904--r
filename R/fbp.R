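#' FBP configuration
#'
#' @param filter Ramp filter kind: `"ram-lak"` (pure band-limited ramp) or
#'   `"hann"` (Hann-windowed ramp, trades resolution for noise).
#' @param pad_factor Zero-padding factor for the frequency-domain filtering
#'   (>= 2, default 2); padding to at least twice the detector count makes
#'   the circular convolution linear.
#' @return An object of class `fbp_config`.
#' @export
fbp_config <- function(filter = c("ram-lak", "hann"), pad_factor = 2) {
  filter <- match.arg(filter)
  if (pad_factor < 2) stop("pad_factor must be >= 2")
  structure(list(filter = filter, pad_factor = pad_factor),
            class = "fbp_config")
}

# Band-limited ramp impulse response on the equiangular detector, sampled at
# the angular pitch dgamma (the curved-detector form: sin^2 instead of the
# flat-detector n^2 in the odd taps).
.fan_ramp_kernel <- function(npad, dgamma) {
  idx <- c(0:(npad - 1), -(npad):-1)  # FFT ordering over 2*npad taps
  g <- numeric(2 * npad)
  g[idx == 0] <- 1 / (8 * dgamma^2)
  odd <- idx %% 2 != 0
  g[odd] <- -0.5 / (pi * sin(idx[odd] * dgamma))^2
  g
}

#' Fan-beam filtered backprojection
#'
#' Equiangular curved-detector FBP: cosine pre-weighting of the detector
#' samples, per-view ramp filtering by padded frequency-domain
#' multiplication, and distance-weighted (1/L^2) backprojection. Linear in
#' the sinogram. Full-scan (2*pi) acquisitions only; shorter angular ranges
#' reconstruct but with a warning, since no short-scan weighting is applied.
#'
#' @param sino A `sinogram` tagged `line_integrals`.
#' @param proj A `ct_projector` defining the output grid.
#' @param cfg An [fbp_config()].
#' @return A `ct_recon` object whose `image` element holds the
#'   reconstruction.
#' @export
fbp <- function(sino, proj, cfg = fbp_config()) {
  .check_domain(sino, "line_integrals")
  stopifnot(inherits(proj, "ct_projector"), inherits(cfg, "fbp_config"))
  g <- proj$geometry
  if (!isTRUE(all.equal(g$angular_range, 2 * pi)))
    warning("FBP assumes full 2*pi angular coverage; no short-scan weighting applied")
  a <- .proj_args(proj)
  ndet <- a$ndet
  dg <- a$dgamma
  gam <- (seq_len(ndet) - 1 - (ndet - 1) / 2) * dg
  # cosine weighting and source-distance factor
  p <- sweep(sino$values, 2, g$source_to_center * cos(gam), `*`)
  npad <- cfg$pad_factor * 2^ceiling(log2(ndet))
  kern <- .fan_ramp_kernel(npad / 2, dg)[seq_len(npad)]
  if (cfg$filter == "hann") {
    H <- Re(stats::fft(kern))
    w <- 0.5 * (1 + cos(2 * pi * seq(0, npad - 1) / npad))
    Hf <- H * w
  } else {
    Hf <- Re(stats::fft(kern))
  }
  P <- matrix(0, nrow(p), npad)
  P[, seq_len(ndet)] <- p
  Q <- t(apply(P, 1, function(row) {
    Re(stats::fft(stats::fft(row) * Hf, inverse = TRUE)) / npad
  }))[, seq_len(ndet), drop = FALSE]
  Q <- Q * dg  # discretized convolution over gamma
  dbeta <- g$angular_range / g$n_views
  img <- fbp_backproject_cpp(Q, a$angles, ndet, dg, a$rs, a$h, a$n, dbeta)
  new_ct_recon(image_grid(img, proj$pixel_size), method = "fbp",
               proj = proj, details = list(config = cfg))
}
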