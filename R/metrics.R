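#' Peak signal-to-noise ratio
#'
#' `10 * log10(peak^2 / MSE)` in dB; identical inputs return `Inf`.
#'
#' @param image,reference Same-shaped numeric matrices or `image_grid`s.
#' @param peak Signal peak; defaults to the maximum of the reference.
#' @return PSNR in dB.
#' @export
psnr <- function(image, reference, peak = NULL) {
  a <- if (inherits(image, "image_grid")) image$values else as.matrix(image)
  b <- if (inherits(reference, "image_grid")) reference$values else as.matrix(reference)
  if (!all(dim(a) == dim(b))) stop("image and reference shapes differ")
  if (is.null(peak)) peak <- max(b)
  if (peak <= 0) stop("peak must be > 0")
  mse <- mean((a - b)^2)
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}

.gauss_band <- function(n, win, sd) {
  half <- (win - 1) / 2
  g <- exp(-((-half):half)^2 / (2 * sd^2))
  g <- g / sum(g)
  M <- matrix(0, n, n)
  for (o in (-half):half) {
    idx <- seq_len(n - abs(o))
    if (o >= 0) M[cbind(idx + o, idx)] <- g[o + half + 1]
    else M[cbind(idx, idx - o)] <- g[o + half + 1]
  }
  M
}

#' Structural similarity index
#'
#' Mean local SSIM over an 11x11 Gaussian window (sd 1.5) with stability
#' constants `K1 = 0.01`, `K2 = 0.03`. Local statistics are computed by
#' separable Gaussian filtering and the border of half a window width is
#' cropped before averaging, so every retained window has full support.
#' The dynamic range defaults to `max - min` of the reference (1 if the
#' reference is constant).
#'
#' @param image,reference Same-shaped matrices or `image_grid`s, at least
#'   11 pixels per side.
#' @param dynamic_range Intensity range L entering the stability constants;
#'   default from the reference.
#' @return Mean SSIM (in `[-1, 1]`).
#' @export
ssim <- function(image, reference, dynamic_range = NULL) {
  a <- if (inherits(image, "image_grid")) image$values else as.matrix(image)
  b <- if (inherits(reference, "image_grid")) reference$values else as.matrix(reference)
  if (!all(dim(a) == dim(b))) stop("image and reference shapes differ")
  win <- 11L; sd <- 1.5; K1 <- 0.01; K2 <- 0.03
  if (any(dim(a) < win)) stop("images must be at least 11 x 11 for SSIM")
  if (is.null(dynamic_range)) {
    dynamic_range <- diff(range(b))
    if (dynamic_range == 0) dynamic_range <- 1
  }
  C1 <- (K1 * dynamic_range)^2
  C2 <- (K2 * dynamic_range)^2
  Gr <- .gauss_band(nrow(a), win, sd)
  Gc <- .gauss_band(ncol(a), win, sd)
  f <- function(x) Gr %*% x %*% t(Gc)
  mu1 <- f(a); mu2 <- f(b)
  s11 <- f(a * a) - mu1^2
  s22 <- f(b * b) - mu2^2
  s12 <- f(a * b) - mu1 * mu2
  map <- ((2 * mu1 * mu2 + C1) * (2 * s12 + C2)) /
    ((mu1^2 + mu2^2 + C1) * (s11 + s22 + C2))
  half <- (win - 1) / 2
  ri <- (half + 1):(nrow(a) - half)
  ci <- (half + 1):(ncol(a) - half)
  mean(map[ri, ci])
}
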