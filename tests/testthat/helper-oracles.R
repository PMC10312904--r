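# Shared oracles and small fixtures, all built in code at test time.

# Small fan-beam setups sized so that exact (dense) linear algebra is cheap.
small_geometry <- function(n_detectors = 128L, n_views = 90L, pitch = 1.7) {
  scan_geometry(595, 1085.6, n_detectors, pitch, n_views)
}

# Lazily built and cached 32x32 weighted-least-squares problem with the
# materialized system matrix (used by several oracle tests).
.fixture_env <- new.env(parent = emptyenv())
small_wls_problem <- function() {
  if (!is.null(.fixture_env$p32)) return(.fixture_env$p32)
  g <- small_geometry()
  proj <- projector(g, 32)
  truth <- random_phantom(11, n = 32, pixel_size = proj$pixel_size)
  counts <- sample_counts(expected_counts(forward_project(truth, proj), 1e5),
                          seed = 2)
  sys <- linearize(counts, 1e5)
  A <- materialize_system_matrix(proj)
  .fixture_env$p32 <- list(geometry = g, proj = proj, truth = truth,
                           sys = sys, A = A,
                           D = as.vector(sys$D), b = as.vector(sys$b))
  .fixture_env$p32
}

# Naive dense double-precision 2-D convolution, same padding, weight layout
# row = c*k^2 + kx*k + ky (matching the package's compiled kernels). The
# independent reference for the conv dual-implementation checks.
ref_conv2d <- function(x, w, b, k) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  Cout <- ncol(w)
  pad <- (k - 1) / 2
  y <- array(0, c(H, W, Cout))
  for (co in seq_len(Cout)) {
    acc <- matrix(b[co], H, W)
    for (ci in seq_len(C)) for (kx in 0:(k - 1)) for (ky in 0:(k - 1)) {
      wgt <- w[(ci - 1) * k * k + kx * k + ky + 1, co]
      if (wgt == 0) next
      dr <- ky - pad; dc <- kx - pad
      rr <- seq_len(H); cc <- seq_len(W)
      src_r <- rr + dr; src_c <- cc + dc
      ok_r <- src_r >= 1 & src_r <= H; ok_c <- src_c >= 1 & src_c <= W
      acc[rr[ok_r], cc[ok_c]] <- acc[rr[ok_r], cc[ok_c]] +
        wgt * x[src_r[ok_r], src_c[ok_c], ci]
    }
    y[, , co] <- acc
  }
  y
}

# Conjugate gradients on a symmetric positive definite operator; the
# independent route to weighted least squares solutions.
cg_solve <- function(opfun, rhs, tol = 1e-12, maxit = 5000L) {
  x <- numeric(length(rhs))
  r <- rhs; p <- r
  rs <- sum(r * r)
  for (i in seq_len(maxit)) {
    Ap <- opfun(p)
    alpha <- rs / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    rs_new <- sum(r * r)
    if (sqrt(rs_new) < tol * sqrt(sum(rhs^2))) break
    p <- r + (rs_new / rs) * p
    rs <- rs_new
  }
  x
}

# Central-difference gradient of a scalar function of a vector.
num_grad <- function(f, x, h = 1e-5) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    e <- numeric(length(x)); e[i] <- h
    g[i] <- (f(x + e) - f(x - e)) / (2 * h)
  }
  g
}
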