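# The residual score network. Four residual blocks -- the first two with
# three 5x5 convolutions of 32 filters each, the last two with three 3x3
# convolutions of 32 filters -- followed by a 16-filter 3x3, an 8-filter 3x3
# and a single-filter 3x3 head. Every convolution is followed by a ReLU
# except the output layer, which stays linear so the network can represent
# a signed score field; the 1 -> 32 channel jump at the entry block is
# bridged by a 1x1 projection on the skip path. Weights are drawn from
# N(0, 0.01^2), biases start at zero.

.score_layer_defs <- function() {
  data.frame(
    name = c("b1c1", "b1c2", "b1c3", "b1p",
             "b2c1", "b2c2", "b2c3",
             "b3c1", "b3c2", "b3c3",
             "b4c1", "b4c2", "b4c3",
             "h1", "h2", "h3"),
    k    = c(5, 5, 5, 1,  5, 5, 5,  3, 3, 3,  3, 3, 3,  3, 3, 3),
    cin  = c(1, 32, 32, 1,  32, 32, 32,  32, 32, 32,  32, 32, 32,  32, 16, 8),
    cout = c(32, 32, 32, 32,  32, 32, 32,  32, 32, 32,  32, 32, 32,  16, 8, 1),
    stringsAsFactors = FALSE)
}

#' Architecture summary of the score network
#'
#' @return A data frame with one row per convolution layer (kernel size,
#'   input and output channels); `b1p` is the 1x1 skip projection of the
#'   entry block.
#' @export
score_network_spec <- function() .score_layer_defs()

#' Build an untrained score network
#'
#' All convolution weights are drawn i.i.d. from a zero-mean Gaussian with
#' standard deviation `init_sd`; biases are zero. Deterministic given the
#' seed.
#'
#' @param seed Integer seed for the weight draw.
#' @param init_sd Initialization standard deviation (default 0.01).
#' @return An object of class `score_prior` (untrained: `$trained` is FALSE).
#' @export
score_network <- function(seed = 1L, init_sd = 0.01) {
  defs <- .score_layer_defs()
  layers <- .with_seed(seed, {
    out <- list()
    for (i in seq_len(nrow(defs))) {
      d <- defs[i, ]
      out[[d$name]] <- list(
        w = matrix(stats::rnorm(d$k * d$k * d$cin * d$cout, sd = init_sd),
                   d$k * d$k * d$cin, d$cout),
        b = numeric(d$cout), k = d$k)
    }
    out
  })
  structure(list(layers = layers, defs = defs, schedule = NULL, scale = 1,
                 trained = FALSE, history = numeric(0)),
            class = "score_prior")
}

#' Number of trainable parameters of a score network
#' @param net A `score_prior`.
#' @return Total count of weights and biases.
#' @export
count_parameters <- function(net) {
  sum(vapply(net$layers, function(l) length(l$w) + length(l$b), numeric(1)))
}

#' @export
print.score_prior <- function(x, ...) {
  cat(sprintf("Score prior: residual CNN, %d layers, %d parameters (%s)\n",
              nrow(x$defs), count_parameters(x),
              if (x$trained) "trained" else "untrained"))
  if (!is.null(x$schedule))
    cat(sprintf("  noise schedule: %d levels, sigma in [%g, %g]\n",
                length(x$schedule$sigmas), min(x$schedule$sigmas),
                max(x$schedule$sigmas)))
  if (x$scale != 1)
    cat(sprintf("  intensity normalization: 1 unit = %g mm^-1\n", x$scale))
  invisible(x)
}

.relu <- function(y) { y[y < 0] <- 0; y }

.as_batch <- function(x) {
  if (is.matrix(x)) array(x, c(dim(x), 1L, 1L))
  else if (length(dim(x)) == 3L) array(x, c(dim(x)[1:2], 1L, dim(x)[3]))
  else x
}

# Forward pass. x: array (H, W, 1, N). Returns the output field and, when
# cache = TRUE, every convolution's input and post-activation output plus
# the block inputs (needed for the skip-path gradients).
.net_forward <- function(net, x, cache = FALSE) {
  L <- net$layers
  cc <- if (cache) new.env(parent = emptyenv()) else NULL
  conv <- function(name, x, act) {
    l <- L[[name]]
    y <- conv2d_fwd_cpp(x, l$w, l$b, l$k)
    if (act) y <- .relu(y)
    if (cache) assign(name, list(x = x, y = y), envir = cc)
    y
  }
  block <- function(x, pre, skip_name = NULL) {
    t <- conv(paste0(pre, "c1"), x, TRUE)
    t <- conv(paste0(pre, "c2"), t, TRUE)
    t <- conv(paste0(pre, "c3"), t, TRUE)
    s <- if (is.null(skip_name)) x else conv(skip_name, x, FALSE)
    t + s
  }
  h <- block(x, "b1", "b1p")
  h <- block(h, "b2")
  h <- block(h, "b3")
  h <- block(h, "b4")
  h <- conv("h1", h, TRUE)
  h <- conv("h2", h, TRUE)
  out <- conv("h3", h, FALSE)
  list(out = out, cache = cc)
}

# Reverse pass: returns a list of per-layer gradients (dw, db) given the
# cache of a forward pass and the loss gradient with respect to the output.
.net_backward <- function(net, cache, dout) {
  L <- net$layers
  grads <- list()
  conv_bwd <- function(name, dy, act) {
    cval <- get(name, envir = cache)
    if (act) dy <- dy * (cval$y > 0)
    g <- conv2d_bwd_cpp(cval$x, L[[name]]$w, dy, L[[name]]$k)
    grads[[name]] <<- list(dw = g$dw, db = g$db)
    g$dx
  }
  block_bwd <- function(dy, pre, skip_name = NULL) {
    d <- conv_bwd(paste0(pre, "c3"), dy, TRUE)
    d <- conv_bwd(paste0(pre, "c2"), d, TRUE)
    d <- conv_bwd(paste0(pre, "c1"), d, TRUE)
    dskip <- if (is.null(skip_name)) dy else conv_bwd(skip_name, dy, FALSE)
    d + dskip
  }
  d <- conv_bwd("h3", dout, FALSE)
  d <- conv_bwd("h2", d, TRUE)
  d <- conv_bwd("h1", d, TRUE)
  d <- block_bwd(d, "b4")
  d <- block_bwd(d, "b3")
  d <- block_bwd(d, "b2")
  d <- block_bwd(d, "b1", "b1p")
  grads
}

#' Evaluate the score network on an image or patch batch
#'
#' Deterministic; the output has the spatial shape of the input. Inputs are
#' expected on the normalized `[0, 1]` intensity scale the network was
#' trained on (see [adsf_reconstruct()] for the chain-rule bridge back to
#' attenuation units).
#'
#' @param object A `score_prior`.
#' @param x A matrix (single image), a 3-D array (batch of single-channel
#'   patches), or a 4-D `(H, W, 1, N)` array.
#' @param ... Unused.
#' @return The score field(s), shaped like the input.
#' @export
predict.score_prior <- function(object, x, ...) {
  xb <- .as_batch(x)
  out <- .net_forward(object, xb, cache = FALSE)$out
  if (!all(is.finite(out))) stop("score network produced non-finite output")
  if (is.matrix(x)) matrix(out, nrow(x), ncol(x))
  else if (length(dim(x)) == 3L) array(out, dim(x))
  else out
}
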