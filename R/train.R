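#' Training configuration for the score network
#'
#' Defaults follow the reference training recipe (Adam with decay rates
#' 0.9/0.999, learning rate 1e-4, 32x32 patches, Gaussian init of sd 0.01);
#' the epoch default is a desk-scale 50 rather than the full-scale 1000.
#'
#' @param learning_rate Adam step size (> 0).
#' @param epochs Number of passes over the patch set (>= 1).
#' @param beta1,beta2 Adam exponential decay rates for the first and second
#'   moment estimates.
#' @param batch_size Patches per gradient step.
#' @param lr_decay Multiplicative per-epoch learning-rate decay (1 keeps the
#'   rate constant); annealing the step late in training damps the
#'   oscillation of stochastic updates around the optimum.
#' @param ema_decay Per-step exponential moving average of the weights
#'   (0 disables). With decay `d` the returned model averages roughly the
#'   last `1/(1-d)` update steps, suppressing the stochastic jitter of the
#'   final iterates (Polyak-style averaging).
#' @param patch_size Expected patch side (default 32); informational.
#' @param seed Seed controlling initialization order, shuffling and the
#'   noise draws; training is fully determined by it under serial execution.
#' @param init_sd Weight initialization standard deviation.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, epochs = 50L, beta1 = 0.9,
                         beta2 = 0.999, batch_size = 16L, patch_size = 32L,
                         seed = 1L, init_sd = 0.01, lr_decay = 1,
                         ema_decay = 0) {
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  if (epochs < 1) stop("epochs must be >= 1")
  if (lr_decay <= 0 || lr_decay > 1) stop("lr_decay must be in (0, 1]")
  if (ema_decay < 0 || ema_decay >= 1) stop("ema_decay must be in [0, 1)")
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 beta1 = beta1, beta2 = beta2,
                 batch_size = as.integer(batch_size),
                 patch_size = as.integer(patch_size), seed = as.integer(seed),
                 init_sd = init_sd, lr_decay = lr_decay,
                 ema_decay = ema_decay),
            class = "train_config")
}

#' Train the score network by mixture denoising score matching
#'
#' Stochastic gradient training of the responsibility-weighted denoising
#' loss: each patch is perturbed with a noise level drawn from the
#' schedule, the network predicts a score field on the perturbed patch, and
#' the loss `lambda * mean((s + diff / sigma^2)^2)` is averaged over the
#' batch (zero-sigma draws contribute identity perturbations and are
#' excluded from the loss, with per-batch renormalization). Optimized with
#' Adam; serial and fully deterministic given `cfg$seed`.
#'
#' @param patches 3-D array `(H, W, N)` of training patches on the
#'   normalized `[0, 1]` intensity scale.
#' @param schedule A `noise_schedule` with at least one sigma > 0.
#' @param cfg A [train_config()].
#' @param net Optional starting network (default: fresh [score_network()]
#'   seeded from `cfg`).
#' @param scale Intensity normalization constant (mm^-1 per normalized
#'   unit) recorded in the returned prior and inverted at reconstruction
#'   time.
#' @return A trained `score_prior`; `$history` holds the per-epoch mean loss.
#' @export
train_score <- function(patches, schedule, cfg = train_config(), net = NULL,
                        scale = 1) {
  stopifnot(inherits(schedule, "noise_schedule"))
  if (all(schedule$sigmas == 0)) stop("schedule must contain a sigma > 0")
  if (length(dim(patches)) != 3L) stop("patches must be an (H, W, N) array")
  if (is.null(net)) net <- score_network(seed = cfg$seed, init_sd = cfg$init_sd)
  H <- dim(patches)[1]; W <- dim(patches)[2]; N <- dim(patches)[3]
  P <- H * W
  adam_m <- lapply(net$layers, function(l) list(w = 0 * l$w, b = 0 * l$b))
  adam_v <- adam_m
  ema <- if (cfg$ema_decay > 0) lapply(net$layers, function(l) l[c("w", "b")])
  t_step <- 0L
  history <- numeric(cfg$epochs)
  .with_seed(cfg$seed + 1L, {
    for (epoch in seq_len(cfg$epochs)) {
      lr <- cfg$learning_rate * cfg$lr_decay^(epoch - 1)
      ord <- sample.int(N)
      losses <- numeric(0)
      for (start in seq(1L, N, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, N)]
        B <- length(idx)
        sig <- schedule$sigmas[sample.int(length(schedule$sigmas), B,
                                          replace = TRUE,
                                          prob = schedule$probs)]
        keep <- which(sig > 0)
        if (!length(keep)) next
        B <- length(keep)
        x <- array(patches[, , idx[keep]], c(H, W, 1L, B))
        diffs <- array(stats::rnorm(P * B), c(H, W, 1L, B))
        for (i in seq_len(B)) diffs[, , 1L, i] <- diffs[, , 1L, i] * sig[keep[i]]
        xt <- x + diffs
        fwd <- .net_forward(net, xt, cache = TRUE)
        s <- fwd$out
        resid <- s
        lam <- numeric(B)
        for (i in seq_len(B)) {
          di <- diffs[, , 1L, i]
          lam[i] <- lambda_weights(di, schedule)[
            match(sig[keep[i]], schedule$sigmas)]
          resid[, , 1L, i] <- s[, , 1L, i] + di / sig[keep[i]]^2
        }
        loss <- sum(vapply(seq_len(B), function(i)
          lam[i] * sum(resid[, , 1L, i]^2), numeric(1))) / (B * P)
        if (!is.finite(loss))
          stop(sprintf("non-finite training loss at epoch %d (step %d); ",
                       epoch, t_step + 1L),
               "check patch normalization and the learning rate")
        losses <- c(losses, loss)
        dout <- resid
        for (i in seq_len(B))
          dout[, , 1L, i] <- 2 * lam[i] * resid[, , 1L, i] / (B * P)
        grads <- .net_backward(net, fwd$cache, dout)
        t_step <- t_step + 1L
        corr1 <- 1 - cfg$beta1^t_step
        corr2 <- 1 - cfg$beta2^t_step
        for (nm in names(net$layers)) {
          g <- grads[[nm]]
          adam_m[[nm]]$w <- cfg$beta1 * adam_m[[nm]]$w + (1 - cfg$beta1) * g$dw
          adam_m[[nm]]$b <- cfg$beta1 * adam_m[[nm]]$b + (1 - cfg$beta1) * g$db
          adam_v[[nm]]$w <- cfg$beta2 * adam_v[[nm]]$w + (1 - cfg$beta2) * g$dw^2
          adam_v[[nm]]$b <- cfg$beta2 * adam_v[[nm]]$b + (1 - cfg$beta2) * g$db^2
          net$layers[[nm]]$w <- net$layers[[nm]]$w -
            lr * (adam_m[[nm]]$w / corr1) /
            (sqrt(adam_v[[nm]]$w / corr2) + 1e-8)
          net$layers[[nm]]$b <- net$layers[[nm]]$b -
            lr * (adam_m[[nm]]$b / corr1) /
            (sqrt(adam_v[[nm]]$b / corr2) + 1e-8)
          if (cfg$ema_decay > 0) {
            ema[[nm]]$w <- cfg$ema_decay * ema[[nm]]$w +
              (1 - cfg$ema_decay) * net$layers[[nm]]$w
            ema[[nm]]$b <- cfg$ema_decay * ema[[nm]]$b +
              (1 - cfg$ema_decay) * net$layers[[nm]]$b
          }
        }
      }
      history[epoch] <- mean(losses)
    }
  })
  if (cfg$ema_decay > 0)
    for (nm in names(net$layers)) {
      net$layers[[nm]]$w <- ema[[nm]]$w
      net$layers[[nm]]$b <- ema[[nm]]$b
    }
  net$trained <- TRUE
  net$schedule <- schedule
  net$scale <- scale
  net$history <- history
  net
}

#' Save / load a trained score prior
#'
#' One checkpoint file holding the weights, the layer table, the noise
#' schedule, the intensity normalization constant and the loss history
#' (R serialization).
#'
#' @param prior A `score_prior`.
#' @param path Checkpoint file path.
#' @return `read_score_prior` returns the `score_prior`; the writer returns
#'   `path` invisibly.
#' @export
write_score_prior <- function(prior, path) {
  stopifnot(inherits(prior, "score_prior"))
  saveRDS(prior, path)
  invisible(path)
}

#' @rdname write_score_prior
#' @export
read_score_prior <- function(path) {
  p <- readRDS(path)
  if (!inherits(p, "score_prior")) stop("not a score prior checkpoint: ", path)
  p
}
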