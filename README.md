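# scorect

Iterative fan-beam CT reconstruction with a learned score-function prior.

## The problem

Low-dose and sparse-view CT protocols reduce patient exposure at the cost
of severe noise and streaking in classical filtered backprojection (FBP)
reconstructions. Model-based iterative reconstruction fixes this by
combining the physics of the measurement with an image prior — but the
prior has to come from somewhere. Hand-crafted priors such as total
variation over-smooth textures; `scorect` instead learns the prior's
*score function* — the gradient of the log image density,
`s(mu) = grad log p(mu)` — from images alone, with no paired labels, and
plugs it into a MAP fixed-point iteration. The package is aimed at
researchers in tomographic image reconstruction who want a compact,
fully testable reference implementation of this approach together with
its classical baselines.

## The model

Photon counts are Poisson around the Beer–Lambert mean
`ybar_i = n0 exp(-(A mu)_i)`, with `A` the fan-beam system matrix. A
second-order expansion of the Poisson negative log-likelihood gives the
weighted least squares data term `(1/2) (A mu - b)' D (A mu - b)` with
`b_i = log(n0 / y_i)` and `D = diag(y_i)`. MAP estimation then iterates

```
mu[k+1] = mu[k] - omega * A' D (A mu[k] - b) + sigma * s(mu[k])
```

The score `s` is trained by denoising score matching under a
Gaussian-mixture corruption model: noise levels `sigma_j = 0.00 ... 0.10`
drawn with binomial(10, 1/2) weights, posterior noise-level
responsibilities `lambda(sigma, diff)` weighting the loss
`lambda * || s_theta(x~) + diff / sigma^2 ||^2`, whose minimizer is
exactly the mixture score
`-diff * sum_j lambda_j / sigma_j^2`. The network is a small residual
CNN (four residual blocks, 5x5 and 3x3 kernels, 32 filters; linear
output layer; ~190k parameters). Convergence of the iteration is
governed by the spectrum of `A' D A` and a Lipschitz bound `C` on the
score: the package validates the step sizes against the sufficient
conditions `0 < sigma < omega lambda_min / C` and
`sigma C / lambda_min < omega < (2 - sigma C) / lambda_max`, and
monitors the empirical contraction factor `q`.

The matched forward/backprojector pair (ray-driven Joseph
interpolation; the transpose scatters through identical weights) is
compiled code; FBP and TV-regularized MBIR are included as baselines,
plus synthetic ellipse phantoms, Poisson measurement simulation, and a
PSNR/SSIM comparison harness.

## Worked example

Simulate a low-dose few-view scan of a random phantom, reconstruct with
FBP and with a trained score prior, and compare:

```r
library(scorect)

geom  <- scan_geometry(595, 1085.6, 368, 2.5716, 120)  # 120-view fan beam
proj  <- projector(geom, 128)
truth <- random_phantom(3001, n = 128, pixel_size = proj$pixel_size)

li     <- forward_project(truth, proj)                  # line integrals
counts <- sample_counts(expected_counts(li, 1e5), seed = 77)
sys    <- linearize(counts, 1e5)                        # b, D

rec_fbp <- fbp(sinogram(sys$b, "line_integrals", geom), proj)

patches <- training_phantom_patches(seed = 1)           # synthetic corpus
prior   <- train_score(patches, binomial_noise_schedule(),
                       train_config(learning_rate = 1e-3, epochs = 6,
                                    batch_size = 8, seed = 1),
                       scale = attr(patches, "scale"))
rec_adsf <- adsf_reconstruct(sys, proj, prior,
                             adsf_config(sigma_prior = 2.5e-5 * prior$scale^2,
                                         max_iters = 25, validate = FALSE))

psnr(coef(rec_fbp),  truth)   # 26.87 dB
psnr(coef(rec_adsf), truth)   # 31.59 dB
summary(rec_adsf)
#> CT reconstruction -- adsf
#>   grid        : 128 x 128 at 2.775 mm
#>   attenuation : min 0, median 0.0006558, max 0.03469 mm^-1
#>   convergence : final step norm 0.00318, empirical contraction q = 0.984
```

On this phantom the desk-trained prior recovers close to 5 dB over FBP; the directional ordering
(score prior above FBP) is the claim the acceptance suite checks on a
20-phantom test set, mirroring the method's published comparison
protocol at desk scale.

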