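---
title: "Methods: simulating and removing EMI streak noise in OR-PAE B-scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and removing EMI streak noise in OR-PAE B-scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Optical-resolution photoacoustic endoscopy (OR-PAE) acquires one
radio-frequency A-line per angular position of a rotating probe. Stacking
A-lines over a full revolution gives a B-scan; stacking B-scans along a
pullback gives a C-scan volume, summarised as an en-face vasculature map by
radial maximum amplitude projection (RMAP). The acquisition electronics are
vulnerable to electromagnetic interference (EMI): a burst contaminates the
single A-line being digitised at that instant, and after envelope detection
it appears as a bright vertical *streak* confined to one image column. Many
bursts per revolution give the characteristic "rain" pattern, and the
corrupted columns propagate into the RMAP as radial spokes that mask
vasculature.

Streaks are structured, not i.i.d.: they are column-aligned, high-amplitude
and piecewise-contiguous in depth. Generic smoothing (median, Gaussian)
attacks them only by blurring everything; a detector tuned to the column
structure does better but cannot distinguish a streak from a genuine
one-column-wide vessel cross-section. The package therefore implements the
full comparison: a paired-data simulator, four convolutional
encoder-decoder regressors trained to map streaked B-scans to clean ones,
classical baselines, and metrics.

# Data model

## Geometry and signal chain

The full-scale protocol uses 400-sample A-lines at 800 angles per B-scan
(one column per angle, columns circular over 360 degrees), a 40 MHz
acoustic carrier sampled at 200 MHz. Raw bipolar A-lines are converted to
envelopes by the Hilbert transform (`envelopeDetect`), then cropped to the
upper 304 rows (`cropUpper`), the depth range containing the lumen wall and
vasculature, giving the network input size 304 x 800.

`envelopeDetect` computes `Mod(x + i H[x])` per column with an FFT-based
Hilbert transformer. The identity `envelope(A sin(wt)) = A` is exact only
for narrowband signals; the unit tests pin a 2 % relative-error bound on
pure tones away from the boundary. On broadband content (discs with sharp
edges, Rayleigh-distributed thermal noise) the analytic envelope is *not*
a small perturbation of the magnitude — the tests document this rather than
assert a bound that the mathematics does not grant.

## Phantom generator

`generatePhantom` draws a synthetic cross-section: a bright circular lumen
wall band (with angular intensity modulation so that SSIM has structure to
measure), randomly placed vessel discs of varying radius and amplitude, and
Rayleigh thermal background noise of scale `thermalSigma` (the envelope of
complex Gaussian noise is Rayleigh, mean `sigma * sqrt(pi/2)` — this is the
oracle for `estimateThermalLevel`). `generateVolume` adds slice-to-slice
continuity so vessels persist across B-scans and the RMAP shows connected
vasculature. All sampling is seed-driven through `withSeed`/`childSeed`
(an LCG-derived stream splitter keeping every derived seed below 2^31).

## Streak injector

`sampleStreaks` draws per-image streak counts, column positions, depth
starts, lengths and amplitudes from a `NoiseConfig`; `injectStreaks` adds
each streak's amplitude to its one-column footprint and saturates at the
dynamic range (255). Injection is strictly additive and saturating:
outside footprints the noisy image is bit-identical to the clean one, and
never falls below it — properties the unit tests assert exactly. The
full-scale configuration uses 100-400 streaks per 800-column B-scan.

# Networks

Four fully convolutional encoder-decoder architectures are provided as
regression networks (single-channel linear head, no softmax):

* **U-Net** — strided copies of the encoder feature maps are concatenated
  into the decoder at every level; upsampling by learned 2 x 2 transposed
  convolutions.
* **SegNet** — batch normalisation after every convolution; upsampling by
  max-*unpooling* using the argmax indices recorded by the matching
  encoder pooling layer.
* **FCN-16s / FCN-8s** — a convolutional encoder whose upsampled output is
  *added* to one (16s) or two (8s) earlier encoder taps.

At full scale the U-Net has encoder channels 64 -> 1024 over four poolings,
with feature maps 304 x 800 at level 0 and 19 x 50 x 1024 at the bottleneck
(`architectureSummary` reproduces these numbers). Because no deep-learning
framework is assumed, the networks run on a small static-DAG engine
(`R/nn-graph.R`) with Armadillo im2col convolution kernels; every op has a
hand-derived backward pass.

## Numerical design decisions

Three engine-level findings shaped the tests:

1. **ReLU kinks at initialisation.** Convolution biases initialise to
   zero, and SegNet decoders see *sparse* unpool maps, so a fresh model has
   many pre-activations exactly at 0 — the ReLU kink, where the one-sided
   analytic subgradient and a central finite difference legitimately
   disagree. Gradient checks therefore jitter all parameters by
   `N(0, 0.05)` to a generic point first; after that, analytic gradients
   match finite differences to better than 1e-3 (typically 1e-5) for all
   four architectures. This is a property of nondifferentiable
   activations, not an engine defect.
2. **Batch-norm train/inference split.** The backward pass must match the
   forward branch actually taken: the training branch backpropagates
   through the batch statistics, the inference branch treats the running
   statistics as constants. The cache records which branch ran.
3. **Loss and regulariser.** Training minimises the half-MSE data term
   `(1/K) * sum_k 0.5 * sum (y - x)^2` plus `lambda * sum w^2` over
   convolution weights only (not biases, not BN scale/shift), so the
   weight gradient picks up `+ 2 lambda w`.

## Training

`trainModel` uses Adam (beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
bias-corrected), batch size 1, and a step learning-rate schedule
`lr * 0.3^floor(epoch / 10)`. Validation RMSE is evaluated every 50
iterations and the best-validation checkpoint's weights are returned, so a
late divergence cannot destroy a good model.

# Desk-scale study sizes

Training the full 304 x 800 networks is far outside an interactive R
session, so the package defines a *desk scale* as its own study size:
96 x 160 phantoms, a 3-level U-Net with 8 base channels, 100 clean/noisy
pairs split 80/20, 10 epochs (`deskPhantomConfig`, `deskNoiseConfig`,
`deskArchitectureSpec`, `deskTrainConfig`, `deskDataset`). The
architecture-comparison experiment uses an even smaller 64 x 96 / 26-pair /
4-epoch setting so that all four architectures can be trained at three
seeds each. These sizes are the package's choices for a self-contained,
reproducible study; the full-scale configuration remains available through
the non-`desk` constructors.

```{r desk-example}
library(paedenoise)
pairs <- deskDataset(100, seed = 20240101L)
split <- splitDataset(100, 0.8, seed = 20240102L)
model <- buildModel(deskArchitectureSpec("unet"), seed = 20240103L)
fit <- trainModel(model, pairs[split@train], pairs[split@val],
                  deskTrainConfig(seed = 20240104L))
fit$history$bestValRMSE
```

# Classical baselines and their limits

`gradientDetect` flags a pixel when it exceeds *both* circular transverse
neighbours by `factor * thermalLevel`; `replaceFlagged` substitutes the
minimum of the two neighbours; `gradientDenoise` composes them. Two
limitations are deliberate test subjects rather than hidden:

* **Vessel confusion.** A genuine one-column vessel cross-section
  satisfies the same gradient condition as a streak and is flagged — the
  structural reason a learned denoiser is worth its cost.
* **Adjacent-column masking.** If two streaks occupy neighbouring columns
  over the same rows, neither pixel exceeds its (also elevated) neighbour,
  so the rule cannot flag them *by construction*. At 60 streaks on 200
  columns this costs 5-8 % recall. Detector *power* is therefore measured
  on column-isolated streaks (recall 1.0), with the masking effect
  documented separately.

# Metrics

`rmse`, `mae` and `ssim` operate on matched matrices. SSIM is the global
(single-window) statistic with population (1/N) moments,
`c1 = (0.01 L)^2`, `c2 = (0.03 L)^2`, dynamic range L = 255 by default;
a windowed mode is available via `metricsConfig`. Negative SSIM is
reported raw with a warning, never clipped. `sweepNoiseLevels` evaluates a
denoiser across images and streak counts with per-row error capture, and
`errorMap` averages multiple outputs before differencing.

# File formats

All artefacts are text or standard formats: B-scans as 16-bit TIFF with a
YAML sidecar recording the affine normalisation (`writeBScanTIFF` maps
`(x - offset) / scale` into [0, 1] because TIFF float storage clamps that
interval; round-trips are exact to 16-bit quantisation), models as a YAML
architecture spec plus CSV parameter/state tables, streak lists and metric
reports as CSV, configurations as tagged YAML.

# Reproducing the study

`scripts/acceptance.R` runs the whole pipeline — structural constants,
metric hand cases, simulator oracles, the desk-scale U-Net training
experiment, volume denoising with RMAP comparison, and the classical
detector analysis — from a single `--seed`, writing a flat JSON report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
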