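---
title: "Simulation-trained probabilistic localization for high-concentration ULM"
author: "ulmloc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulation-trained probabilistic localization for high-concentration ULM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Ultrasound localization microscopy (ULM) reaches roughly ten-fold
super-resolution by localizing individual microbubbles (MBs) — intravenously
injected contrast agents that act as point scatterers — over thousands of
frames and accumulating their positions into a vascular map. The method
faces a concentration trade-off: few bubbles per frame keep their
point-spread signatures isolated and easy to localize but require very long
acquisitions to fill the vasculature, while high concentrations overlap
signatures and break conventional template-matching localization. This
package implements, entirely on synthetic data with known ground truth, a
pipeline designed for the high-concentration regime: a realistic MB
simulator, a probabilistic context-aware localization network, a
conventional normalized-cross-correlation (NCC) baseline, tracking,
super-resolved reconstruction including functional activation mapping, and
the benchmark machinery to compare localizers.

## The simulator defines the study conditions

`simulateSequence()` chains three stages, each of which mirrors how bubbles
behave in contrast-enhanced acquisitions.

**Kinematics.** Bubble counts per frame are Poisson with mean
`concentration x FOV area`, with the areal concentration expressed in
bubbles per squared wavelength (MBs/λ²) so that it transfers across imaging
frequencies. Initial positions are uniform in the field of view; speeds are
uniform in 5–25 mm/s; lifetimes are uniform on 1–20 frames; headings are
uniform on the unit circle. At every frame the heading is perturbed by a
2-vector of independent N(0, 0.2²) components and renormalized — a
first-order model of tortuous flow. Expired bubbles and bubbles leaving the
FOV are replaced by fresh draws so the expected density is stationary; the
replacement policy is our choice (the behaviour after bubble death is
otherwise unspecified) and keeps per-frame counts exactly constant within a
sequence, which the tests exploit.

**Appearance.** Each bubble carries one template from a `TemplateBank` for
its whole lifetime (temporal coherence a temporal-context network can
exploit) and a brightness drawn once from N(μ_Imax, σ_Imax), the statistics
recorded by the bank. Banks come from three sources: parametric bivariate
Gaussians (`gaussianTemplateBank()`), patches extracted around detected
peaks in real-style stacks (`extractTemplates()`, 65-pixel patches whose
detected peak defines the centre), or samples from a least-squares GAN
(`trainLSGAN()` / `sampleTemplates()`) trained on extracted patches.
Rendering stamps the peak-normalized template at the continuous position by
bilinear shifting (mathematically equivalent to convolving a bilinear delta
image with the template, but far cheaper), sums overlaps, and block-averages
the fine grid by 2 into the network input grid: the default bench
configuration renders 80×80 fine pixels of 12.3 μm and feeds the network
40×40 frames.

**Noise.** B-mode magnitudes with additive complex Gaussian electronics
noise are Rician distributed; `addRicianNoise()` implements exactly that
construction, and `estimateSigma()` recovers the per-pixel noise scale from
noise-only recordings through the Rayleigh mean relation
σ̂ = √(2/π)·mean_t E(x,z,t). The density function `ricianPDF()` uses the
standard Rician form with σ² in the leading denominator; the sampling
construction determines this form uniquely, and the test suite enforces
sampler/density agreement by χ² goodness of fit. When no noise recording is
supplied, a constant σ equal to 10% of μ_Imax is the documented
synthetic-data convention.

What the generator deliberately does **not** emulate: vascular-graph
constrained flow, RF/channel-domain physics (nonlinear propagation,
aberration, reverberation), tissue clutter, or correlated electronic noise.
Benchmarks passed on this synthetic data therefore demonstrate correctness
of the estimation machinery under the stated generative model, not in vivo
image quality.

## The localization network

`buildDecodeNetwork()` follows the two-stage design of probabilistic
single-emitter localization networks: a frame-analysis U-Net applied to each
of three consecutive frames, then a temporal-context U-Net over the
concatenated features, producing nine channels for the centre frame: the
detection probability `p` (per-pixel Bernoulli field), sub-pixel offsets in
(−0.5, 0.5) pixels, brightness, their three uncertainties, and a background
mean and uncertainty. Each U-Net has two pooling levels with 3×3
convolutions, ELU activations, and channel widths (f, 2f, 4f); the reference
width is f = 48 (≈2.3 M parameters), while the desk-scale studies in this
package use f = 8 so that the full training protocol runs on one CPU in
minutes. Whether the three frame stems share weights is genuinely open;
both modes are implemented (`sharedStem`), with sharing the default since
the per-frame feature extraction task is identical.

The training loss is the sum of two terms, with the background term
identically zero because background noise is modelled separately by the
simulator:

* **Count loss.** The predicted count is Poisson-binomial over the pixel
  probabilities; with many pixels it is approximated by a Gaussian with
  μ = Σp and σ² = Σp(1−p), giving the negative log-likelihood
  ½(E−μ)²/σ² + log(√(2π)σ) for the true count E. The variance is floored at
  1e-6 so saturated maps stay finite.
* **Localization loss.** Every pixel contributes a 3-D diagonal-Gaussian
  mixture component over (row, col, brightness), weighted by p_k/Σp, with
  mean (pixel centre + offsets, predicted brightness) and the predicted
  variances. The loss is the negative mean log-likelihood of the ground
  truth bubbles, computed with log-sum-exp. Frames with no bubbles
  contribute the count term only, since the mixture likelihood is undefined
  at E = 0.

Both terms have analytic gradients that the test suite checks against
numerical differentiation and against naive scalar reimplementations. The
engine itself — im2col-free per-tap GEMM convolutions, max pooling, nearest
upsampling, Adam — is written in the package (R + RcppArmadillo) and
gradient-checked end to end.

Training (`trainDecode()`) simulates every three-frame window freshly, so no
sample is ever reused; each window draws its concentration uniformly from
0.02–0.40 MBs/λ² so one model serves the whole benchmark sweep. Defaults:
Adam at 6e-4 halved when the epoch loss stops improving, batch 16, global
gradient-norm clip. The desk profile trains 5 epochs × 2000 windows of
40×40 frames; the reference regime would use 10,000 frames per epoch.

Inference (`decodeInfer()`) slides the three-frame window over a stack
(interior frames only). `decodeDetections()` turns a probability map into
discrete localizations — a rule the underlying method leaves open; ours
aggregates the Bernoulli field by summing p over a (2r+1)² neighbourhood
(r = 1), accepts local maxima whose aggregated mass reaches 0.6, places the
localization at pixel centre plus predicted offset, and finally discards the
5% of detections with the largest positional uncertainty
√(σ_row² + σ_col²), honouring the idea that the network's own uncertainty
flags unreliable localizations. All three constants are configuration, not
claims.

## Baseline, tracking, reconstruction

The conventional baseline (`nccLocalize()`) computes zero-normalized
cross-correlation against a bivariate Gaussian template (border policy:
fill −1), takes strict regional maxima above 0.6 with greedy suppression
within 3 px (higher peak wins, ties row-major), and refines to sub-pixel
precision by the vertex of a least-squares paraboloid on the 3×3
correlation neighbourhood, clamped to ±0.5 px (a 5×5 intensity centroid is
the alternative). On isolated noise-free bubbles this baseline is accurate
to better than 0.25 fine px RMSE — its failure mode is overlap, not
precision.

Tracking is a two-step linear assignment: frame-to-frame linking by
minimum-total-distance optimal assignment gated at 1.5× the fastest
expected per-frame displacement, then segment joining across gaps of up to
2 frames with distance ≤ gate × gap and a 45° angle gate between the
segment's terminal velocity (displacement over its last ≤3 steps) and the
joining displacement; joined tracks below 10 frames of span are discarded.
The full uTrack cost model (birth/death costs, motion models) is
deliberately replaced by this simplest optimal-assignment scheme honouring
the persistence and angle rules. The solver is a Jonker-Volgenant shortest
augmenting path implementation in `src/lap.cpp`, tested against brute-force
enumeration.

Reconstruction rounds localizations to a λ/10 grid and bins them into λ/5
pixels (at 15.625 MHz: λ = 98.56 μm, λ/2 = 49.28 μm, λ/5 = 19.712 μm,
λ/10 = 9.856 μm). Density maps count track points; directional maps sign
each point by the axial component of the local track velocity, with motion
toward the transducer (decreasing row) positive — a convention stated once
and used everywhere. For functional analysis, `mbCountSeries()` counts
*distinct tracks* per pixel per one-second window (a lingering track counts
once), and `activationMap()` correlates each pixel series with the
stimulation pattern over the analysis mask — stimulation seconds and stable
rest seconds only, the 10-second transitions excluded — calling r > 0.2
activated. The count series live on the λ/5 reconstruction grid (the text
leaves λ/5 vs λ/10 open; we use the coarser reconstruction grid, which
favours non-empty counts).

## Benchmarks and their numerical conventions

`matchLocalizations()` pairs predictions with ground truth by optimal (not
greedy) gated assignment — greedy matching inflates accuracy at high
density — with the gate at 0.32λ (≈2 fine px at the bench configuration;
`matchRadiusPx()` converts). Detection accuracy is TP/(TP+FP), miss rate
FN/(TP+FN), and the localization error is the averaged root mean-squared
distance with the per-pair division by two inside the root, exactly as the
benchmark defines it. `benchmarkSweep()` aggregates per frame and reports
mean ± SD over frames, mirroring the protocol of 500 frames per
concentration from 0.02 to 0.37 MBs/λ² in steps of 0.02 (18 sets); the
desk-scale runs use fewer frames, stated where they are used.

## Numerical and degenerate-input choices

* Variance floor 1e-6 in the count loss; σ floors of 0.01 px via
  softplus + floor on all uncertainty channels.
* Offsets squashed by tanh/2 into (−0.5, 0.5); probabilities by the
  logistic.
* Zero-probability mixture components receive zero weight and vanish from
  the localization loss; an all-zero probability map is an error.
* A direction vector that perturbs to the zero vector keeps its previous
  heading (probability ~0 event).
* Constant stacks are rejected by 0–1 normalization (degenerate range);
  thresholding keeps the boundary value (strict <).
* Assignment ties are broken by index order; peak ties row-major.
* The LSGAN generator works on the next multiple of 4 above the template
  side and centre-crops; its softplus output head opens from a dark
  background (bias −3) because templates are sparse. The discriminator
  learning rate defaults to a quarter of the generator's: on small template
  sets an evenly paced discriminator wins early and starves the generator
  of gradient. Generated patches are clamped at zero and renormalized to
  unit peak before banking; brightness statistics are copied from the
  training bank because brightness is modelled separately.
* All stochastic stages derive their seeds from one master seed and a stage
  tag (`deriveSeed()`), so stages can be re-run independently without
  perturbing each other.

## Problem sizes used by the shipped studies

The packaged tests and the acceptance script run everything at desk scale,
chosen so the whole suite completes on a single CPU: 80×80 fine grids
(40×40 network input), a 50-template Gaussian bank, noise σ = 0.1 μ_Imax,
training 5 epochs × 2000 freshly simulated windows at f = 8, evaluation on
200 held-out frames at 0.05 and 0.30 MBs/λ², NCC benchmarking on the same
frames, 50-frame tracking sequences, and 15-cycle functional protocols with
Poisson count series. The GAN module test trains on 200 isotropic σ = 2
Gaussian templates of side 21 for 150 epochs with latent dimension 16.
These sizes are the package's own desk-scale study conditions; the
reference-scale settings (65-pixel templates, latent 64, f = 48, 10,000
frames/epoch, 500-frame benchmarks) remain the documented defaults of the
corresponding functions.

## Known limitations

* The simulator's realism gap (no vascular structure, no clutter) means
  detection metrics here bound the method's behaviour under the generative
  model only.
* The desk-scale network (f = 8) underfits relative to the reference width;
  its benchmark numbers demonstrate the expected *direction* of the
  comparison against NCC (higher accuracy, lower miss at high
  concentration), not the reference-scale magnitudes.
* The LSGAN at desk scale learns first-order template statistics (width,
  eccentricity within the training bank's spread); it is not a
  high-fidelity generative model of in vivo point-spread functions at this
  size, and mode-collapse diagnostics beyond the moment check are out of
  scope.
* Tracking has no motion model and no merge/split handling; crossing
  vessels with similar speeds can swap identities at the crossing point.
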