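# ulmloc

Simulation, probabilistic deep localization, tracking and reconstruction for
super-resolution **ultrasound localization microscopy (ULM)** at high
microbubble concentrations.

ULM localizes intravenously injected microbubbles (MBs) — point scatterers
circulating in the bloodstream — over thousands of ultrasound frames and
accumulates their sub-wavelength positions into microvascular maps roughly
ten-fold beyond the diffraction limit. The method's bottleneck is a
concentration trade-off: sparse bubbles are easy to localize but fill
vessels slowly; dense bubbles overlap and defeat conventional
template-matching localization. `ulmloc` implements a complete pipeline for
studying this regime on synthetic data with known ground truth:

* **Simulator** — stochastic bubble flow (counts Poisson in
  concentration × FOV area, speeds U(5, 25) mm/s, lifetimes U{1..20}
  frames, heading perturbed by N(0, 0.2²) per step), per-bubble brightness
  N(μ_Imax, σ_Imax), sub-pixel template rendering on a fine grid with ×2
  block-averaging, and Rician background noise
  (σ̂ = √(2/π)·mean_t E(x,z,t) from noise-only recordings).
* **Template banks** — parametric bivariate Gaussians, patches extracted
  around detected peaks, or samples from a least-squares GAN trained on
  such patches (`trainLSGAN`, discriminator loss
  ½E[(D(x)−1)²] + ½E[D(G(z))²], generator loss ½E[(D(G(z))−1)²]).
* **Probabilistic localization network** — a frame-analysis U-Net over
  three consecutive frames plus a temporal-context U-Net, emitting per-pixel
  detection probability `p`, sub-pixel offsets, brightness and
  uncertainties. Trained with the joint count loss
  ½(E−μ)²/σ² + log(√(2π)σ), μ = Σp, σ² = Σp(1−p), and a Gaussian-mixture
  localization loss −(1/E) Σ_e log Σ_k (p_k/Σp) N₃(u_e; μ_k, Σ_k) over
  (row, col, brightness). Implemented with the package's own
  gradient-checked conv-net engine (RcppArmadillo GEMM kernels + Adam).
* **Conventional baseline** — zero-normalized cross-correlation against a
  Gaussian template, regional maximum search, paraboloid sub-pixel
  refinement.
* **Tracking** — two-step linear assignment (Jonker–Volgenant solver):
  frame-to-frame linking, gap closing ≤ 2 frames with a 45° linking-angle
  gate, 10-frame minimum persistence.
* **Reconstruction** — λ/10 rounding, λ/5 accumulation grids, directional
  flow maps, per-pixel MB-count series, and functional activation maps
  (Pearson r of count series against a stimulation pattern; r > 0.2 is
  activated).
* **Metrics** — optimal gated matching (radius 0.32λ), detection accuracy
  TP/(TP+FP), miss rate FN/(TP+FN), localization error
  √(mean((Δx²+Δy²)/2)), vessel filling %, concentration sweeps.

## Worked example

Simulate a labeled sequence, train the desk-scale localizer, and compare it
with the NCC baseline at a high bubble concentration:

```r
library(ulmloc)

cfg  <- imagingConfig()                      # 20 MHz, 12.3 um fine px, 80x80
bank <- gaussianTemplateBank(50, seed = deriveSeed(1, "bank"))
nm   <- noiseModel(0.1, c(40L, 40L))         # sigma = 0.1 mu_Imax

model <- trainDecode(cfg, bank, nm, epochs = 5, framesPerEpoch = 2000,
                     baseFilters = 8L, seed = 1)   # ~13 min on one CPU

sim <- simulateSequence(cfg, bank, nm, 202, concentration = 0.30,
                        seed = deriveSeed(1, "eval-hi"))
det <- decodeLocalize(model, sim$stack)      # network localizations
ncc <- nccLocalize(sim$stack)                # conventional baseline

radius <- matchRadiusPx(cfg)                 # 0.32 lambda ~ 2.0 fine px
t <- 100
m1 <- matchLocalizations(det[det$frame == t, ], sim$gt[sim$gt$frame == t, ], radius)
m2 <- matchLocalizations(ncc[ncc$frame == t, ], sim$gt[sim$gt$frame == t, ], radius)
c(decode = missRate(m1), ncc = missRate(m2))
```

Averaged over 200 held-out frames, the same protocol (seed 1, as run by
`scripts/acceptance.R`) prints:

```
decode_accuracy_pct_low_density            99.875
decode_miss_pct_low_density                  14.4
decode_loc_error_um_low_density           3.48
ncc_miss_pct_low_density                     24.5
decode_miss_pct_high_density              39.2
ncc_miss_pct_high_density                  68.1
```

i.e. at 0.05 MBs/λ² the network localizes essentially every detection
correctly (99.9% accuracy) while missing 14% of (mostly dim) bubbles with a
3.5 μm localization error, and at 0.30 MBs/λ² it misses 39% of bubbles
where conventional NCC localization misses 68% — the overlap regime the
probabilistic network is built for.
Tracking and reconstruction then turn localizations into maps:

```r
trk  <- trackLocalizations(det, cfg)         # 45-degree gate, 10-frame persistence
dens <- accumulateDensity(trk, cfg)          # lambda/5 super-resolved counts
```

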