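---
title: "Multi-stage artifact reduction for parallel-beam CT: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-stage artifact reduction for parallel-beam CT: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mstar)
```

## The problem

Synchrotron and laboratory parallel-beam CT pipelines process data in three
representations: projection images (one per rotation angle), sinograms (one
per detector row, collecting that row across all angles), and reconstructed
slices.  Acquisition artifacts enter in the projection domain and propagate:

* **Poisson noise** — photon-counting statistics; local in every domain.
* **Ring artifacts** — systematic per-detector-pixel offsets; identical in
  every projection, hence straight stripes in sinograms and concentric arcs
  in reconstructions.  Non-local in the reconstruction domain.
* **Zingers** — isolated saturated pixels from high-energy photon hits;
  point-like in one projection, crossing streaks after reconstruction.

A network applied only to reconstructed slices sees ring and zinger
artifacts as large non-local structures and handles them poorly.  `mstar`
instead trains one small 2D network per domain and chains them, so each
artifact is reduced where it is still local, with *bypass connections*
giving every stage access to the raw data as well as the previous stages'
outputs.  Formally, with corrupted projections $\tilde p = p + n$ and a
linear reconstruction operator, $\mathrm{recon}(\tilde p) = r + \tilde n$:
artifact terms survive the pipeline additively (this superposition is
asserted literally in the test suite), which motivates attacking $n$ before
it spreads.

## Pipeline definition

Let $\mathcal{R}$ denote the lossless rearrangement between projection and
sinogram stacks ($s[m, a, n] = p[a, m, n]$), $U_k$ linear angle-upsampling
by factor $k$, and $\mathrm{fbp}$ filtered back projection.  With stage
networks $f_p$, $f_s$, $f_r$:

1. **Projection stage** — $\hat p_i = f_p(\tilde p_i)$ per projection
   (1 input channel).
2. **Sinogram stage** — per detector row, the 2-channel input
   $[U_k\mathcal{R}\tilde p,\; U_k\mathcal{R}\hat p]$ yields $\hat s$ at
   the high-quality angle count (2 input channels).
3. **Reconstruction stage** — per slice, the 3-channel input
   $[\mathrm{fbp}(U_k\mathcal{R}\tilde p),\;
     \mathrm{fbp}(U_k\mathcal{R}\hat p),\; \mathrm{fbp}(\hat s)]$
   yields the final $\hat r$ (3 input channels).

The no-bypass ablation drops the raw channels (all stages have 1 input
channel).  Both upsampled stage-2 channels and both raw-derived stage-3
reconstructions share the high-quality angle grid; upsampling *before* the
sinogram network lets that network also correct interpolation error, and
reconstructing the stage-3 raw channel from the upsampled sinogram keeps
all three channels on one grid.  The alternative (refine at native angles,
upsample afterwards) was considered and rejected because it denies the
sinogram network any chance to repair interpolation artifacts.

## Stage networks

Every stage uses a width-1 mixed-scale dense (MS-D) network: `depth`
dilated 3×3 convolutions, layer $i$ consuming the concatenation of the
input and all previous layer outputs with dilation $((i-1) \bmod 10) + 1$,
ReLU activations, reflection padding, and a final 1×1 linear layer over all
channels.  The parameter count is exactly
$\sum_{i=1}^{d} \left[9\,(c_{\mathrm{in}} + i - 1) + 1\right]
 + (c_{\mathrm{in}} + d)\,c_{\mathrm{out}} + c_{\mathrm{out}}$:

```{r}
sapply(1:3, function(c_in) msd_count_params(msd_spec(c_in, depth = 100L)))
msd_count_params(msd_spec(1L, depth = 180L))
```

45652 / 46553 / 47454 parameters for the three depth-100 stages (139659
total) and 146972 for the depth-180 single-network post-processing
baseline with matched capacity.  Dilation choice does not affect the
count.  Design details the architecture leaves open were fixed as follows:
reflection padding (preserves spatial size without biasing borders toward
zero); He-normal initialization of the dense layers with a zero final
layer, so the initial prediction is the normalized-target mean; per-stage
input/output normalization constants computed from the training split and
stored in the checkpoint.  Forward and backward passes are implemented in
compiled code with exact gradients (verified against finite differences).

## Training procedure

Training is sequential and supervised, never end-to-end: stage 1 is
trained and frozen, its best-validation checkpoint builds the stage-2
pairs, and so on.  No gradient crosses a stage boundary, which keeps the
memory footprint at one 2D image per step regardless of volume size.

Pairs come from one corrupted low-quality scan ($N_a$ angles) and one
clean high-quality scan ($k N_a$ angles) of the same object, with
low-quality angle $i$ coinciding with high-quality angle $ik$ so targets
can be selected directly.  Defaults follow the benchmark protocol: ADAM,
initial learning rate $10^{-3}$, mean-squared-error loss, epoch budgets
(200, 200, 500) — the reconstruction stage trains longest because
reconstructed images carry the most complex features — and early stopping
after 10 epochs without validation improvement.  Choices the protocol
leaves open: validation split of 10% of images per stage (fixed per seed,
disjoint from training); "best model" means lowest validation loss; inputs
for later stages are computed with the best (not final) earlier
checkpoints; whole-image training without augmentation; an open-ended
wall-clock cap is exposed as a configurable `max_seconds`.

## Synthetic data: what it emulates and what it does not

The generator builds cylindrical foam phantoms — non-overlapping
zero-attenuation spherical bubbles (centers uniform in the cylinder, radii
log-uniform, rejection sampling with at most $1000\,n$ candidate draws) in
a material of $\mu = 1$ — and scans them with a slice-wise parallel-beam
geometry: detector width equals slice width, rotation about the slice
center over $[0, \pi)$, linear interpolation, no magnification.  The
full-scale object is a 512-voxel cube with 100000 bubbles scanned at
1024 angles (256 for the low-quality variant); `scaled_foam_spec()`
produces desk-scale variants that keep the bubble volume fraction near
0.16 with radii a fixed fraction (2–8%) of the grid size, since neither
the bubble-size law nor the material attenuation is pinned down by the
benchmark description.

Corruption follows the acquisition physics in a fixed order:

1. **Absorption calibration** — a single global scale $c$ solved by
   bisection so the mean absorbed fraction $1 - e^{-c p}$ over
   object-intersecting rays equals $\gamma$ (0.5: "about half the photons
   absorbed" is interpreted as exactly one half).
2. **Poisson noise** — counts $k \sim \mathrm{Poisson}(I_0 e^{-p})$,
   clipped below at 1 (the description is silent on zero counts; the clip
   makes the re-log finite), then $p' = -\log(k / I_0)$.  A Gaussian
   approximation replaces the Poisson draw above $10^7$ expected counts.
3. **Ring offsets** — exactly $\mathrm{round}(P_{\mathrm{ring}} M N)$
   detector pixels (drawn without replacement) receive fixed
   $\mathcal{N}(0, \sigma_{\mathrm{ring}}^2)$ offsets, $\sigma_{\mathrm{ring}}
   = 0.005$, added identically to every projection.
4. **Zingers** — exactly $\mathrm{round}(P_{\mathrm{proj}} N_a)$
   projections get $\mathrm{round}(P_{\mathrm{zinger}} M N)$ pixels
   overwritten with $v = 5$, modelling detector saturation (overwriting,
   not adding, and applied last for the same reason).

Exact counts (rather than per-pixel Bernoulli draws) make corruption
statistics assertable; "percentage of affected pixels" is read as a fixed
fraction, and all $P_\ast$ parameters are fractions (0.1 means 10%) — the
benchmark tables pair $P_{\mathrm{ring}} = 0.1$ with $P_{\mathrm{zinger}} =
0.001$, which only makes sense on a common fractional scale.  Ring and
zinger corruption operate in the post-log attenuation domain (offsets are
added directly to projection images, and $v = 5$ matches attenuation-scale
values); Poisson noise operates in the photon-count domain.  Whether ring
offsets precede or follow Poisson noise is not specified by the benchmark;
noise-then-ring is the default and the steps can be toggled individually.

What the phantom does *not* emulate: multi-material objects, detector
point-spread, beam hardening, phase contrast, flat-field structure of real
detectors, or cone-beam geometry.  Passing tests on this generator
demonstrate that the pipeline removes the modelled artifact classes from
single-material objects; they say nothing about generalization to real
detector physics or across specimens.

## Numerical choices

* **FBP** — Ram-Lak (ramp) filter applied in Fourier space via the
  standard band-limited spatial-domain construction, zero-padded to the
  next power of two at least twice the detector width; linear
  interpolation in back projection; output scaled by $\pi / (2 N_a)$ so
  round-trip amplitude is preserved (a 128-voxel disk round-trips with
  relative RMSE < 0.05, matching reference implementations); no circular
  mask.  The filter window is not specified by the benchmark — absolute
  corrupted-baseline PSNR depends mildly on it.
* **Angle upsampling** — linear interpolation on $[0, \pi)$, wrap-aware at
  the boundary through $s(\theta + \pi, n) = s(\theta, N - 1 - n)$.
* **Wavelet-Fourier ring filter** — periodized orthogonal multilevel 2D
  DWT (standard sym5/db2/haar analysis filters hardcoded; perfect
  reconstruction verified to machine precision).  At each level the band
  that is lowpass along the angle axis and highpass along the detector
  axis is Fourier-transformed along the angle axis and damped by
  $g(k) = 1 - e^{-k^2 / 2\sigma^2}$; $\sigma = 0$ is treated as the limit
  that removes only the exactly angle-constant component.  Sinograms are
  reflect-padded to multiples of $2^{\mathrm{level}}$ and cropped back.
* **Median zinger filter** — one-sided detection (only pixels *above*
  their local median by more than `dif` are replaced), matching the
  saturation mechanism.
* **SSIM** — 11×11 Gaussian window, $\sigma = 1.5$, $C_1 = (0.01 R)^2$,
  $C_2 = (0.03 R)^2$, averaged over the fully windowed region, with the
  *global* reference-volume range $R$ as `data_range` (reading "the
  reference data's range" as the volume's range, not per-slice).  A
  uniform 7×7 window — a common software default whose choice moves
  scores in the third decimal — is available as a documented switch.
* **Ring geometry under 180°** — a constant offset at signed detector
  position $d$ backprojects to a *half*-arc of radius $|d|$ (its tangent
  points sweep only the half-circle matching the sign of $d$), so
  concentricity checks are evaluated within the covered angular range.
* **Ties in the classical grid search** are broken by first occurrence in
  grid order; the full score table is returned.

## Problem sizes used in the shipped studies

The package's own test studies run at reduced scale so that the full
suite completes on one CPU core in minutes: the ablation study uses
64-voxel foams, 32 low-quality / 128 high-quality angles, depth-20
networks and epoch budgets (40, 40, 60); the corrupted-baseline and
classical-baseline studies use 128-voxel foams with 64 / 256 angles.
These sizes were chosen as the smallest at which the studied effects are
cleanly visible; `scripts/full_scale_baseline.R` contains the full-scale
(512-voxel, 100000-bubble, 256/1024-angle) corrupted-baseline protocol
for machines with hours of compute to spare.  At desk scale the absolute
PSNR/SSIM numbers of the full-scale benchmark are not reproducible — FBP
noise amplification and bubble feature sizes change with the grid — but
the orderings (degradation with decreasing $I_0$, improvement from
classical pre-processing, single-stage < multi-stage < multi-stage with
bypass) are, and those are what the tests assert.  Single-stage ablation
baselines reuse the depth-20 architecture rather than matching the
three-stage parameter total; at these image sizes capacity is not the
binding constraint.  Each single-stage pipeline replaces exactly one stage
with a network and leaves the rest classical: since angle upsampling is a
sinogram-stage operation, the projection-only and reconstruction-only
pipelines reconstruct at the native low-quality angle count (as the
corrupted baseline does), and only pipelines that include sinogram
processing work on the upsampled grid.

## Known limitations

* Parallel-beam, equally spaced angles on $[0, \pi)$ only; no fan- or
  cone-beam geometry, no iterative reconstruction.
* Networks are instantiated with one output channel; the parameter-count
  formula is general.
* Training is CPU-bound and single-threaded; paper-scale training (depth
  100 at 512³) is out of reach in this implementation and out of scope
  for its tests.
* The corrupted-baseline PSNR at full scale depends on FBP conventions
  (filter window, padding) at the ±1 dB level.

## A worked example

```{r, eval = FALSE}
art <- artifact_config(I0 = 30, P_ring = 0.1, P_zinger = 0.001, seed = 1L)
scan <- simulate_paired_scan(
  generate_foam_phantom(scaled_foam_spec(64L, seed = 1L)),
  n_angles_lq = 32L, factor = 4L, art)
models <- train_all(scan, cfg = training_config(epochs = c(40L, 40L, 60L)),
                    specs = lapply(1:3, function(c) msd_spec(c, 20L)))
test_scan <- simulate_paired_scan(
  generate_foam_phantom(scaled_foam_spec(64L, seed = 2L)),
  n_angles_lq = 32L, factor = 4L,
  artifact_config(I0 = 30, P_ring = 0.1, P_zinger = 0.001, seed = 2L))
enh <- enhance(test_scan$p_lq, models)
evaluate_volume(enh$r_hat, test_scan$r_hq)
```

The same protocol, including the no-bypass and single-stage ablations, is
exercised by `tests/testthat/test-acceptance.R` and, end to end with file
outputs and a manifest, by `run_experiment()`.
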