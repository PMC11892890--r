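# mstar — multi-stage artifact reduction for parallel-beam tomography

`mstar` is an R toolkit for simulating and removing acquisition artifacts
in parallel-beam X-ray CT.  It targets the three artifact classes that
dominate high-flux (synchrotron-style) scans — Poisson photon noise,
**ring artifacts** from miscalibrated detector pixels, and **zinger**
outliers from high-energy photon hits — and removes them with a chain of
three small 2D convolutional networks, one per data domain:

1. a **projection-stage** network cleans each projection image,
2. a **sinogram-stage** network cleans each detector row's sinogram
   (where ring artifacts are straight stripes) and upsamples the angle
   grid,
3. a **reconstruction-stage** network refines each reconstructed slice.

*Bypass connections* feed every stage both the raw data and all previous
stages' outputs, so one stage's mistakes cannot erase information
downstream.  The stages are trained sequentially and independently
(supervised, from one corrupted low-quality scan plus one clean
high-quality scan of the same object), never end-to-end, so memory use
stays at one 2D image per gradient step no matter how large the volume.

For whom: anyone who processes parallel-beam CT data and wants a
self-contained, seedable environment to study artifact-reduction
pipelines — the package needs no external data, since it generates its
own foam phantoms (a cylinder packed with non-overlapping spherical
bubbles) and simulates the full acquisition.

## The model in brief

A scan with detector rows $M$, columns $N$ and angles $N_a$ gives
corrupted projections $\tilde p = p + n$.  With the rearrangement
$\mathcal{R}$ ($s[m,a,n] = p[a,m,n]$), angle-upsampling $U_k$ and
filtered back projection, the enhanced reconstruction is

$$\hat p_i = f_p(\tilde p_i), \quad
  \hat s = f_s\!\left[U_k\mathcal{R}\tilde p,\ U_k\mathcal{R}\hat p\right], \quad
  \hat r = f_r\!\left[\mathrm{fbp}(U_k\mathcal{R}\tilde p),\
                      \mathrm{fbp}(U_k\mathcal{R}\hat p),\
                      \mathrm{fbp}(\hat s)\right].$$

Each $f$ is a width-1 mixed-scale dense network (dilated 3×3 dense
layers, cyclic dilations 1–10, final 1×1 layer): a depth-100 stage has
only 45652 / 46553 / 47454 trainable parameters for 1 / 2 / 3 input
channels.  Classical baselines (median-filter zinger removal and
Münch-style wavelet-Fourier ring suppression with an SSIM-maximizing grid
search) and PSNR/SSIM evaluation are included.

## A worked example

Train the scaled-down pipeline on one synthetic foam scan and evaluate on
a second, unseen phantom (about 4 minutes on one CPU core):

```r
library(mstar)

art  <- artifact_config(I0 = 30, P_ring = 0.1, P_zinger = 0.001, seed = 1L)
scan <- simulate_paired_scan(
  generate_foam_phantom(scaled_foam_spec(64L, seed = 1L)),
  n_angles_lq = 32L, factor = 4L, art)

models <- train_all(scan,
                    specs = lapply(1:3, function(c) msd_spec(c, depth = 20L)),
                    cfg = training_config(epochs = c(40L, 40L, 60L), seed = 1L))

test_scan <- simulate_paired_scan(
  generate_foam_phantom(scaled_foam_spec(64L, seed = 2L)),
  n_angles_lq = 32L, factor = 4L,
  artifact_config(I0 = 30, P_ring = 0.1, P_zinger = 0.001, seed = 2L))

evaluate_volume(fbp_reconstruct(rearrange(test_scan$p_lq)), test_scan$r_hq)
#> eval_report vs reference: mean PSNR -1.35 dB, mean SSIM 0.0389 (64 slices)

enh <- enhance(test_scan$p_lq, models)
evaluate_volume(enh$r_hat, test_scan$r_hq)
#> eval_report vs reference: mean PSNR 20.75 dB, mean SSIM 0.7248 (64 slices)
```

The corrupted 32-angle reconstruction is unusable (−1.4 dB against the
clean 128-angle reference: heavy noise at 30 photons/pixel plus rings and
zinger streaks); the three-stage chain lifts it to 20.7 dB / 0.72 SSIM.
Training the ablation variant with `bypass = FALSE` on the same seeds
lands lower, and single-stage models trail further — the ordering the
multi-stage design predicts, asserted quantitatively in the test suite.

A thin command-line wrapper with subcommands
`simulate | project | corrupt | reconstruct | baseline | enhance |
evaluate | experiment` is installed at `inst/cli/mstar`, and
`run_experiment()` drives the whole protocol (simulate → corrupt → train
→ enhance → evaluate) from one config, writing every artifact plus a
manifest.

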