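---
title: "Self-supervised blind-spot denoising of OCT B-scans: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-supervised blind-spot denoising of OCT B-scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(blindspot)
```

## The problem and the model

Optical coherence tomography B-scans are corrupted by speckle: a
multiplicative interference pattern that, after the logarithmic scaling
applied during reconstruction, becomes *additive* noise with approximately
zero mean. Writing a log-intensity pixel as

$$v = s + n, \qquad E(n) = 0,$$

a network trained to predict $v$ from its surroundings can only learn the
deterministic part $s$, because the zero-mean noise realization is
unpredictable — provided the network is given *no information about the
realization of $n$ at the pixel it predicts*. That is the blind-spot
principle: hide the pixel (and everything correlated with it), train with
the original value as target, and the regression optimum is the clean
signal.

In OCT the noise is not spatially white. The A-scan-wise acquisition and
the axial point-spread function correlate noise along depth, so hiding a
single pixel leaks information through its axial neighbors. The masking
scheme therefore hides a 7×1 *axial strip* around each sampled center:
long enough that, with an axial correlation length of about 1.5 px,
correlation beyond the strip is negligible.

### Structured masking with continuous replacement

During training, a fraction of 0.1% of patch pixels is sampled (without
replacement) as blind-spot centers; each center's 7×1 strip is overwritten
by the *continuous strip* found at a random offset, drawn uniformly from
the Chebyshev ball of radius 5 (offset zero allowed), with all reads from
the pristine input. Replacing with a coherent strip — rather than
independent random values — keeps the masked region locally plausible, so
the network cannot detect and ignore masked areas. The loss is the mean
squared error at the *center* pixels only, against the original values.

Two augmentations mirror acquisition variability: a lateral flip with
probability 1/2 (reversing the scan direction while preserving A-scan
structure), and a random remap of the nominal $[0,1]$ intensity range to
$[\max(0,\delta_{lo}),\, 1+\min(0,\delta_{hi})]$ with
$\delta \sim \mathcal N(0, 0.25)$ clipped to $[-1,1]$. Because a draw can
only move a bound inward, each bound stays untouched with probability 1/2
and the whole image with probability 1/4; this emulates different black
levels and dynamic-range scalings.

### The light-weight U-Net family

The denoiser is a depth-2 U-Net: encoder levels with $n$ and $2n$
channels, a bottleneck with $4n$, 2×2 max pooling down and 2×2 transposed
convolutions (stride 2) up. Each level applies size-preserving 3×3
convolutions followed by channel-wise batch normalization and ReLU; a
final 1×1 projection returns to one channel. Two switches define the
family: a global residual addition of the input (`r`), and the top-level
skip concatenation (`t`). Following the N2V2 observation that both paths
let high-frequency noise bypass the bottleneck and produce checkerboard
artifacts in blind-spot training, the recommended variant omits both
(U-Net^{¬r,¬t}); the package builds all four variants for comparison.

The convolution count per level is not fully determined by the published
figure; this implementation uses two 3×3 convolutions per encoder/decoder
level and **one** in the bottleneck. The choice is driven by the padding
contract: deployment pads buffers by 20 A-scans because the receptive
field must not exceed 41×41 px. Backward window arithmetic (verified
empirically by `measure_receptive_field()`, which perturbs an input pixel
and measures the changed-output footprint, maximized over weight draws,
signs and pooling alignments) gives 36 px for this layout and 44 px with a
second bottleneck convolution — so the single bottleneck convolution is
the layout consistent with the stated padding budget.

### Training regime

Full-scale training uses 300 epochs of 600 steps, batch 128 of 200×200
patches, Adam at $2\cdot10^{-5}$; the learning rate halves whenever the
validation loss has not strictly improved for 10 consecutive epochs
(`lr_scheduler()`), and the weights of the best validation epoch are
exported. The validation loss is made deterministic by tiling the
validation images and drawing mask plans from a fixed seed, so it is a
pure function of the weights.

The package ships a `"desk"` profile for CPU-scale experiments: 30 epochs
× 100 steps, batch 16, 64×64 patches. Its learning rate is $2\cdot10^{-3}$
rather than $2\cdot10^{-5}$: with Adam the step size is approximately the
learning rate itself, and compressing ~180k updates into 3k requires
steps larger by roughly the same factor for the optimization to converge
within the schedule — at this rate the validation loss plateaus and the
halving scheduler engages inside the 30 epochs, i.e. the short schedule
actually reaches its converged regime. All
reported desk-scale numbers use this profile with fixed seeds. Training
convolutions run in single precision (the standard training precision for
convolutional networks); a double-precision path backs the finite-
difference gradient tests.

## The synthetic phantom

No acquisitions are distributed with the package, so all tests run on
synthetic layered phantoms (`phantom_spec()`, `make_dataset()`) that
emulate the *statistics the method relies on*, not anatomy:

* piecewise-constant wavy layers (sums of sinusoids around ordered base
  depths, amplitudes bounded so boundaries never cross), a dim background
  above the first boundary, and a thin bright membrane — a cartoon of a
  layered retina in log scale;
* additive zero-mean Gaussian noise, obtained by circularly convolving a
  white field with a separable Gaussian kernel (axial σ_ax = 1.5 px,
  lateral σ_lat = 0), rescaled to marginal σ = 0.1 and mean-centered. The
  circular convolution keeps the field stationary, so its autocorrelation
  follows the closed form $\exp(-k^2/(4\sigma_{ax}^2))$, which the tests
  verify within sampling error. σ_ax = 1.5 px makes correlation negligible
  beyond ±3 px — the regime the 7×1 mask is designed for; A-scans are
  mutually independent, matching the axial-only masking.

Evaluation items additionally carry an `m`-frame average (mean of `m`
independent noise realizations of the same clean image) standing in for
registered-and-averaged ground truth, plus 14 foreground and one
background ROI placed programmatically (foreground inside layers,
background above the first boundary).

What the phantoms deliberately do **not** model: real speckle's
sub-resolution texture and its dependence on tissue microstructure,
attenuation with depth, motion or registration artifacts, and the raw
spectral processing chain. Passing the desk-scale tests therefore shows
that the *pipeline learns and removes axially correlated zero-mean noise
as designed* — it does not certify clinical image quality.

## Deployment pipeline

Inference follows the streaming reconstruction path: buffers (2D slabs of
consecutive A-scans) are denoised **after logarithmic scaling and before
black-level subtraction** — in the domain where the noise is additive and
features near the noise floor are still intact. For throughput, a buffer
is split laterally into 4 sub-buffers carried as 4 channels of a single
network whose weights are replicated per channel with all cross-channel
entries exactly zero (`export_pseudobatch()`; normalization statistics are
frozen before replication so channel independence is exact). Each
sub-buffer is padded by 20 A-scans per side: true neighboring columns at
interior cuts, replicated edge columns at the outer edges. Since 20 px
exceeds the receptive half-width (18 px), the recombined output is
identical to single-pass whole-buffer inference — the package's inference
kernels accumulate in a fixed order precisely so this equivalence is
bit-exact, and a seam test asserts it. The reference smoother is an
isotropic Gaussian (σ = 5 px) truncated at two standard deviations
(21×21), renormalized, with edge replication.

Half-precision deployment is emulated by rounding the weights and every
stored activation to IEEE binary16 (round-to-nearest-even) while keeping
accumulation wide, mirroring fp16 tensor-core execution; the acceptance
suite checks the median output deviation stays under 0.1 gray values on
the 8-bit scale.

## Evaluation protocol

`evaluate()` reports PSNR ($10\log_{10}(R^2/\mathrm{MSE})$), SSIM
(Gaussian window 11/1.5, $K_1 = 0.01$, $K_2 = 0.03$; verified against an
independent reference implementation), and the ROI contrast-to-noise
ratio — the mean over 14 foreground ROIs of
$(\mu_f - \mu_b)/\sqrt{\sigma_f^2 + \sigma_b^2}$ against one background
ROI, with population-convention ROI variances. Aggregates are the equally
weighted mean and *twice the sample standard deviation* across images.
PSNR/SSIM are computed on central crops (default margin 16 px): this
mirrors the protocol of trimming borders, and drops the image-edge zone
where a blind-spot model is weakly constrained (no mask centers lie within
3 px of a border, and the receptive field of edge pixels crosses into
padding). PSNR of identical images is reported as `Inf` and excluded from
aggregation with a warning rather than silently capped.

## Numerical choices and degenerate inputs

* Batch normalization: eps $10^{-5}$, running-statistics momentum 0.1,
  biased batch variance with unbiased running variance.
* Adam: $\beta_1 = 0.9$, $\beta_2 = 0.999$, $\epsilon = 10^{-8}$;
  learning-rate floor $10^{-7}$.
* Plateau = "no strictly lower validation loss for 10 consecutive
  epochs"; the wait counter resets on improvement and after each halving.
* Mask centers whose strip would cross the border are drawn from the
  interior (equivalent to resampling); replacement offsets are redrawn
  until the source strip is in bounds. Overlapping strips are legal: later
  strips overwrite earlier ones, but reads always come from the original
  input, so the result is a pure function of input and plan.
* Range-augmentation draws with an empty target range are redrawn.
* Zero-noise phantoms, zero-layer phantoms, zero-center mask plans, and
  zero-epoch training are all valid degenerate inputs with exact
  contracts (identity corruption, constant image, identity masking,
  initial weights returned).
* Lateral buffer widths not divisible by the sub-buffer count are
  refused, never silently padded; padding below the receptive half-width
  is refused rather than risking silent seams.
* 8-bit export clips to $[0,1]$ and rounds half away from zero.

## Problem sizes used by the shipped checks

The test and acceptance runs use desk-scale sizes chosen to exercise every
code path end-to-end: 256×256 phantoms (8 train / 2 validation / 10
evaluation, 100-frame averages for references), the desk training profile
above for the trained-network checks, a 15-epoch run on 64×64 constant
phantoms for the blind-spot-optimum check, and 512×512 noise fields for
autocorrelation statistics. Full-scale training remains available via
`train_config("paper")`.

## Known limitations

* The bottom few image rows (outside any mask center's reach) are
  unconstrained by the self-supervised loss and can drift; the evaluation
  crop excludes them, and deployment-side padding plays the same role
  laterally. Axial replicate padding at inference would be a
  straightforward extension.
* The desk profile trades final quality for runtime; its PSNR gains are
  well below what full-scale training achieves.
* The phantom noise model is Gaussian in the log domain by construction;
  real log-speckle is only approximately Gaussian and its correlation is
  system-dependent. The generator's correlation lengths are set from the
  masking rationale, not from measured system curves.
* `simulate`-style sampling of new phantoms is deterministic given a
  seed, but clean-geometry variation is limited to boundary waviness and
  layer reflectivity patterns.
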