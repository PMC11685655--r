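---
title: "Saliency-constrained unpaired translation for label-free microscopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Saliency-constrained unpaired translation for label-free microscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyclestain)
```

## The problem

Label-free microscopy modalities (here, a mid-infrared photoacoustic
contrast) report molecular composition without staining, but at coarse
lateral resolution — on the order of 6.6 µm, against the 0.31 µm/pixel
sampling of a confocal fluorescence image. Fluorescence staining, conversely,
gives sharp, molecularly specific images (Hoechst for nuclei, FITC-phalloidin
for F-actin) at the cost of fixing and labelling the sample. `cyclestain`
implements the computational bridge between the two: an unpaired
image-to-image translation that (1) enhances the resolution of the label-free
image and (2) renders it as a virtually stained two-channel image — without
ever having seen registered image pairs.

## The model

Both stages are cycle-consistent adversarial models. Two generators
$G_A: A \to B$ and $G_B: B \to A$ are trained against two least-squares
discriminators $D_A, D_B$. The full objective is

$$L = L_{GAN}(G_A, D_B) + L_{GAN}(G_B, D_A)
      + \lambda\, L_{CYC} + \xi\, L_{SSIM} + \rho\, L_S$$

with

* $L_{GAN}(G_A, D_B) = E_b[(D_B(b) - 1)^2] + E_a[D_B(G_A(a))^2]$ — the
  least-squares adversarial term. The discriminator head is linear (no
  sigmoid): least-squares losses regress scores toward $\{0, 1\}$ and a
  terminal squashing would saturate the gradients. The generator minimises
  $E[(D(G(a)) - 1)^2]$, the standard least-squares generator target.
* $L_{CYC} = E_a\lVert G_B(G_A(a)) - a\rVert_1 + E_b\lVert G_A(G_B(b)) - b\rVert_1$
  — cycle consistency. L1 norms are normalised per pixel so losses are
  resolution-invariant. No identity loss is used: in this setting it is
  ineffective at maintaining image content, and it is deliberately absent.
* $L_{SSIM}$ — one minus the structural similarity between every image and
  its cycle reconstruction, in both directions.
* $L_S$ — the saliency constraint, the explainability term: the soft content
  mask $\mathrm{sigmoid}((x - T)\cdot 100)$ of each input (threshold $T_A$ or
  $T_B$ per domain) must agree in L1 with the soft mask of its translation
  under the *other* domain's threshold. Microscopy backgrounds are flat, so a
  threshold mask is a faithful content descriptor; pinning it prevents the
  translation from inventing or deleting structures.

### Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `lambda_cyc` | 10 | cycle weight (the established CycleGAN convention) |
| `xi_ssim` | 1 | SSIM-loss weight |
| `rho_saliency` | 1 | saliency-constraint weight; 0 disables the constraint |
| `threshold_A`, `threshold_B` | Otsu over a sample of training tiles | content-mask segmentation thresholds, in [0, 1] intensity units |
| `sigmoid_gain` | 100 | sharpness of the soft mask; at 100 the mask saturates once \|x − T\| ≥ 0.4 |
| learning rate | 2e-4, Adam β = (0.5, 0.999) | linear decay to zero over the second half of training |

The weights λ, ξ, ρ and the thresholds are exposed in `loss_config()` and
recorded in every checkpoint; none of them is prescribed numerically by the
method itself, so they are configuration with documented defaults. Otsu
thresholds are the automated stand-in for thresholds that would otherwise be
picked by inspection of the data.

## Architectures

The generator is a residual network: a 3×3 stride-1 convolution to the base
width (64 at full scale), two stride-2 Convolution–InstanceNorm–ReLU layers
doubling the channels (64 → 128 → 256 at quarter resolution), nine residual
blocks, then two bilinear-upsample + convolution stages halving the channels
back, with skip connections between the matching encoder/decoder levels
(implemented as channel concatenation followed by a 1×1 fusion convolution —
the merge rule is a package choice), and a tanh head. Reflection padding
keeps sizes exact; outputs live in [−1, 1] while all image I/O is canonical
[0, 1] (tiles are remapped at the network boundary, and grayscale tiles are
replicated to three channels so both generators stay shape-symmetric).

The discriminator stacks five blocks of two 3×3 convolutions with
leaky-ReLU (slope 0.2, channel doubling per block) and stride-2 average
pooling, then two fully connected layers (→ 512 → 1 at full scale) to a
single unbounded score. An input larger than the head was built for is
subdivided into a mosaic of subtiles and the final score is the mean of the
per-subtile scores; the default scores the whole tile as one.

Grad-CAM introspection treats each residual block as a target layer: the
heatmap is the ReLU of the gradient-channel-weighted activation sum,
bilinearly resized to the input and max-normalised. This is what makes the
model's attention inspectable during translation.

## The synthetic-microscopy generator

All tests and the acceptance experiments run on synthetic scenes, never on
downloaded data. A scene consists of elliptical nuclei (semi-axes drawn from
10–18 × 6–11 px at the default 256-px field) and smooth filaments
(Catmull-Rom splines through random control points, stamped at 3 px width
and feathered by a 1-px Gaussian) — the oval-and-linear phenotype of
fibroblast cultures. Three coupled renderings are produced:

* `hr_stained` — blue = nuclei (intensity 1, soft 1-px edge, so the
  half-intensity contour is the exact ellipse boundary), green = filaments;
* `hr_unlabeled` — a nonnegative channel mixture (0.6·blue + 0.4·green by
  default, reflecting the stronger label-free contrast of nuclei) plus a
  background level of 0.05;
* `lr_unlabeled` — Gaussian PSF blur of the unlabeled view with
  σ = FWHM / (2√(2 ln 2) · pixel size), plus Gaussian noise (sd 0.02),
  clipped to [0, 1]. Boundary handling is whole-sample-symmetric reflection,
  which conserves total intensity exactly — a testable identity.

Everything is a deterministic function of (seed, parameters). What the
generator does **not** emulate: optical aberrations, detector noise
statistics, intensity heterogeneity within organelles, touching or
overlapping nuclei, and the full diversity of real slides. Passing tests on
these scenes therefore demonstrate the correctness of the machinery and the
direction of its training signal, not performance on real tissue.

## The miniature training experiment

Full-scale training is a GPU-days exercise; the package's reference
experiment is deliberately small and CPU-sized: 32 tiles per domain of
64 × 64 px sampled at 1 µm/px (keeping the structure-to-PSF size ratio of
the full-scale study: 10–16 µm nuclei against a 6.6 µm PSF), a base width of
8 with one residual block, a 3-block discriminator with a 64-wide head, batch
size 1, 200 iterations (`synthetic_training_demo()`). Two properties are
monitored:

1. the cycle-consistency loss falls below its initial value — the model
   learns an invertible mapping;
2. content preservation: the mean IoU between the hard content mask of each
   input and of its translation, with per-tile Otsu thresholds, compared
   between a run with the saliency constraint (ρ = 1) and without (ρ = 0).
   Per-tile adaptive thresholds are used for this monitoring statistic
   because 200 iterations are far too few to calibrate absolute brightness
   to the target domain; adaptive thresholds measure structural agreement,
   which is what the constraint is about.

## Evaluation stack

* **PSNR** is reported in the conventional decibel form
  10·log₁₀(MAX²/MSE); a `raw_ratio` mode computes the unlogged ratio
  10·MAX²/MSE for completeness. Identical images report `+Inf`.
* **SSIM** defaults to the windowed form (11×11 Gaussian window, σ = 1.5,
  c₁ = (0.01 L)², c₂ = (0.03 L)²). The global whole-image form — the one the
  training loss uses, and the one oracle tests evaluate term by term — is
  available as `mode = "global"`. Population (biased) variances are used in
  both, matching the formula's plain reading.
* **FID** fits Gaussians to embedded feature sets; the matrix square root is
  Denman–Beavers (via pracma) with an εI ridge (ε = 1e-6) for near-singular
  covariances, and is validated by squaring in the tests.
* **KID** is the unbiased squared-MMD estimator under the polynomial kernel
  (xᵀy/d + 1)³, optionally subset-averaged; it may legitimately be slightly
  negative near zero.
* The **feature embedding is pluggable** and every report names it. The
  shipped default is deterministic and fully offline: channel-mean images
  are average-pooled to 8 × 8 and projected by a frozen seeded random matrix
  to 32 dimensions. FID/KID values are comparable only within one embedding;
  no attempt is made to reproduce published scores that depend on a
  pretrained classification network and the original data.

## Morphometry

Virtually stained (or real stained) tiles are split into blue/green planes.
Nuclei: hard threshold (default 0.5, or Otsu), removal of components under
20 px (~1.9 µm² at 0.31 µm/px), 8-connected component labelling, then area
(pixel count × pixel area) and aspect ratio from the equivalent
second-moment ellipse (a +1/12 pixel self-moment keeps thin shapes honest;
ratios are clamped to ≥ 1). Fibroblast area is the supra-threshold pixel
count of the green plane times the pixel area. Touching or overlapping
nuclei are *not* split (no watershed); overlapping-nucleus scenes are
outside the validated envelope.

## Numerical and design notes

* Tiling is deterministic grid tiling in row-major order; a seeded
  random-offset mode exists but the default is reproducible grids. Tiling at
  stride = tile size inverts exactly via `stitch_tiles()`.
* Augmentations are exact pixel permutations (the dihedral group); no
  interpolation, hence bit-exact involutions.
* Slide-level cross-validation assigns slides to validation folds
  round-robin in input order: deterministic, disjoint, covering.
* 16-bit TIFFs are scaled by their dtype maximum on read; percentile
  normalisation maps the chosen quantiles to [0, 1] and clips; a constant
  image normalises to zeros with a warning rather than an error.
* The optional noise pre-filter is a 3×3 median, off by default.
* The network core (conv via cached im2col gathers + BLAS, instance
  normalisation without affine parameters, bilinear resampling, reverse-mode
  tape) is part of the package and is gradient-checked against central
  differences in the test suite.
* Fake-image history buffers (size 50) feed discriminator updates; per
  iteration both generators update jointly first, then both discriminators —
  neither step touches the other side's parameters.
* Training runs are bit-reproducible for a fixed seed on one machine; the
  run seed fans out to scene sampling, weight initialisation and shuffling
  through labelled sub-seed derivation, so sub-streams are stable when
  unrelated configuration changes.

## Known limitations

* The miniature experiment shows direction-of-improvement properties, not
  converged image quality; 200 iterations produce dim, low-contrast
  translations whose absolute brightness has not yet matched the target
  domain.
* No resume-from-checkpoint: a training run is one call. Checkpoints are
  for inference and archival.
* No multi-GPU, no hyperparameter search, no pyramidal whole-slide formats,
  and no registration between domains (the method is unpaired by design).
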