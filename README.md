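# cyclestain

Unpaired image-to-image translation for label-free microscopy: a
cycle-consistent adversarial network whose objective adds a structural
similarity term and a **saliency-mask constraint** — the soft threshold mask
of every translation is pinned to the mask of its input, preventing the
network from inventing or deleting cellular content. The package implements
the two-stage pipeline used to turn low-resolution label-free intensity
images into high-resolution virtually stained ones (resolution enhancement
followed by virtual fluorescence staining), together with everything needed
to exercise it end to end on one CPU:

* image I/O (TIFF/PNG), tiling, exact dihedral augmentation, percentile
  normalisation, slide-level cross-validation folds;
* a fully seeded synthetic-microscopy scene generator (elliptical nuclei in
  the blue channel, filamentous actin in the green channel, PSF-degraded
  label-free renderings) so no data download is ever required;
* the generator/discriminator graphs, their training loop (least-squares
  adversarial + cycle + SSIM + saliency objective), and Grad-CAM heatmaps of
  the generator's residual blocks;
* the evaluation stack: PSNR, Pearson correlation, SSIM (windowed and
  global), Fréchet and kernel distances over a pluggable, fully offline
  feature embedding;
* morphometric readouts: nucleus count / area / aspect ratio and
  fibroblast (F-actin) area in µm².

The model for audiences familiar with the notation: generators
`G_A: A→B`, `G_B: B→A` and discriminators `D_A`, `D_B` minimise

```
L = L_GAN(G_A, D_B) + L_GAN(G_B, D_A) + λ·L_CYC + ξ·L_SSIM + ρ·L_S
L_S = E_a ||σ(100(a − T_A)) − σ(100(G_A(a) − T_B))||₁ + (symmetric B term)
```

with least-squares adversarial terms, per-pixel-normalised L1 cycle terms,
and Otsu-derived default thresholds `T_A`, `T_B`. The neural-network core
(im2col convolution, instance normalisation, bilinear resampling,
reverse-mode autodiff, Adam) is implemented in base R on BLAS matrix
products and is gradient-checked in the test suite.

## Worked example

Train the miniature reference experiment (32 synthetic 64×64 tiles per
domain, one residual block, 200 iterations — a few minutes on one CPU) and
evaluate the virtual staining against paired ground truth:

```r
library(cyclestain)

run <- synthetic_training_demo(seed = 1, rho_saliency = 1)
run$initial_cycle; run$final_cycle; run$mean_iou

eval_ds <- generate_dataset(16, seed = 99, paired = TRUE, field_size_px = 64,
                            scene_params = list(n_nuclei = 3,
                              nucleus_axes_px = list(a = c(5, 8), b = c(3, 5)),
                              n_filaments = 2),
                            pixel_size_um = 1.0)
out <- translate_tiles(run$model, "AtoB", eval_ds$A$tiles)
evaluate_sets(out, eval_ds$B, pairing = eval_ds$pairing)
```

Output (seed 1):

```
[1] 0.8208264  # cycle loss, iteration 1
[1] 0.4790646  # cycle loss, iteration 200 — the mapping is learning
[1] 0.05033121 # mean saliency-mask IoU, input vs translation (per-tile Otsu)
<metric_report>
  PSNR: 13.321 +/- 0.365 dB  (n = 16 pairs)
  PCC:  -0.0292 +/- 0.1988
  SSIM: 0.0329 +/- 0.0057
  FID: 0.441632   KID: 0.012618   (embedding pool8-proj32-v1, n = 16 vs 16)
```

After 200 iterations the cycle loss has dropped by ~40% and the set-level
distances to the stained domain are small, while the pairwise scores show
what a deliberately tiny run cannot yet do: per-pixel agreement with the
held-out ground truth is still near chance. These are
direction-of-improvement numbers, not converged image quality. Morphometry
on a synthetic stained tile:

```r
sc <- sample_scene(7, n_nuclei = 4, no_overlap = TRUE, noise_sd = 0)
tile <- render_triplet(sc)$hr_stained
cell_features(tile)
#>   tile_id n_nuclei mean_nucleus_area_um2 mean_nucleus_aspect
#> 1   tile1        4              34.62003            1.553971
#>   fibroblast_area_um2 pixel_size_um
#> 1            378.0574          0.31
```

A Grad-CAM heatmap of any residual block:
`gradcam_heatmap(run$model$G_A, eval_ds$A$tiles[[1]], target_layer = 1)`.

A thin command-line wrapper covers the same surface
(`exec/cyclestain synth|tile|train|translate|uidt|evaluate|features`,
`key=value` overrides, JSON/YAML configs, a resolved-config snapshot beside
every output directory).

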