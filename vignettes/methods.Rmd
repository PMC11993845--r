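---
title: "Methods: gland segmentation and breast composition on MLO mammograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gland segmentation and breast composition on MLO mammograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(glandseg)
```

## The problem

Breast composition — the four-category density classification (fatty,
scattered, heterogeneous dense, extremely dense) — is read off the
*mammary gland content ratio*: the area of gland-density tissue divided by
the area of the breast region that could plausibly contain gland, which
excludes the pectoral muscle, the subcutaneous fat rim and the
retromammary gap. Dense breasts (ratio above 50%) lower mammographic
sensitivity and drive decisions about supplemental ultrasound, so a
quantitative, reproducible gland segmentation is clinically valuable.

`glandseg` implements a full pipeline for this task on mediolateral
oblique (MLO) mammograms:

1. **Objective extraction** (`compute_histogram()`, `select_threshold()`,
   `extract_objective_mask()`): a histogram of pixel values inside the
   calculation region is thresholded; the threshold comes from the Kapur
   maximum-entropy criterion when the histogram is unimodal and from Otsu
   discriminant analysis when it has two or more peaks. Foreground is
   intensity *greater than or equal to* the threshold, because gland is
   defined as tissue at or above pectoral-muscle density.
2. **Semi-subjective correction** (`emulate_correction()`): in clinical
   practice a physician deletes every thresholded structure that is not
   gland (vessels, pectoral leakage). On synthetic data the package
   emulates that judgement per connected component: a component survives
   only if at least half of it (configurable) overlaps the gland truth.
   In the end-to-end pipeline (`phantom_pairs()`), objective extraction
   runs over the whole breast — the thresholder does not know where the
   pectoral boundary is, so objective masks genuinely contain the
   pectoral wedge and vessels, and the correction genuinely has
   something to delete; this is what separates the two truth sources in
   the corrected-vs-objective training comparison.
3. **Composition** (`content_ratio()`, `classify_composition()`): bands at
   10 / 50 / 80%.
4. **Preprocessing and orientation** (`preprocess_mammogram()`,
   `orient_pair()`, `split_dataset()`): 14-to-8-bit reduction, symmetric
   lateral padding to a square, nearest-neighbour resize, four
   orientation-dataset variants, seeded splits.
5. **Segmentation** (`build_unet()`, `train_unet()`, `run_grid()`): a
   configurable U-Net trained to reproduce corrected masks from images.
6. **Evaluation** (`dice()`, `dice_with_unmasked_rule()`,
   `stratified_report()`, `compare_truth_sources()`): Dice overlap,
   stratified by composition, with a complement rule for gland-free cases.

Because clinical mammograms with physician truth are private, the package
ships a synthetic phantom generator (`generate_phantom()`) that provides
exact ground truth for every stage; every empirical statement in the test
suite is computed on phantoms.

## The phantom generator

A phantom is built in a left-lateral frame and mirrored for right
laterality:

- **Breast contour**: a half-ellipse against the chest-wall edge
  (semi-axes 0.80 width, 0.46 height, centred at 0.48 height).
- **Pectoral wedge**: a triangle in the upper chest-wall corner, excluded
  (with a small safety margin) from the calculation region.
- **Fat rim**: the outer 16% of the elliptical radius, also excluded.
- **Gland**: the calculation region's top fraction of a Gaussian-smoothed
  random field. The cut is the exact order statistic — the k-th largest
  field value for k = round(ratio × region area) — so the measured content
  ratio matches the target to a single pixel. A smoothed-field threshold
  naturally produces the scattered, island-like morphology seen at
  intermediate ratios. (An iterative bisection on the field threshold
  would converge to the same cut; the order statistic is closed-form and
  exact, so the package uses it.)
- **Vessels**: thin, bright quadratic Bezier curves crossing the breast.
  Vessels are drawn only where they stay separable from the gland (they
  are clipped away from a 5-pixel dilation of the gland truth). This is a
  deliberate modelling choice, not a simplification of convenience: a
  vessel overlying dense gland is indistinguishable from gland by
  intensity, and the physician's deletion — like the package's emulation
  of it — operates on visibly distinct structures.
- **Intensities** (fractions of the bit-depth maximum): background ~0.02,
  fat 0.22–0.30, pectoral 0.53–0.57, vessels ~0.66, gland 0.60–0.76.
  Gland is sampled at or above the pectoral mean, mirroring the
  density-based gland definition; optional Gaussian noise is added, with
  a default standard deviation of about 1% of the 14-bit range.

Everything is driven by one seed (`withr::with_seed`), so phantoms are
bit-reproducible.

**What phantoms do not model**: X-ray physics, scatter, compression,
pathology (masses, calcifications — excluded from the study population in
any case), detector response, or the anatomical variety of real
parenchyma. Passing tests on phantoms therefore demonstrates that the
pipeline's machinery is correct and internally consistent — not that its
accuracy numbers transfer to clinical images.

## Thresholding details

Parameters the source method leaves unspecified are exposed as
configuration with these defaults:

| parameter | default | meaning |
|---|---|---|
| `n_bins` | 256 | uniform bins over the in-region min–max range |
| `smooth_window` | 5 bins | centred moving average before peak counting |
| `min_prominence` | 0.05 | topographic prominence floor, fraction of the smoothed maximum |
| comparison | `>=` | foreground is intensity at or above the threshold |

Entropy uses natural logarithms with 0·log 0 = 0; candidate thresholds
are all bin boundaries with non-empty classes on both sides; ties resolve
to the smallest optimal threshold, making both methods deterministic.
Both are verified against exhaustive brute-force scans in the test suite.

## Composition boundaries

The bands are lower-bound inclusive: [0, 0.10), [0.10, 0.50),
[0.50, 0.80), [0.80, 1]. The densest band is explicitly "at least 80%" in
the classification rule, and the same convention is applied at 0.10 and
0.50 for consistency; the grouping texts ("fatty breast below 50%",
"dense breast above 50%") leave exactly 0.50 unassigned, which this
convention resolves as heterogeneous dense / dense breast.

## Preprocessing order

Bit-depth reduction is a linear rescale (value × 255/16383, rounded), not
bit truncation. Padding to a square precedes resizing so the breast keeps
its aspect ratio; the pad value defaults to 0 and the two lateral pads
differ by at most one pixel. Resizing is nearest neighbour at pixel
centres, which preserves the binary label set of masks. Orientation
mode 1 aligns every image chest-wall-left, mode 2 keeps the anatomical
side, and modes 3/4 add an independent per-image horizontal flip with
probability 0.5 (configurable) — image and mask always flip together.

## The U-Net and its training engine

The architecture is the canonical encoder–decoder: per level two 3×3 same
convolutions with ReLU and 2×2 max pooling; a two-convolution bottleneck;
per decoder level a 2×2 stride-2 transposed convolution, concatenation
with the encoder skip tensor, and two convolutions; a final 1×1
convolution with sigmoid. Channels double per level from `base_kernels`
(64 at full study scale). Internal layer details (activation, padding,
upsampling operator) follow the canonical architecture since only the
depth/kernel schedule is prescribed.

No neural-network framework is involved: forward pass, backpropagation
and Adam live in the package's own C++ (RcppArmadillo) engine, in single
precision — the standard arithmetic for network training. Convolutions
are evaluated as nine shifted GEMMs; gradients were validated in double
precision against an independent analytic backpropagation and against
finite differences, and the shipped test uses a directional-derivative
check (per-coordinate finite differences sit below single-precision
resolution).

Choices the source method leaves open, and the package's defaults:

- **Optimizer**: Adam (β₁ = 0.9, β₂ = 0.999), the de-facto default of
  GUI deep-learning environments; `learning_rate` and `batch_size` are
  the grid's axes.
- **Loss**: binary cross-entropy *plus soft Dice* (`loss = "bce_dice"`).
  Pure cross-entropy learns to rank pixels quickly but calibrates the
  absolute probabilities across the 0.5 cutoff only slowly; with the
  small learning rates of the study grid and short epoch budgets, a
  trained-but-uncalibrated network binarizes to an empty mask. The soft
  Dice term — today's standard for class-imbalanced segmentation —
  directly rewards crossing the decision threshold. Pure `"bce"` and
  pure `"dice"` remain available.
- **Output-layer initialization**: the final 1×1 convolution starts at
  zero so the network begins from a neutral probability map (0.5
  everywhere) instead of arbitrarily saturated predictions; hidden
  layers use He initialization. Zero-initializing the head is a common
  stabilization in segmentation and detection models.
- **Input scale**: images enter the network in their stored 8-bit range
  (0–255), with no further normalization (none is prescribed).
- **Binarization threshold**: 0.5.
- **Checkpointing**: the weights with the best validation Dice are kept;
  validation Dice uses the same unmasked rule as evaluation.

Training is seed-deterministic: initialization, shuffling and flips all
derive from configuration seeds, and repeated runs produce identical
weights and reports.

## Evaluation

Dice = 2|X∩Y| / (|X|+|Y|) on foreground pixels. For *unmasked* images —
truths with zero foreground, the judged gland-free cases — the score is
instead the Dice of the background regions over the full image grid (the
evaluation domain is configurable to the breast region). Unmasked
detection is exact zero foreground, no tolerance. Masks are compared at
network resolution, matching the pipeline rather than native resolution.
Reports stratify by composition category; a category with no images is
reported as absent, not zero, and replicate runs are averaged (averaging
across replicates, rather than selecting the best replicate, is the
default and is configurable by filtering the per-image table).

## Demonstration scale

The package's demonstration experiment (used by its acceptance script and
end-to-end tests) runs on one CPU core in minutes, not on a GPU farm, so
it scales the study design down while keeping its structure:

- 60 training / 12 validation phantoms, ratios uniform on 0.05–0.90;
- a 20-phantom test set mirroring the clinical test fold's composition
  proportions (1 fatty — a gland-free unmasked case — 7 scattered,
  11 heterogeneous dense, 1 extremely dense);
- 128×96 phantoms preprocessed to 128×128 inputs;
- depth 3 (the shallow end of the study grid), learning rate 0.0001,
  batch 16, 20 epochs, and 16 base kernels — the width chosen so one
  training run takes roughly two minutes on a single core while still
  converging within the short epoch budget (`demo_unet_config()`).

At this scale the corrected-truth-trained network reaches a held-out mean
Dice above 0.8, and training on raw objective masks (which retain vessels)
scores lower against corrected truth — the same direction the full-scale
comparison reports. The absolute full-scale accuracy (overall mean Dice
around 0.88 on clinical data) is not reproducible without the private
clinical dataset, and the package makes no claim that phantom numbers
estimate it.

## Known limitations

- Phantom realism, as above; results quantify machinery, not clinical
  accuracy.
- The calculation region on real images is taken as given (the phantom
  generator produces it as truth); delineating it on clinical data is a
  separate problem outside this package.
- DICOM ingestion is not provided (no R DICOM reader in the supported
  stack); images are read and written as 16-bit TIFF with a JSON sidecar
  plus 8-bit PNG masks.
- The training engine is single-core; the full 20-cell grid at study
  scale (256×256, 64 base kernels, 670 images) is far outside its
  intended envelope.
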