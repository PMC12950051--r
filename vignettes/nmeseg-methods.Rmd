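---
title: "Segmenting non-mass enhancement in two-phase breast DCE-MRI: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting non-mass enhancement in two-phase breast DCE-MRI: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Non-mass enhancement (NME) is a pattern of diffuse, irregular contrast
uptake in breast dynamic contrast-enhanced MRI that does not form a
well-defined mass. It is clinically important (it can indicate DCIS) and
notoriously hard to delineate: the lesion has low conspicuity on any single
phase, and the most informative signal is *temporal* — how intensity changes
between the pre-contrast and the early post-contrast acquisition. The
principal false-positive sources are other enhancing structures: vessels and
normal fibroglandular parenchyma.

`nmeseg` implements a volumetric segmentation pipeline built around that
temporal signal, together with everything needed to exercise it end to end
without clinical data: a synthetic two-phase phantom generator, the image
preparation chain, Dice-loss training, and a paired statistical comparison
harness.

## The model

The segmentation network is a hybrid CNN–transformer encoder–decoder
("TransUNet"-style) over 3D volumes with two parallel convolutional
encoders:

* an **early branch** encoding the early post-contrast volume, and
* a **difference branch** encoding the positive-clamped early-minus-pre
  subtraction volume.

Each encoder applies three blocks of (3D convolution, batch normalisation,
ReLU, max-pooling). Pooling factors are (2, 2, 1), so three blocks divide the
in-plane extent by 8 and preserve the slice count: a 176 x 176 x 144 input
becomes a C x 22 x 22 x 144 feature map.

The two feature maps are fused by the **temporal attention gate**

F_att = F_early + F_early ⊙ F_diff,

an element-wise, parameter-free operation: voxels with both strong early
signal and strong temporal change are multiplicatively amplified, while the
residual term preserves the early-phase representation. We deliberately add
no learned temperature or projection here — the gate as defined has no
parameters, which is also what makes the parameter-count comparison against
the concatenation variant clean.

The gated map is partitioned into non-overlapping 3D patches (8 x 8 x 8 by
default), each patch flattened, linearly projected to the embedding width
and given a learned positional embedding. A pre-norm transformer encoder
(x ← x + MHSA(LN(x)); x ← x + MLP(LN(x)), scaled dot-product multi-head
attention) models long-range context between patches. Since 22 is not a
multiple of 8, the feature map is zero-padded to 24 x 24 x 144 before
patching (grid 3 x 3 x 18, 162 tokens) and cropped after unpatching.

A U-Net style decoder mirrors the encoder: three stages of transposed
convolution (x2 in-plane, x1 through-plane) followed by skip concatenation
and a conv-BN-ReLU block, then a pointwise projection and logistic map to
per-voxel probabilities at the input resolution.

### Ablation variants

Four variants share the transformer and decoder and differ only in the
encoder/fusion stage; all are behind one `model_config(variant = ...)`
switch so comparisons are architecture-controlled:

1. `baseline` — one encoder over a 3-channel input (pre, early, diff).
2. `single_enc_attention` — baseline plus voxel-level self-attention (learned
   Q/K/V/output projections, residual) on the encoder output.
3. `dual_enc_no_attention` — two encoders, channel concatenation, 1 x 1 x 1
   projection back to C channels.
4. `dual_enc_temporal_attention` — two encoders fused by the gate above
   (the proposed model).

### Design choices the architecture description leaves open

* **Layer widths, embedding width, depth, heads** are not published; all are
  exposed in `model_config()`. Defaults (32/64/128 encoder channels, 256-d
  embedding, depth 4, 8 heads) target GPU-scale runs; every experiment in
  this package's tests uses reduced widths, which leave all shape contracts
  unchanged.
* **Skip-connection source** is ambiguous for dual-encoder variants. The
  package default is the early branch's pre-pooling activations (the gate is
  anchored on the early branch through its residual term);
  `skip_source = "fused"` (element-wise sum of both branches) is available
  and is what the scaled experiments use: with early-only skips the decoder
  receives *no* subtraction-image information at full resolution — it only
  enters through the /8 bottleneck — which systematically starves the
  dual-encoder variants at reduced scale, while the three-channel baseline's
  skips carry the difference channel directly.
* **Input normalisation**: per-volume min–max scaling to [0, 1], applied to
  each channel independently; configurable.
* **Binarisation threshold** for evaluation is 0.5 (the published evaluation
  does not state one).
* **Transformer initialisation** is random; a hook (`pretrained_init`)
  accepts externally supplied weights but nothing is downloaded.

## Training

Training minimises the soft Dice loss

L = 1 − (2 Σ p_i q_i + ε) / (Σ p_i + Σ q_i + ε)

with AdamW. The published recipe (batch 2, up to 100 epochs, learning rate
1e-4) is the `train_config()` default. The smoothing term ε (default 1e-5)
is our addition for empty-mask robustness; ε = 0 recovers the exact formula
and is used in the formula tests. No stopping rule is published and no
validation split is described, so the default runs all epochs and keeps the
last checkpoint (`best_train_loss` is available). Batch-norm statistics are
computed over the mini-batch during training and frozen running averages are
used at inference.

The entire network and its backpropagation are implemented in the package
(R with C++ kernels for convolution, pooling and resampling); determinism
is exact under fixed seeds, which the reproducibility tests assert bitwise.

## Image preparation

* **Rigid registration**: the early phase (moving) is aligned to the
  pre-contrast phase (fixed) by multi-resolution (3 levels, Gaussian
  smoothing + factor-2 downsampling) Nelder–Mead minimisation of the mean
  squared intensity difference over rigid parameters; a translation-only
  mode is the default in the pipeline since the phantom applies
  translation-only motion. On noise-free phantoms with ≤ 5 mm shifts the
  recovered translation is within 0.25 mm per axis (asserted in tests; the
  residual ~0.1 mm reflects interpolation bias).
* **Subtraction imaging**: voxel-wise `max(early_aligned − pre, 0)`;
  negative differences (noise, residual misregistration) are zeroed.
* **Foreground segmentation**: a global Otsu threshold; the foreground class
  is chosen as the one (proportionally) absent from the most anterior image
  border, which makes the operation invariant to contrast inversion; then
  components reaching the anterior half are kept and a box closing applied.
* **Landmarks**: per lateral half, the nipple is the most anterior
  foreground voxel (ties resolved toward the half's centroid); the sternum
  point is the most anterior midline foreground voxel strictly posterior to
  the nipple midpoint. "Level of the sternum" has no published operational
  definition; this is our stand-in and is isolated in one function.
* **ROI**: the rectangle spans the full left–right extent and the
  posterior–anterior interval from the sternum point to the nipple level,
  then is centrally cropped — or symmetrically zero-padded when smaller —
  to 176 x 176 in-plane (all slices kept). The identical integer window is
  applied to images and annotation masks (whether the original protocol
  cropped or resampled annotations is unstated; an integer crop preserves
  mask voxel counts).

Coordinates are 1-based (R convention) with y increasing anteriorly; the
half-open 0-based intervals that a Python implementation would use map to
the recorded `roi_spec` windows by subtracting one from the starts.

## The phantom

The generator emulates a bilateral axial two-phase acquisition at the
clinical geometry (352 x 352 x 144 voxels of 0.91 x 0.91 x 1.0 mm by
default, freely reducible):

* a dark posterior chest-wall slab (fat-suppressed pectoral tissue) and a
  thin bright subcutaneous layer across the chest surface;
* two half-ellipsoidal breast mounds with protruding single-voxel nipple
  apices (recorded, so landmark detection is testable exactly) and smoothed
  Gaussian-field fibroglandular texture;
* a diffuse lesion built as the union of ≥ 3 overlapping anisotropic
  smoothed blobs inside one mound's core, thresholded to an exact target
  voxel count (default 0.25% of the grid) — irregular and multi-focal, not
  a ball;
* enhancement: the early phase adds `amplitude × (1 + heterogeneity × texture)`
  relative to mean breast intensity inside the lesion, bright spline-tube
  vessels (radius 2 voxels) and mild parenchymal uptake elsewhere — the two
  canonical false-positive sources;
* inter-phase translation (≤ 2 mm per axis by default) and additive Gaussian
  noise applied to the early phase after enhancement.

Malignant lesions default to amplitude 0.8 and heterogeneity 0.5, benign to
0.25 and 0.1. These encode the qualitative clinical contrast — malignant NME
enhances strongly and heterogeneously, benign weakly, homogeneously and
gradually — as no quantitative uptake magnitudes are published; they are
package choices, fixed once. Noise is additive Gaussian (σ = 2 on a ~100
intensity scale), not Rician; intensities are arbitrary units.

What the phantom does **not** model: pharmacokinetic (Tofts-type) uptake
curves, delayed phases, deformable motion, coil inhomogeneity, Rician noise,
ductal anatomy. Passing tests on the phantom therefore demonstrate that the
pipeline's machinery is correct and that the temporal-attention signal is
exploitable when enhancement kinetics separate lesion from background — not
clinical-grade accuracy on real data.

## Scaled experiments

Published full-scale results require the private clinical cohort, unstated
layer widths and GPU training, and are out of reach by construction. The
package's experiments instead run a reduced design chosen once:

* cohorts of 20 patients (12 in the acceptance script) on an 88 x 88 x 36
  grid, benign fraction 0.5;
* reduced widths (encoder 4/4/8, decoder 8/4/2, 4³ patches, 32-d embedding,
  depth 2, 4 heads) — shape contracts are width-independent — and an output
  bias initialised to −4, the standard sparse-foreground prior, so the
  initial prediction mass is already close to the lesion's volume fraction;
* learning rate 2e-2 with batch 2 and 10 epochs per fold: with tens rather
  than tens of thousands of optimisation steps, the tiny model needs a
  proportionally larger step size than the published 1e-4 (which remains the
  `train_config()` default). Batch 1 at comparable step sizes destabilises
  the batch-norm statistics and can collapse the prediction, so the
  mini-batch of 2 is kept;
* a patient-level k = 2 split scored on the first held-out fold, repeated
  over independent cohort replicates (3 master seeds in the acceptance
  test).

The end-to-end claim these experiments check is ordinal, mirroring the
published ablation: the dual-encoder temporal-attention variant should match
or exceed the baseline's held-out mean Dice on most replicates, and both
should clear a 0.3 sanity floor — not the published magnitudes.

## Numerical notes and limitations

* Convolution is im2col + GEMM in C++ (depth-chunked to bound memory);
  max-pool argmax ties break toward the first window element; all forward
  passes are finite for finite inputs and every trainable parameter of every
  variant receives gradient (asserted by a dead-branch test; the
  finite-difference agreement of the full backward pass was verified to
  ~1e-6 relative error during development).
* Registration cost is evaluated on in-field voxels only; optimisation is
  derivative-free, so it tolerates the piecewise-smooth interpolation cost.
* Both-empty masks score 1.0 in Jaccard/Dice (never triggered by the
  phantom, whose lesions are nonempty).
* Wilcoxon signed-rank: zeros dropped, mid-ranks for ties, exact null for
  n ≤ 25 without ties, otherwise normal approximation with tie and
  continuity corrections; Holm step-down per metric across the comparisons
  against the reference variant.
* The spatial self-attention of the `single_enc_attention` variant is
  O(voxels²) at the encoder resolution and is intended for reduced grids;
  the published description of that ablation is one sentence, and our
  single-layer residual form is one reasonable reading of it.
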