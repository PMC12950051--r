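# nmeseg

Volumetric segmentation of **non-mass enhancement (NME)** in two-phase
breast dynamic contrast-enhanced MRI (DCE-MRI), for image-analysis
researchers who want a fully testable, CPU-scale implementation of a
dual-encoder hybrid CNN–transformer segmentation network driven by temporal
contrast kinetics.

NME is diffuse, irregular contrast uptake without a well-defined mass; the
discriminative signal is the *change* between the pre-contrast and the early
post-contrast acquisition, and the main false positives are vessels and
enhancing fibroglandular tissue. The package implements:

* **Model** — a 3D TransUNet-style network with two parallel CNN encoders
  (early post-contrast volume; positive-clamped early−pre subtraction
  volume) fused by a parameter-free **temporal attention gate**

  F_att = F_early + F_early ⊙ F_diff,

  followed by 3D patch embedding (8×8×8), a pre-norm transformer encoder,
  and a U-Net decoder with skip connections. Three ablation variants
  (three-channel single-encoder baseline, single-encoder + self-attention,
  dual-encoder + concatenation) share the transformer/decoder behind one
  `model_config(variant = ...)` switch. The network, its backpropagation and
  AdamW are implemented in the package (R + C++ kernels), so everything is
  deterministic and testable without a deep-learning framework.
* **Preprocessing** — multi-resolution rigid registration (MSE), clamped
  subtraction imaging, Otsu foreground segmentation, nipple/sternum landmark
  detection, and the landmark-driven central crop to 176×176 in-plane.
* **Synthetic phantom** — two-phase breast cohorts with ground-truth diffuse
  lesions, enhancing vessels, fibroglandular texture, benign/malignant
  kinetics, inter-phase motion and noise, at any grid size (clinical
  geometry 352×352×144 at 0.91×0.91×1.0 mm by default). NIfTI-1 I/O and CSV
  manifests.
* **Training / evaluation** — soft Dice loss (`1 − 2Σpq/(Σp+Σq)`), AdamW
  (batch 2, lr 1e-4 defaults), patient-level k-fold cross-validation,
  Jaccard `|A∩B|/|A∪B|` and Dice `2|A∩B|/(|A|+|B|)`, subgroup aggregation
  (all / benign / malignant), and paired Wilcoxon signed-rank tests with
  Holm correction against the proposed variant.

## Worked example

A complete reduced experiment — synthetic cohort, preprocessing,
cross-validated training of the baseline and the proposed variant, paired
statistics — in a few lines:

```r
library(nmeseg)

res <- run_experiment(list(
  seed = 3,
  out_dir = tempfile("nme"),
  phantom = list(n_patients = 2L, grid_shape = c(48L, 48L, 16L)),
  model = list(enc_channels = c(2L, 2L, 3L), patch_size = c(2L, 2L, 2L),
               embed_dim = 8L, transformer_depth = 1L, n_heads = 2L,
               mlp_ratio = 2, dec_channels = c(3L, 3L, 2L)),
  train = list(max_epochs = 1L),
  evaluate = list(k = 2L),
  log_level = "quiet"))

print(res$scores[, c("patient_id", "variant", "label", "dice")], digits = 3)
```

```
  patient_id                     variant     label   dice
1       P001                    baseline malignant 0.0000
2       P001 dual_enc_temporal_attention malignant 0.0000
3       P002                    baseline    benign 0.0167
4       P002 dual_enc_temporal_attention    benign 0.0248
```

(Two patients, one epoch: the scores are near-random — the point of the
smoke configuration is the end-to-end plumbing. `summary.csv`,
`scores.csv`, per-patient NIfTI volumes, ROI JSONs and a run log land under
`out_dir`.) At experiment scale, `default_run_config()` uses 20 patients on
an 88×88×36 grid with ten training epochs; there the temporal-attention
variant matches or exceeds the baseline's held-out mean Dice on most cohort
replicates — the ordinal claim the scaled acceptance experiment checks.

Individual stages are ordinary functions:

```r
cfg    <- phantom_config(grid_shape = c(88, 88, 36), lesion_label = "malignant")
bg     <- generate_breast_background(cfg)
lesion <- place_nme_lesion(bg, bg$breast_mask, cfg)
early  <- apply_enhancement(bg$volume, lesion, bg$breast_mask, cfg)
diff   <- subtract_clamp(early, bg$volume)
fg     <- segment_breast_foreground(early)
lm     <- detect_landmarks(fg)
roi    <- extract_roi(list(pre = bg$volume, early = early, diff = diff,
                           mask = lesion), lm, target_inplane = 88)
```

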