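---
title: "Fine-tuning a 3D U-Net for axon segmentation with sparse slice annotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fine-tuning a 3D U-Net for axon segmentation with sparse slice annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(axontune)
```

## The problem

Light-sheet fluorescence microscopy of cleared mouse brain produces 16-bit 3D
stacks in which labeled axons appear as bright curvilinear filaments on a dark,
noisy background. Expert annotation of such volumes is so laborious that in
practice only periodic z-slices are labeled — in the regime this package
targets, every 20th slice starting at the 15th, on cubic subvolumes of side
160 voxels cut from the stitched stack, each paired with a 188-voxel padded
intensity cube that gives the network surrounding context.

`axontune` implements the complete fine-tuning recipe for this setting: label
preparation (a one-voxel *edge* class around axons), patch sampling with
foreground oversampling, spatial and intensity augmentation, a class-weighted
masked cross-entropy loss for a small 3D U-Net with optional layer freezing,
Gaussian-weighted overlapping sliding-window inference, and an edge-tolerant
metric suite with the half-standard-deviation rule used to decide which
training modifications to keep. A synthetic phantom generator makes the whole
chain testable end to end without microscope data.

## Label model

Voxels carry one of five codes: `unlabeled` (0), `background` (1), `axon` (2),
`edge` (3), `artifact` (4). Annotation is *slice-atomic*: a z-slice is either
fully annotated or fully unlabeled. Two devices absorb annotation imprecision:

* **Masking.** Unlabeled voxels get loss weight exactly 0 and are excluded
  from every metric. Because the loss divides by the fixed voxel count of the
  block rather than the weight sum, this masking is exact: predictions on
  unlabeled slices cannot move the loss or its gradient by even one ulp.
* **The edge class.** `generate_edges()` recodes every labeled non-axon voxel
  adjacent to an axon as `edge`. Edges carry a near-zero loss weight (0.05)
  and are discounted in evaluation, so a positive prediction one voxel off an
  expert's boundary is nearly free. The default connectivity is the in-plane
  8-neighborhood, computed slice by slice, because annotation lives on
  isolated slices and boundary ambiguity is an in-plane phenomenon there; a
  26-neighborhood 3D mode is available (`edge_config("3d26")`). Which of the
  two the original edge annotator used is not documented; the choice is a
  single configurable constant.

The default class weights are axon 1.5, background 0.2, artifact 0.8,
edge 0.05. Setting the background weight to 1.5 makes all labeled classes
equal — the "equal weights" configuration of the ablation grid
(`class_weights(w_background = 1.5)`).

## Sampling and augmentation

Training pairs are `in_side`³ intensity windows (default 64) with centered
`out_side`³ label targets (default 32); the network commits only to voxels
with full surrounding context. Corners are drawn uniformly over all positions
where the window fits — never padded — except that with probability 0.3 the
corner is drawn from the list of axon voxels, anchoring the window on
foreground. Note the anchor voxel sits at the window's *corner*, not its
center; this matches the sampling scheme being reproduced even though
centering would be more conventional, and it means an oversampled draw does
not guarantee foreground inside the central target crop. Validation volumes
come from the last 64 voxels along x (`split_train_val()`), training from the
rest, with windows never crossing the boundary; validation draws are uniform
and unaugmented.

One spatial transform per training pair — per-axis flips (p = 1/2 each),
rotations up to ±15° per axis, optionally an elastic displacement field — is
applied identically to image (trilinear) and labels (nearest-neighbor), so
co-located structures stay co-located; this invariant is tested with fiducial
markers. Magnitudes beyond the flip set are not prescribed by the recipe
being reproduced, so the defaults here (±15°, elastic α = 8 voxels smoothed
over σ = 4 voxels, gain 0.8–1.2, offset ±0.05) are conventional values for
fibrous 3D data, all exposed in `augment_config()`. The elastic field is
sampled on a coarse control grid with ~4σ spacing and upsampled trilinearly —
an inexpensive stand-in for Gaussian-smoothed dense noise with the same two
parameters. Intensities are normalized by division by 65535 (no z-scoring:
absolute brightness separates axons from background and is worth keeping),
then gain/offset jitter is applied to training images only. The fixed order
normalize → spatial → intensity makes draws reproducible from one seed.

## Network and training

The model is a compact encoder–decoder with skip connections: two
(3×3×3 convolution → normalization → ReLU) blocks per resolution level, 2×
max-pooling down, nearest-neighbor upsampling and channel concatenation up,
and a 1×1×1 sigmoid head giving a per-voxel axon probability. The head is
single-channel: the per-class structure enters through the per-voxel loss
weights rather than a softmax, which is consistent with thresholding the
output at 0.5 and with down-weighting rather than re-classifying edges. Logits
are computed at full window size and center-cropped, so one trained model can
emit 32³ targets during training and 36³ tiles at inference.

The loss is weighted binary cross-entropy, normalized by the block's total
voxel count (not the weight sum) — the choice that makes masking exact and
keeps the weight grid comparable across batches. Predictions are clamped at
1e-7 inside the logs. Training uses Adam (η = 1e-3 by default; the study grid
also contains 5e-4 and 1e-4, and conventional β₁ = 0.9, β₂ = 0.999), batch
size 6 for 50 epochs by default, `n_train / batch_size` steps per epoch, and
keeps the checkpoint at the validation-loss minimum. An optional
reduce-on-plateau schedule multiplies η by 0.1 after a patience (default 5
epochs, min-delta 1e-4) without validation improvement; only the factor 0.1
is prescribed, the patience and min-delta are this package's defaults.

Because no deep-learning framework is available as an R dependency at this
scale, the forward and backward passes are authored here directly, with the
convolutions in compiled code; gradients are verified against finite
differences in the test suite. The normalization layers compute statistics
over each sample's own spatial extent (batch-size-independent, as is now
common for small-batch 3D segmentation) with learnable gain and offset;
cross-batch statistics are not used. Consequently training is deterministic
given seeds, and "batch size" acts through gradient averaging only.

**Layer freezing.** `set_trainable()` implements transfer-learning modes:
`full` (default), or training only the `first`, `middle`, or `last` two 3D
convolution layers, counted in forward order over all convolutions including
the head. In partial modes every normalization layer remains trainable —
freezing them is known to hurt fine-tuning — and frozen kernels are exactly
invariant (the optimizer skips them), which the tests check bit-for-bit.

## Inference

`sliding_window_inference()` tiles a normalized volume with 64³ windows
producing 36³ outputs (offset 14), so a 188³ padded cube yields exactly the
160³ labeled region. In `uniform` mode tiles abut; in `gaussian` mode tiles
overlap by half a window and each prediction is multiplied by a center-peaked
Gaussian (`gaussian_matrix()`, σ = out_side/8 — the conventional importance-map
width, as σ itself is not prescribed) before accumulation; each voxel is the
weighted mean of all covering windows. The final tile along each axis is
snapped flush to the boundary and resolved by the same weighted accumulation.
Mirrored-prediction averaging at inference is deliberately not implemented.
Implementation equivalence to a per-voxel brute-force weighted mean is tested
to 1e-6. Binary masks use a strict threshold: `prob > 0.5`.

The training geometry uses a 32³ output and inference a 36³ output for the
same 64³ input; both are valid center crops of the full-size logits, and the
package keeps `out_side` a free parameter of the window geometry rather than
of the trained weights.

## Evaluation and the ablation harness

`confusion_counts()` scores only labeled voxels: positives are axon voxels;
background, artifact and edge voxels are negatives; `EA` counts edge voxels
predicted positive (a subset of the false positives). The suite
(`compute_metrics()`) contains accuracy, precision, recall, F1, and the
edge-adjusted variants with EA removed from the false positives:
EdgePrecision = TP/(TP+FP−EA) and Edge F1, the harmonic mean of recall and
edge precision — the primary criterion. *Adjusted accuracy* is implemented as
(TP+TN)/(TP+TN+FP+FN−EA), i.e. accuracy with edge-as-axon calls removed from
the error total by the same logic as edge precision; the tables this mirrors
never define it in their methods, so this reading is an explicit
interpretation, flagged here. Undefined ratios propagate as `NA` and are
dropped (with a count) from averages, never imputed as 0.

Aggregation follows the leave-one-cube-out design (`fold_plan()`): metrics
are averaged per validation section over the models that validated on it,
then across sections. `compare_to_default()` takes per-section differences of
a variant against the default configuration and reports their mean and sample
(n−1) standard deviation; `selection_rule()` keeps a modification iff
avg ≥ 0.5 · sd. The sample standard deviation is a choice (n vs n−1 is not
specified in the source of the rule); at the six-section scale the difference
is ~10% of the sd and has not changed any of the documented keep/reject
examples, which the tests reproduce.

## The synthetic phantom

`generate_axon_cube()` emulates the structure of the study material: bright
tubular filaments — fixed-step 3D random walks with Gaussian-perturbed
direction, rasterized as Euclidean tubes of radius 1.5–3 voxels — on Gaussian
background noise, generated jointly over the padded extent so fibers run
naturally into the context shell. Default intensities (background 300 ± 100,
axon 3000 ± 800 on the 16-bit scale) are plausible for labeled fibers in
cleared tissue; density classes are qualitative (sparse 3, moderate 8, dense
20 filaments), since the real cubes' axon-voxel fractions are not published.
Optional bright ellipsoids stand in for imaging artifacts. Labels derive from
the rasterized tube mask, then pass through edge generation and slice
sparsification — the same preprocessing as real data.

What the phantom does *not* emulate: the light-sheet PSF, stripe artifacts,
intensity inhomogeneity across the field, annotator disagreement, and real
axonal branching or varicosities. Passing tests therefore demonstrate that
the machinery is correct and that the training dynamics behave as designed —
not that any particular accuracy transfers to real brains.

## Numerical choices and degenerate inputs

* Probability clamp 1e-7 in the loss; normalization ε = 1e-5; Gaussian weight
  floor 1e-8 (keeps the stitching denominator strictly positive, asserted at
  run time).
* Slice indexing for "every 20th, starting at the 15th" is 1-based
  (15, 35, …, 155: eight slices per 160), configurable in
  `sparsify_labels()`.
* Oversampling with no reachable axon voxel falls back to uniform sampling
  with a one-time warning; a start slice beyond the volume depth yields an
  all-unlabeled volume with a warning; windows that would leave the volume
  are rejected, never padded.
* Ties in `threshold_segmentation()` (prob exactly 0.5) are negative.
* `max`-pooling ties take the first voxel in column-major order.

## Scale of the built-in experiments

The test suite exercises training at desk scale: the overfitting check runs a
depth-2, 2-channel U-Net on five 64³ windows for 200 optimizer steps, and the
transfer check pretrains on one synthetic distribution and fine-tunes on a
shifted one (dimmer axons, brighter background) with 32³ windows, five seeded
repeats, scoring Edge F1 on held-out volumes of the shifted distribution.
These sizes were chosen so the full pipeline — not a mock — runs in minutes on
one CPU core; the architecture accepts larger `model_spec()` values without
code changes.

```{r example, eval = FALSE}
cube <- generate_axon_cube(synthetic_spec(density_class = "dense", seed = 1))
labels <- sparsify_labels(generate_edges(dense_labels(cube)))
cfg <- run_config(synthetic = synthetic_spec(density_class = "dense", seed = 1))
res <- run_pipeline(cfg, out_dir = "axontune_demo")
res$metrics$edge_f1
```

## Known limitations

* Single-channel sigmoid output: the artifact class shapes the loss but is
  not predicted as a class.
* Per-sample normalization statistics mean the model has no "evaluation mode"
  distinct from training; very small inference windows would make the
  statistics noisy.
* The training loop is single-threaded and in-memory; terabyte-scale stacks
  need out-of-core tiling that is out of scope here.
* The half-standard-deviation selection rule is a heuristic, not a
  significance test, and with six validation sections its sd estimate is
  itself noisy.
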