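# axontune

Fine-tuning small 3D U-Nets to segment axons in light-sheet microscopy
volumes where expert annotation exists only on periodic z-slices.

Whole-brain light-sheet imaging of cleared tissue shows labeled axons as
bright, thin filaments in 16-bit 3D stacks. Hand-labeling such data is so
costly that practical training sets annotate only every 20th slice of a few
160³-voxel cubes (each embedded in a 188³ padded intensity cube for context).
`axontune` implements the full transfer-learning recipe for this regime:

* **Sparse-label machinery** — slice-atomic label volumes with codes
  {unlabeled, background, axon, edge, artifact}; a one-voxel **edge class**
  generated around axons (`generate_edges()`), down-weighted so boundary
  ambiguity is nearly free; exact **masking** of unlabeled slices in both
  loss and metrics.
* **Sampling & augmentation** — 64³ input windows with centered 32³ targets,
  corners drawn uniformly or (30% of the time) anchored on axon voxels;
  train/validation split along x (last 64 voxels validate); flips, rotations,
  elastic deformation applied identically to image and labels; intensity
  gain/offset jitter after division by 65535.
* **Weighted masked loss** — per-voxel binary cross-entropy on the axon
  probability, weighted by annotated class (axon 1.5, background 0.2,
  artifact 0.8, edge 0.05; unlabeled exactly 0), normalized by the block's
  voxel count:

  L = (1/N) Σᵥ wᵥ [ −tᵥ log pᵥ − (1 − tᵥ) log(1 − pᵥ) ]

* **A compact 3D U-Net** with seeded initialization, per-sample
  normalization layers, center-cropped output, and layer-freezing modes
  (`full` / `first` / `middle` / `last` two convolutions, normalization never
  frozen), trained with Adam (1e-3, batch 6, 50 epochs by default), optional
  reduce-on-plateau (×0.1), checkpoint at the validation-loss minimum. The
  network's forward/backward passes are implemented in the package (Rcpp
  kernels) and verified against finite differences.
* **Gaussian-weighted sliding-window inference** — 64³→36³ windows (offset
  14; a 188³ input segments exactly the 160³ labeled region), half-window
  overlap, predictions blended with a center-peaked Gaussian:
  out(v) = Σᵢ wᵢ(v) pᵢ(v) / Σᵢ wᵢ(v); thresholded at prob > 0.5.
* **Edge-tolerant evaluation** — TP/TN/FP/FN plus EA (edge voxels predicted
  axon); EdgePrecision = TP/(TP+FP−EA); Edge F1 (harmonic mean with recall)
  as the primary criterion; leave-one-cube-out fold plan; per-validation-
  section aggregation; and the ablation **selection rule**: keep a
  modification iff mean improvement ≥ 0.5 × sd of the per-section
  differences.
* **A synthetic phantom generator** (`generate_axon_cube()`) — seeded random-
  walk tubular filaments with realistic 16-bit intensity statistics — so the
  entire pipeline is testable without microscope data.

## Worked example

A desk-scale end-to-end run on a synthetic dense cube (64³ labels, 8-voxel
padding, 32³→16³ training windows, ~2.5 min on one CPU core):

```r
library(axontune)

g <- window_geometry(in_side = 64, out_side = 36)
g$offset                             # 14
output_extent(c(188, 188, 188), g)   # 160 160 160

cfg <- run_config(
  synthetic = synthetic_spec(label_side = 64, pad_offset = 8,
                             density_class = "dense", seed = 1),
  sampling  = sample_config(in_side = 32, out_side = 16, val_strip = 32,
                            n_train_per_cube = 40, n_val_per_cube = 5),
  augment   = augment_config(rotate = FALSE, elastic = FALSE, flip = TRUE),
  training  = train_config(epochs = 20, batch_size = 2, seed = 2),
  model     = model_spec(depth = 2, base_channels = 4, in_side = 32, out_side = 16),
  weights   = class_weights(w_background = 1.0),
  inference = window_geometry(32, 16),
  seed = 7)
res <- run_pipeline(cfg, out_dir = "axontune_demo", verbose = FALSE)
lapply(res$metrics, round, 4)
```

```
$accuracy            0.9674
$adjusted_accuracy   0.9905
$precision           0.5232
$edge_precision      0.8045
$recall              0.9772
$f1                  0.6815
$edge_f1             0.8825
```

The pattern is the instructive part: recall is near 1 and plain precision
looks poor (0.52), but almost all "false positives" sit on the one-voxel edge
band around true axons, so edge precision (0.80) and Edge F1 (0.88) — the
metrics designed for annotator boundary ambiguity — are high. The pipeline
writes the intensity/label/probability stacks, the training history and a
JSON metrics report (each with a reproducibility sidecar) under `out_dir`.

A thin CLI over the same functions lives at `inst/cli/axontune.R`
(subcommands `generate`, `make-edges`, `evaluate`, `pipeline`, `config`).

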