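#' Run the end-to-end pipeline on synthetic data
#'
#' Desk-scale orchestration of the whole method: generate a synthetic cube,
#' derive edge labels and sparse slice annotation, split train/validation
#' along x, fine-tune the U-Net, segment the padded cube with sliding-window
#' inference, and score the labeled slices. Each stage writes its artifacts
#' under `out_dir` with a JSON sidecar recording the configuration hash and
#' seed; later stages refuse to run if an upstream artifact is missing.
#'
#' @param cfg A [run_config()].
#' @param stages Character subset of
#'   `c("generate", "edges", "train", "infer", "evaluate")`.
#' @param out_dir Output directory (created if needed).
#' @param verbose Print stage progress.
#' @return Invisible list of in-memory stage results.
#' @export
run_pipeline <- function(cfg = run_config(),
                         stages = c("generate", "edges", "train", "infer",
                                    "evaluate"),
                         out_dir = tempfile("axontune_run_"),
                         verbose = TRUE) {
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(...)
  res <- list(out_dir = out_dir)
  paths <- list(input = file.path(out_dir, "cube_input.tif"),
                labels = file.path(out_dir, "cube_labels.tif"),
                edged = file.path(out_dir, "cube_labels_edged.tif"),
                ckpt = file.path(out_dir, "checkpoint.rds"),
                prob = file.path(out_dir, "cube_prob.tif"),
                report = file.path(out_dir, "report.json"))
  set.seed(cfg$seed)

  if ("generate" %in% stages) {
    say("stage generate: synthetic cube")
    cube <- generate_axon_cube(cfg$synthetic)
    res$cube <- cube
    write_stack(cube$intensity, paths$input, bits = 16L)
    write_sidecar(paths$input, cfg, "generate")
    write_stack(dense_labels(cube), paths$labels, bits = 8L)
    write_sidecar(paths$labels, cfg, "generate")
  }

  if ("edges" %in% stages) {
    if (!file.exists(paths$labels))
      stop("stage 'edges' needs the output of stage 'generate'", call. = FALSE)
    say("stage edges: one-voxel boundary class + sparse slices")
    labels <- read_stack(paths$labels, "labels")
    labels <- generate_edges(labels)
    labels <- sparsify_labels(labels)
    res$labels <- labels
    write_stack(labels, paths$edged, bits = 8L)
    write_sidecar(paths$edged, cfg, "edges")
  }

  if ("train" %in% stages) {
    if (!file.exists(paths$edged) || !file.exists(paths$input))
      stop("stage 'train' needs the outputs of stage 'edges'", call. = FALSE)
    say("stage train: fine-tuning")
    intensity <- read_stack(paths$input, "intensity")
    labels <- read_stack(paths$edged, "labels")
    side <- dim(labels)[1]
    pad <- cfg$synthetic$pad_offset
    sp <- split_train_val(side, cfg$sampling)
    tr <- make_sampler(intensity, labels, cfg$sampling, cfg$augment,
                       region = sp$train + pad, pad_offset = pad, augment = TRUE)
    vcfg <- cfg$sampling
    vcfg$oversample_prob <- 0 # foreground oversampling is a training-only device
    va <- make_sampler(intensity, labels, vcfg, cfg$augment,
                       region = sp$val + pad, pad_offset = pad, augment = FALSE)
    val_set <- sample_pairs(va, cfg$sampling$n_val_per_cube)
    model <- build_unet(cfg$model, seed = cfg$seed)
    fit <- train_unet(model, tr, val_set, cfg$training, cfg$weights)
    res$fit <- fit
    saveRDS(fit$model, paths$ckpt)
    utils::write.csv(fit$history, file.path(out_dir, "history.csv"),
                     row.names = FALSE)
    write_sidecar(paths$ckpt, cfg, "train")
  }

  if ("infer" %in% stages) {
    if (is.null(res$fit) && !file.exists(paths$ckpt))
      stop("stage 'infer' needs the checkpoint from stage 'train'", call. = FALSE)
    say("stage infer: sliding-window segmentation")
    model <- if (!is.null(res$fit)) res$fit$model else readRDS(paths$ckpt)
    intensity <- read_stack(paths$input, "intensity")
    geom <- window_geometry(cfg$model$in_side, cfg$inference$out_side)
    prob <- sliding_window_inference(normalize_intensity(intensity),
                                     model, geom, mode = "gaussian")
    res$prob <- prob
    write_stack(round(prob * 65535), paths$prob, bits = 16L)
    write_sidecar(paths$prob, cfg, "infer")
  }

  if ("evaluate" %in% stages) {
    if (!file.exists(paths$prob))
      stop("stage 'evaluate' needs the output of stage 'infer'", call. = FALSE)
    say("stage evaluate: edge-tolerant metrics on labeled slices")
    labels <- read_stack(paths$edged, "labels")
    prob <- read_stack(paths$prob, "intensity") / 65535
    # align: probability volume covers the label cube when pad == offset
    stopifnot(identical(dim(prob), dim(labels)))
    mask <- threshold_segmentation(prob, 0.5)
    rep <- compute_metrics(confusion_counts(mask, labels))
    res$metrics <- rep
    jsonlite::write_json(rep, paths$report, auto_unbox = TRUE, digits = NA)
    write_sidecar(paths$report, cfg, "evaluate")
  }
  invisible(res)
}
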