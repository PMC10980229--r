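#' Patch-sampling configuration
#'
#' @param in_side Input window side in voxels (the network sees `in_side`^3).
#' @param out_side Target side in voxels; the label target is the centered
#'   `out_side`^3 crop of the input footprint.
#' @param oversample_prob Probability that a draw anchors the window's
#'   top-left-back corner on an axon-labeled voxel instead of sampling the
#'   corner uniformly.
#' @param n_train_per_cube,n_val_per_cube Volumes drawn per cube per epoch.
#' @param val_strip Width in voxels of the strip at the far end of the x axis
#'   reserved for validation.
#' @return A `sample_config` list.
#' @export
sample_config <- function(in_side = 64L, out_side = 32L, oversample_prob = 0.3,
                          n_train_per_cube = 75L, n_val_per_cube = 25L,
                          val_strip = 64L) {
  stopifnot(oversample_prob >= 0, oversample_prob <= 1,
            out_side <= in_side, in_side %% 2 == 0, out_side %% 2 == 0)
  structure(list(in_side = as.integer(in_side), out_side = as.integer(out_side),
                 oversample_prob = oversample_prob,
                 n_train_per_cube = as.integer(n_train_per_cube),
                 n_val_per_cube = as.integer(n_val_per_cube),
                 val_strip = as.integer(val_strip)),
            class = "sample_config")
}

#' Partition a cube along x into training and validation regions
#'
#' The validation region is the strip of width `val_strip` at the far end of
#' the x axis; training uses the rest. Regions are half-open 0-based x extents
#' in the frame of side `cube_side`; samplers restricted to a region never
#' place a window across the boundary.
#'
#' @param cube_side Side of the sampling frame in voxels.
#' @param cfg A [sample_config()].
#' @return List with `train` and `val`, each `c(x_min, x_max)` (0-based,
#'   half-open).
#' @export
#' @examples
#' split_train_val(160, sample_config())  # train [0, 96), val [96, 160)
split_train_val <- function(cube_side, cfg = sample_config()) {
  if (cube_side <= cfg$val_strip)
    stop("cube x-extent (", cube_side, ") must exceed the validation strip (",
         cfg$val_strip, ")", call. = FALSE)
  list(train = c(0L, as.integer(cube_side - cfg$val_strip)),
       val = as.integer(c(cube_side - cfg$val_strip, cube_side)))
}

# axon-voxel corner candidates (0-based, sampling frame), restricted to the
# valid corner range per axis (xlim bounds the x corner so the window fits)
axon_corner_candidates <- function(labels, max_corner, xlim, pad_offset) {
  idx <- which(labels == label_codes()[["axon"]], arr.ind = TRUE)
  if (nrow(idx) == 0L) return(idx)
  corners <- idx - 1L + pad_offset # to 0-based frame coordinates
  keep <- corners[, 1] <= max_corner[1] & corners[, 2] <= max_corner[2] &
    corners[, 3] >= xlim[1] & corners[, 3] <= xlim[2]
  corners[keep, , drop = FALSE]
}

#' Draw a training-window corner, optionally oversampling axons
#'
#' With probability `1 - oversample_prob` the top-left-back corner is uniform
#' over the valid region (all positions where an `in_side`^3 window fits in
#' the frame); with probability `oversample_prob` the corner is drawn
#' uniformly from the axon-labeled voxels inside the valid region, so the
#' window is anchored on foreground. If no axon voxel lies in the valid
#' region the draw falls back to uniform sampling (warned once per session).
#'
#' Coordinates are 0-based in a cubic frame of side `cube_side`. When the
#' intensity cube is padded beyond the label cube, pass the padded side as
#' `cube_side` and the padding as `pad_offset` so axon label coordinates are
#' shifted into the padded frame.
#'
#' @param labels 3D integer label array (the label cube).
#' @param cube_side Side of the sampling frame; defaults to the label cube
#'   side plus `2 * pad_offset`.
#' @param cfg A [sample_config()].
#' @param region Optional 0-based half-open x extent (from
#'   [split_train_val()]) that the whole window must stay inside.
#' @param pad_offset Padding between label-cube and frame coordinates.
#' @return List with `corner` (length-3 integer, 0-based z, y, x) and
#'   `oversampled` (logical: was the corner taken from the axon list).
#' @export
sample_corner <- function(labels, cube_side = NULL, cfg = sample_config(),
                          region = NULL, pad_offset = 0L) {
  if (is.null(cube_side)) cube_side <- dim(labels)[1] + 2L * pad_offset
  if (cube_side < cfg$in_side)
    stop("cube side (", cube_side, ") smaller than the sampling window (",
         cfg$in_side, ")", call. = FALSE)
  max_corner <- rep(cube_side - cfg$in_side, 3L)
  xlim <- c(0L, max_corner[3])
  if (!is.null(region)) {
    xlim <- c(region[1], region[2] - cfg$in_side)
    if (xlim[2] < xlim[1])
      stop("region narrower than the sampling window", call. = FALSE)
  }
  oversampled <- runif(1) < cfg$oversample_prob
  if (oversampled) {
    cand <- axon_corner_candidates(labels, max_corner, xlim, pad_offset)
    if (nrow(cand) == 0L) {
      if (!isTRUE(.axontune$warned_no_axon)) {
        warning("no axon voxel in the valid corner region; falling back to uniform sampling",
                call. = FALSE)
        .axontune$warned_no_axon <- TRUE
      }
      oversampled <- FALSE
    } else {
      pick <- cand[sample.int(nrow(cand), 1L), ]
      return(list(corner = as.integer(pick), oversampled = TRUE))
    }
  }
  corner <- c(sample.int(max_corner[1] + 1L, 1L) - 1L,
              sample.int(max_corner[2] + 1L, 1L) - 1L,
              xlim[1] + sample.int(xlim[2] - xlim[1] + 1L, 1L) - 1L)
  list(corner = as.integer(corner), oversampled = oversampled)
}

#' Extract an aligned input/target pair at a window corner
#'
#' The input is the `in_side`^3 intensity crop at `corner`; the target is the
#' `out_side`^3 label crop centered within the input footprint (offset
#' `(in_side - out_side) / 2` on each axis), because the network predicts
#' axons only for the center of its input window.
#'
#' @param intensity 3D intensity array (possibly padded).
#' @param labels 3D label array (unpadded label cube).
#' @param corner 0-based corner in the intensity frame (see [sample_corner()]).
#' @param cfg A [sample_config()].
#' @param pad_offset Padding between the intensity frame and label cube.
#' @return List with `input` (`in_side`^3 numeric) and `target`
#'   (`out_side`^3 integer labels).
#' @export
extract_training_pair <- function(intensity, labels, corner,
                                  cfg = sample_config(), pad_offset = 0L) {
  d_in <- dim(intensity); d_lab <- dim(labels)
  if (any(corner < 0L) || any(corner + cfg$in_side > d_in))
    stop("input window at corner (", paste(corner, collapse = ","),
         ") exceeds the intensity volume", call. = FALSE)
  off <- crop_offset(cfg$in_side, cfg$out_side)
  tcorner <- corner + off - pad_offset
  if (any(tcorner < 0L) || any(tcorner + cfg$out_side > d_lab))
    stop("target window at label corner (", paste(tcorner, collapse = ","),
         ") exceeds the label volume", call. = FALSE)
  i1 <- seq_len(cfg$in_side)
  t1 <- seq_len(cfg$out_side)
  list(input = intensity[corner[1] + i1, corner[2] + i1, corner[3] + i1],
       target = labels[tcorner[1] + t1, tcorner[2] + t1, tcorner[3] + t1])
}

#' Normalize 16-bit intensities to \[0, 1\]
#'
#' Divides by the 16-bit maximum 65535 (raw intensity scale is retained,
#' rather than z-scoring, so absolute brightness stays informative).
#'
#' @param volume Numeric array of 16-bit intensities.
#' @return Numeric array in \[0, 1\].
#' @export
normalize_intensity <- function(volume) volume / 65535

#' Build a seeded pair sampler for a cube
#'
#' Wraps corner sampling, pair extraction, normalization and (for training)
#' augmentation into a draw function for the training loop. Validation
#' samplers are never augmented.
#'
#' @param intensity Padded intensity cube.
#' @param labels Label cube (sparse slices, edge class already generated).
#' @param cfg A [sample_config()].
#' @param aug An [augment_config()], used only when `augment = TRUE`.
#' @param region Optional x region from [split_train_val()] (in the padded
#'   frame when `pad_offset > 0`; see Details).
#' @param pad_offset Padding between intensity and label frames.
#' @param augment Apply spatial + intensity augmentation to each draw?
#' @details When `pad_offset > 0`, regions from [split_train_val()] computed
#'   on the label-cube side should be shifted by `pad_offset` into the padded
#'   frame before being passed here.
#' @return List with `draw()` (returns a list `input`, `target`,
#'   `oversampled`) and `n`, the number of volumes this cube contributes per
#'   epoch.
#' @export
make_sampler <- function(intensity, labels, cfg = sample_config(),
                         aug = augment_config(), region = NULL,
                         pad_offset = 0L, augment = TRUE) {
  cube_side <- dim(intensity)[1]
  force(labels); force(cfg); force(aug); force(region); force(augment)
  draw <- function() {
    sc <- sample_corner(labels, cube_side, cfg, region, pad_offset)
    pair <- extract_training_pair(intensity, labels, sc$corner, cfg, pad_offset)
    input <- normalize_intensity(pair$input)
    target <- pair$target
    if (augment) {
      sp <- augment_spatial(input, target, aug)
      input <- augment_intensity(sp$input, aug)
      target <- sp$target
    }
    list(input = input, target = target, oversampled = sc$oversampled)
  }
  list(draw = draw,
       n = if (augment) cfg$n_train_per_cube else cfg$n_val_per_cube)
}

#' Materialize n draws from a sampler
#' @param sampler A sampler from [make_sampler()].
#' @param n Number of pairs to draw.
#' @return List of `n` input/target pairs.
#' @export
sample_pairs <- function(sampler, n) lapply(seq_len(n), function(i) sampler$draw())
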