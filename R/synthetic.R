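#' Specification for a synthetic axon cube
#'
#' Describes a phantom that structurally mimics the study material: a cubic
#' label region of bright, tubular, curvilinear filaments (axon-like random
#' walks) on a noisy dark background, embedded in a larger padded intensity
#' cube so that sliding-window inference has realistic context, with optional
#' bright non-axon blobs standing in for imaging artifacts.
#'
#' Intensities are 16-bit. The defaults (background mean 300 sd 100, axon mean
#' 3000 sd 800) are plausible light-sheet values for labeled fibers on cleared
#' tissue background and are freely configurable. Density classes set the
#' filament count qualitatively: sparse 3, moderate 8, dense 20.
#'
#' @param label_side Side of the cubic label region in voxels.
#' @param pad_offset Padding added outward on every side of the intensity cube
#'   (a 160 label side with pad 14 gives a 188 intensity side).
#' @param density_class One of `"sparse"`, `"moderate"`, `"dense"`; sets
#'   `n_filaments` when that is `NULL`.
#' @param n_filaments Number of filaments; overrides `density_class`.
#' @param radius_range Tube radius range in voxels; each filament draws one.
#' @param filament_step Random-walk step length in voxels.
#' @param curvature Scale of the Gaussian perturbation applied to the walk
#'   direction each step (unitless; larger = wigglier fibers).
#' @param axon_intensity_mean,axon_intensity_sd Foreground intensity Gaussian.
#' @param background_intensity_mean,background_intensity_sd Background
#'   intensity Gaussian. The axon mean must exceed the background mean.
#' @param n_artifacts Number of bright ellipsoidal artifact blobs.
#' @param seed Integer seed; generation is a pure function of the spec.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(label_side = 160L, pad_offset = 14L,
                           density_class = c("moderate", "sparse", "dense"),
                           n_filaments = NULL,
                           radius_range = c(1.5, 3),
                           filament_step = 2,
                           curvature = 0.25,
                           axon_intensity_mean = 3000, axon_intensity_sd = 800,
                           background_intensity_mean = 300,
                           background_intensity_sd = 100,
                           n_artifacts = 0L,
                           seed = 1L) {
  density_class <- match.arg(density_class)
  if (is.null(n_filaments))
    n_filaments <- c(sparse = 3L, moderate = 8L, dense = 20L)[[density_class]]
  spec <- list(label_side = as.integer(label_side),
               pad_offset = as.integer(pad_offset),
               density_class = density_class,
               n_filaments = as.integer(n_filaments),
               radius_range = radius_range,
               filament_step = filament_step,
               curvature = curvature,
               axon_intensity_mean = axon_intensity_mean,
               axon_intensity_sd = axon_intensity_sd,
               background_intensity_mean = background_intensity_mean,
               background_intensity_sd = background_intensity_sd,
               n_artifacts = as.integer(n_artifacts),
               seed = as.integer(seed))
  for (f in c("label_side", "filament_step"))
    if (spec[[f]] <= 0) stop("synthetic_spec: field '", f, "' must be positive",
                             call. = FALSE)
  if (spec$pad_offset < 0) stop("synthetic_spec: field 'pad_offset' must be >= 0",
                                call. = FALSE)
  if (spec$n_filaments < 0) stop("synthetic_spec: field 'n_filaments' must be >= 0",
                                 call. = FALSE)
  if (any(radius_range <= 0)) stop("synthetic_spec: field 'radius_range' must be positive",
                                   call. = FALSE)
  if (axon_intensity_mean <= background_intensity_mean)
    stop("synthetic_spec: axon_intensity_mean must exceed background_intensity_mean",
         call. = FALSE)
  structure(spec, class = "synthetic_spec")
}

# integer offsets of a Euclidean ball of the given radius
ball_offsets <- function(radius) {
  r <- ceiling(radius)
  g <- as.matrix(expand.grid(-r:r, -r:r, -r:r))
  g[rowSums(g^2) <= radius^2, , drop = FALSE]
}

# one random-walk filament: matrix of center points (rows), real coordinates
walk_filament <- function(side, step, curvature, max_steps) {
  pos <- runif(3, 1, side)
  dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
  pts <- matrix(NA_real_, max_steps, 3)
  for (i in seq_len(max_steps)) {
    pts[i, ] <- pos
    dir <- dir + curvature * rnorm(3)
    dir <- dir / sqrt(sum(dir^2))
    pos <- pos + step * dir
    if (any(pos < -3) || any(pos > side + 3)) return(pts[seq_len(i), , drop = FALSE])
  }
  pts
}

# rasterize tube voxels around the given centers into a logical mask (in place)
stamp_tube <- function(mask, centers, radius) {
  d <- dim(mask)
  offs <- ball_offsets(radius)
  for (i in seq_len(nrow(centers))) {
    ctr <- round(centers[i, ])
    v <- sweep(offs, 2, ctr, "+")
    keep <- v[, 1] >= 1 & v[, 1] <= d[1] & v[, 2] >= 1 & v[, 2] <= d[2] &
      v[, 3] >= 1 & v[, 3] <= d[3]
    if (!any(keep)) next
    v <- v[keep, , drop = FALSE]
    mask[v[, 1] + d[1] * (v[, 2] - 1) + d[1] * d[2] * (v[, 3] - 1)] <- TRUE
  }
  mask
}

#' Generate a synthetic intensity/label cube pair
#'
#' Filaments are fixed-step 3D random walks with Gaussian-perturbed direction,
#' rasterized as Euclidean-distance tubes of per-filament radius. They are
#' generated jointly over the padded extent (not pasted into reflected or zero
#' padding), so fibers run naturally into the context shell that inference
#' windows see. Tube voxels draw from the axon intensity Gaussian, everything
#' else from the background Gaussian; values are clipped to \[0, 65535\] and
#' rounded. Identical specs (including seed) give bit-identical output.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `intensity` (numeric 3D array of side
#'   `label_side + 2 * pad_offset`, 16-bit values), `mask` (logical 3D array of
#'   side `label_side`, TRUE at axon voxels), `artifact_mask` (same shape, TRUE
#'   at artifact voxels, absent axons win ties), and `spec`.
#' @export
#' @examples
#' cube <- generate_axon_cube(synthetic_spec(label_side = 40, pad_offset = 4,
#'                                           density_class = "sparse", seed = 7))
#' dim(cube$intensity)  # 48 48 48
#' mean(cube$mask)      # axon voxel fraction
generate_axon_cube <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  side <- spec$label_side + 2L * spec$pad_offset
  with_seed(spec$seed, {
    mask_pad <- array(FALSE, c(side, side, side))
    art_pad <- array(FALSE, c(side, side, side))
    max_steps <- ceiling(2.5 * side / spec$filament_step)
    if (spec$n_filaments > 0) {
      for (f in seq_len(spec$n_filaments)) {
        radius <- runif(1, spec$radius_range[1], spec$radius_range[2])
        pts <- walk_filament(side, spec$filament_step, spec$curvature, max_steps)
        mask_pad <- stamp_tube(mask_pad, pts, radius)
      }
    }
    if (spec$n_artifacts > 0) {
      for (a in seq_len(spec$n_artifacts)) {
        ctr <- runif(3, 1, side)
        rad <- runif(3, 3, 8)
        ax <- seq_len(side)
        d2 <- outer(outer((ax - ctr[1])^2 / rad[1]^2, (ax - ctr[2])^2 / rad[2]^2, "+"),
                    (ax - ctr[3])^2 / rad[3]^2, "+")
        art_pad <- art_pad | (d2 <= 1)
      }
      art_pad <- art_pad & !mask_pad
    }
    n <- side^3
    intensity <- rnorm(n, spec$background_intensity_mean, spec$background_intensity_sd)
    fg <- which(mask_pad | art_pad)
    intensity[fg] <- rnorm(length(fg), spec$axon_intensity_mean, spec$axon_intensity_sd)
    intensity <- round(pmin(pmax(intensity, 0), 65535))
    dim(intensity) <- c(side, side, side)
    ctr_idx <- seq_len(spec$label_side) + spec$pad_offset
    list(intensity = intensity,
         mask = mask_pad[ctr_idx, ctr_idx, ctr_idx],
         artifact_mask = art_pad[ctr_idx, ctr_idx, ctr_idx],
         spec = spec)
  })
}

#' Dense label volume from generator masks
#'
#' Turns the axon (and optional artifact) masks of [generate_axon_cube()] into
#' a fully annotated label volume: background everywhere, axon/artifact where
#' masked. Edge voxels are added separately with [generate_edges()].
#'
#' @param cube Output of [generate_axon_cube()].
#' @return 3D integer label array of side `label_side`.
#' @export
dense_labels <- function(cube) {
  codes <- label_codes()
  labels <- array(codes[["background"]], dim(cube$mask))
  labels[cube$artifact_mask] <- codes[["artifact"]]
  labels[cube$mask] <- codes[["axon"]]
  labels
}

#' Restrict labels to periodically annotated slices
#'
#' Keeps annotation only on z-slices at 1-based indices `start`,
#' `start + period`, `start + 2 * period`, ...; every other slice becomes
#' wholly unlabeled. The default pattern (every 20th slice starting at the
#' 15th) reproduces sparse expert annotation: a 160-slice cube retains the 8
#' slices 15, 35, ..., 155.
#'
#' @param labels 3D integer label array.
#' @param period Slice period (>= 1).
#' @param start First annotated slice, 1-based (>= 1).
#' @return Label array with non-retained slices set to unlabeled.
#' @export
sparsify_labels <- function(labels, period = 20L, start = 15L) {
  stopifnot(start >= 1, period >= 1)
  depth <- dim(labels)[1]
  if (start > depth) {
    warning("first annotated slice (", start, ") is beyond the volume depth (",
            depth, "); all slices unlabeled", call. = FALSE)
    keep <- integer(0)
  } else {
    keep <- seq.int(start, depth, by = period)
  }
  out <- array(label_codes()[["unlabeled"]], dim(labels))
  if (length(keep)) out[keep, , ] <- labels[keep, , ]
  out
}

#' Z indices of annotated slices
#' @param depth Volume depth in slices.
#' @inheritParams sparsify_labels
#' @return Integer vector of 1-based slice indices.
#' @export
labeled_slice_indices <- function(depth, period = 20L, start = 15L) {
  if (start > depth) return(integer(0))
  as.integer(seq.int(start, depth, by = period))
}
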