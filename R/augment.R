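#' Augmentation configuration
#'
#' One spatial transform (flip decisions, rotation angles, one elastic
#' displacement field) is drawn per training pair and applied identically to
#' the image and its labels, so the two stay co-registered. Intensity
#' augmentation (random gain and offset) applies to the image only, after
#' normalization. Validation data is never augmented.
#'
#' Magnitude defaults are conventional for fibrous 3D data and configurable:
#' rotations up to ±15° per axis, elastic displacement of ~8 voxels smoothed
#' over ~4 voxels, gain in \[0.8, 1.2\] and offset in \[-0.05, 0.05\]
#' normalized units.
#'
#' @param rotate Enable random rotations about all three axes.
#' @param rotate_max Maximum rotation angle per axis, radians.
#' @param elastic Enable elastic deformation.
#' @param elastic_alpha Displacement magnitude, voxels (sd of control-point
#'   displacements).
#' @param elastic_sigma Smoothness scale of the displacement field, voxels.
#' @param flip Enable independent flips along each axis with probability 1/2.
#' @param intensity_scale Multiplicative gain interval.
#' @param intensity_shift Additive offset interval (normalized units).
#' @return An `augment_config` list (`augment_validation` is fixed `FALSE`).
#' @export
augment_config <- function(rotate = TRUE, rotate_max = pi / 12,
                           elastic = FALSE, elastic_alpha = 8, elastic_sigma = 4,
                           flip = TRUE,
                           intensity_scale = c(0.8, 1.2),
                           intensity_shift = c(-0.05, 0.05)) {
  stopifnot(all(intensity_scale > 0), rotate_max >= 0,
            elastic_alpha >= 0, elastic_sigma > 0)
  structure(list(rotate = rotate, rotate_max = rotate_max,
                 elastic = elastic, elastic_alpha = elastic_alpha,
                 elastic_sigma = elastic_sigma, flip = flip,
                 intensity_scale = intensity_scale,
                 intensity_shift = intensity_shift,
                 augment_validation = FALSE),
            class = "augment_config")
}

rotation_matrix <- function(angles) {
  cx <- cos(angles[1]); sx <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cz <- cos(angles[3]); sz <- sin(angles[3])
  rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  rz %*% ry %*% rx
}

# trilinear interpolation of vol at coords (n x 3 matrix, 1-based, real);
# coordinates outside the volume return `fill`
interp_trilinear <- function(vol, coords, fill) {
  d <- dim(vol)
  out <- rep(fill, nrow(coords))
  inside <- coords[, 1] >= 1 & coords[, 1] <= d[1] &
    coords[, 2] >= 1 & coords[, 2] <= d[2] &
    coords[, 3] >= 1 & coords[, 3] <= d[3]
  if (!any(inside)) return(out)
  p <- coords[inside, , drop = FALSE]
  f0 <- pmin(floor(p), rep(d, each = nrow(p)) - 1)
  fr <- p - f0
  acc <- 0
  for (b1 in 0:1) for (b2 in 0:1) for (b3 in 0:1) {
    w <- (if (b1) fr[, 1] else 1 - fr[, 1]) *
      (if (b2) fr[, 2] else 1 - fr[, 2]) *
      (if (b3) fr[, 3] else 1 - fr[, 3])
    idx <- (f0[, 1] + b1) + d[1] * (f0[, 2] + b2 - 1) + d[1] * d[2] * (f0[, 3] + b3 - 1)
    acc <- acc + w * vol[idx]
  }
  out[inside] <- acc
  out
}

# nearest-neighbor lookup; outside -> fill
interp_nearest <- function(vol, coords, fill) {
  d <- dim(vol)
  p <- round(coords)
  out <- rep(fill, nrow(coords))
  inside <- p[, 1] >= 1 & p[, 1] <= d[1] & p[, 2] >= 1 & p[, 2] <= d[2] &
    p[, 3] >= 1 & p[, 3] <= d[3]
  idx <- p[inside, 1] + d[1] * (p[inside, 2] - 1) + d[1] * d[2] * (p[inside, 3] - 1)
  out[inside] <- vol[idx]
  out
}

# smooth random displacement field over an n^3 grid: control points with
# spacing ~4*sigma voxels, N(0, alpha) displacements, trilinearly upsampled
elastic_field <- function(n, alpha, sigma) {
  g <- max(2L, as.integer(ceiling(n / (4 * sigma))) + 1L)
  ctrl <- array(rnorm(g^3 * 3, 0, alpha), c(g, g, g, 3))
  ax <- seq(1, g, length.out = n)
  coords <- as.matrix(expand.grid(ax, ax, ax))
  vapply(1:3, function(k) interp_trilinear(ctrl[, , , k], coords, 0),
         numeric(n^3))
}

#' Spatially augment an aligned image/label pair
#'
#' Draws one transform — per-axis flip decisions, rotation angles, an elastic
#' displacement field — and applies it identically to the input window and its
#' center-cropped label target, both expressed in the input window's frame, so
#' co-located structures stay co-located. The image is resampled trilinearly;
#' labels use nearest-neighbor (no new codes can appear). Voxels pulled from
#' outside the original field of view become the image mean (image) and
#' unlabeled (labels). Flips are exact array reversals.
#'
#' @param input Numeric 3D array (side `in_side`, normalized intensities).
#' @param target Integer 3D label array (side `out_side`, centered in the
#'   input footprint).
#' @param cfg An [augment_config()].
#' @param draws Optional list of pre-drawn transform parameters (`flips`,
#'   `angles`, `disp`), e.g. the `draws` element of a previous call, to
#'   reapply the identical transform.
#' @return List with `input`, `target`, and `draws` (the sampled transform).
#' @export
augment_spatial <- function(input, target, cfg = augment_config(), draws = NULL) {
  n <- dim(input)[1]
  m <- dim(target)[1]
  off <- crop_offset(n, m)
  if (is.null(draws)) {
    draws <- list(
      flips = if (cfg$flip) runif(3) < 0.5 else rep(FALSE, 3),
      angles = if (cfg$rotate) runif(3, -cfg$rotate_max, cfg$rotate_max) else NULL,
      disp = if (cfg$elastic && cfg$elastic_alpha > 0)
        elastic_field(n, cfg$elastic_alpha, cfg$elastic_sigma) else NULL
    )
  }
  if (draws$flips[1]) { input <- input[n:1, , ]; target <- target[m:1, , ] }
  if (draws$flips[2]) { input <- input[, n:1, ]; target <- target[, m:1, ] }
  if (draws$flips[3]) { input <- input[, , n:1]; target <- target[, , m:1] }
  if (!is.null(draws$angles) || !is.null(draws$disp)) {
    ctr <- (n + 1) / 2
    ax <- seq_len(n)
    q <- as.matrix(expand.grid(ax, ax, ax)) # input-frame voxel positions
    src <- q
    if (!is.null(draws$angles)) {
      rinv <- t(rotation_matrix(draws$angles))
      src <- sweep(sweep(src, 2, ctr) %*% t(rinv), 2, ctr, "+")
    }
    if (!is.null(draws$disp)) src <- src + draws$disp
    fill <- mean(input)
    input <- array(interp_trilinear(input, src, fill), dim(input))
    # target voxels live at input-frame positions (j + off); pick those rows
    keep <- q[, 1] > off & q[, 1] <= off + m &
      q[, 2] > off & q[, 2] <= off + m &
      q[, 3] > off & q[, 3] <= off + m
    tsrc <- src[keep, , drop = FALSE] - off # to target-frame coordinates
    target <- array(as.integer(interp_nearest(target, tsrc,
                                              label_codes()[["unlabeled"]])),
                    dim(target))
  }
  list(input = input, target = target, draws = draws)
}

#' Randomly rescale and shift image intensities
#'
#' Training-only intensity augmentation: `input * s + c` with gain `s` and
#' offset `c` drawn uniformly from the configured intervals.
#'
#' @param input Normalized numeric array.
#' @param cfg An [augment_config()].
#' @return The transformed array, with the drawn `scale` and `shift` attached
#'   as attributes.
#' @export
augment_intensity <- function(input, cfg = augment_config()) {
  s <- runif(1, cfg$intensity_scale[1], cfg$intensity_scale[2])
  c0 <- runif(1, cfg$intensity_shift[1], cfg$intensity_shift[2])
  out <- input * s + c0
  attr(out, "scale") <- s
  attr(out, "shift") <- c0
  out
}
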