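#' Sliding-window geometry
#'
#' The network consumes an `in_side`^3 window and commits only to the centered
#' `out_side`^3 region, so the segmented output of a volume is smaller than
#' the input by `offset = (in_side - out_side) / 2` on every side. With the
#' default inference geometry (64 in, 36 out) the offset is 14, and a 188^3
#' padded input yields a 160^3 segmented output.
#'
#' @param in_side Input window side.
#' @param out_side Output window side (<= `in_side`, even difference).
#' @param stride Spacing between successive output tiles; defaults per mode
#'   in [sliding_window_inference()] (`out_side` for uniform tiling,
#'   `out_side / 2` for gaussian overlap).
#' @return A `window_geometry` list with the derived `offset`.
#' @export
window_geometry <- function(in_side = 64L, out_side = 36L, stride = NULL) {
  in_side <- as.integer(in_side); out_side <- as.integer(out_side)
  off <- crop_offset(in_side, out_side)
  if (!is.null(stride)) {
    stride <- as.integer(stride)
    stopifnot(stride >= 1, stride <= out_side)
  }
  structure(list(in_side = in_side, out_side = out_side, offset = off,
                 stride = stride),
            class = "window_geometry")
}

#' Segmented output extent of a volume
#'
#' @param input_shape Integer vector of input dimensions (each >= `in_side`).
#' @param geom A [window_geometry()].
#' @return Integer vector: `input_shape - 2 * offset`.
#' @export
#' @examples
#' output_extent(c(188, 188, 188), window_geometry(64, 36)) # 160 160 160
output_extent <- function(input_shape, geom = window_geometry()) {
  if (any(input_shape < geom$in_side))
    stop("every input axis must be >= the window side (", geom$in_side, ")",
         call. = FALSE)
  as.integer(input_shape - 2L * geom$offset)
}

#' Gaussian stitching weights for one output window
#'
#' A separable isotropic Gaussian over the `out_side`^3 output grid, centered
#' on the window center and normalized so the center value is 1, floored at a
#' small positive `eps`. Overlapping window predictions multiplied by this
#' matrix count more where they are central (well-contextualized) and less
#' near the window edge.
#'
#' @param out_side Output window side.
#' @param sigma Gaussian standard deviation in voxels; default `out_side / 8`.
#' @param eps Positive floor applied to the weights.
#' @return 3D array of positive weights, maximum at the center.
#' @export
gaussian_matrix <- function(out_side, sigma = out_side / 8, eps = 1e-8) {
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  ctr <- (out_side + 1) / 2
  g1 <- exp(-((seq_len(out_side) - ctr)^2) / (2 * sigma^2))
  w <- outer(outer(g1, g1), g1)
  pmax(w / max(w), eps)
}

# tile corners along one axis: 0-based, final tile snapped flush to the edge
tile_starts <- function(extent, out_side, stride) {
  if (extent == out_side) return(0L)
  s <- seq.int(0L, extent - out_side, by = stride)
  if (s[length(s)] != extent - out_side) s <- c(s, extent - out_side)
  as.integer(s)
}

#' Sliding-window segmentation of a full volume
#'
#' Tiles the (normalized) volume with `in_side`^3 windows, predicts each
#' window's `out_side`^3 center with `model`, and stitches the predictions
#' into an `output_extent()`-sized probability volume. In `"uniform"` mode the
#' tiles abut (stride `out_side`, every voxel covered once except where the
#' final edge-snapped tile overlaps, resolved by plain averaging). In
#' `"gaussian"` mode tiles overlap by half a window and each prediction is
#' multiplied by [gaussian_matrix()] before accumulation; every voxel's value
#' is the Gaussian-weighted mean of all windows covering it.
#'
#' @param volume Normalized 3D intensity array (every axis >= `in_side`).
#' @param model An `axon_unet`, or any `function(window)` returning an
#'   `out_side`^3 prediction array (useful for stubs and oracles).
#' @param geom A [window_geometry()].
#' @param mode `"gaussian"` or `"uniform"`.
#' @param sigma Gaussian sigma for `"gaussian"` mode.
#' @return Probability volume of dimension `output_extent(dim(volume), geom)`.
#' @export
sliding_window_inference <- function(volume, model, geom = window_geometry(),
                                     mode = c("gaussian", "uniform"),
                                     sigma = geom$out_side / 8) {
  mode <- match.arg(mode)
  d <- dim(volume)
  ext <- output_extent(d, geom)
  predict_fn <- if (inherits(model, "axon_unet")) {
    function(win) unet_predict(model, win, geom$out_side)
  } else model
  stride <- geom$stride
  if (is.null(stride))
    stride <- if (mode == "uniform") geom$out_side else max(1L, geom$out_side %/% 2L)
  wmat <- if (mode == "gaussian") gaussian_matrix(geom$out_side, sigma)
          else array(1, rep(geom$out_side, 3))
  num <- array(0, ext); den <- array(0, ext)
  s1 <- tile_starts(ext[1], geom$out_side, stride)
  s2 <- tile_starts(ext[2], geom$out_side, stride)
  s3 <- tile_starts(ext[3], geom$out_side, stride)
  iwin <- seq_len(geom$in_side)
  iout <- seq_len(geom$out_side)
  for (c1 in s1) for (c2 in s2) for (c3 in s3) {
    win <- volume[c1 + iwin, c2 + iwin, c3 + iwin]
    pred <- predict_fn(win)
    num[c1 + iout, c2 + iout, c3 + iout] <-
      num[c1 + iout, c2 + iout, c3 + iout] + wmat * pred
    den[c1 + iout, c2 + iout, c3 + iout] <-
      den[c1 + iout, c2 + iout, c3 + iout] + wmat
  }
  stopifnot(all(den > 0)) # complete coverage
  num / den
}

#' Threshold a probability volume into a binary axon mask
#'
#' Voxels strictly above `tau` are positive (a probability of exactly 0.5 is
#' negative at the default threshold).
#'
#' @param prob Probability array in \[0, 1\].
#' @param tau Threshold.
#' @return Logical array.
#' @export
threshold_segmentation <- function(prob, tau = 0.5) prob > tau
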