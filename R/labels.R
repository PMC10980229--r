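#' Voxel label codes
#'
#' Label volumes are 3D integer arrays (axis order z, y, x) whose voxels carry
#' one of five class codes. `unlabeled` marks whole slices that carry no
#' annotation; those slices are excluded from both the training loss and the
#' evaluation metrics. The `edge` class is a one-voxel boundary band around
#' axons whose misclassification is deliberately down-weighted.
#'
#' @return Named integer vector mapping class names to codes.
#' @export
#' @examples
#' label_codes()
label_codes <- function() {
  c(unlabeled = 0L, background = 1L, axon = 2L, edge = 3L, artifact = 4L)
}

#' Edge-generation configuration
#'
#' @param connectivity `"2d8"` marks the in-plane 8-neighborhood of each axon
#'   voxel (edges are generated slice by slice, matching annotation that lives
#'   on isolated z-slices); `"3d26"` uses the full 26-neighborhood in 3D.
#'   The boundary band is always one voxel thick.
#' @return An `edge_config` list.
#' @export
edge_config <- function(connectivity = c("2d8", "3d26")) {
  structure(list(connectivity = match.arg(connectivity), thickness = 1L),
            class = "edge_config")
}

# logical array shifted by (a1, a2, a3), zero-filled at the boundary
shift_mask <- function(m, a1, a2, a3) {
  d <- dim(m)
  out <- array(FALSE, d)
  src <- function(n, a) seq.int(max(1L, 1L + a), min(n, n + a))
  s1 <- src(d[1], a1); s2 <- src(d[2], a2); s3 <- src(d[3], a3)
  if (!length(s1) || !length(s2) || !length(s3)) return(out)
  out[s1 - a1, s2 - a2, s3 - a3] <- m[s1, s2, s3]
  out
}

# union of shifted copies of `m` over the given offsets (rows of `offs`)
neighbor_mask <- function(m, offs) {
  out <- array(FALSE, dim(m))
  for (i in seq_len(nrow(offs)))
    out <- out | shift_mask(m, offs[i, 1], offs[i, 2], offs[i, 3])
  out
}

edge_offsets <- function(connectivity) {
  if (connectivity == "2d8") {
    g <- expand.grid(a1 = 0L, a2 = -1:1, a3 = -1:1)
  } else {
    g <- expand.grid(a1 = -1:1, a2 = -1:1, a3 = -1:1)
  }
  as.matrix(g[!(g$a1 == 0 & g$a2 == 0 & g$a3 == 0), , drop = FALSE])
}

#' Generate the one-voxel axon edge class
#'
#' Every labeled, non-axon voxel adjacent to an axon voxel (per the chosen
#' connectivity) is recoded as `edge`. Axon voxels and unlabeled slices are
#' never overwritten; background and artifact voxels adjacent to axons both
#' become edge, since the edge class exists to absorb boundary ambiguity
#' regardless of the neighbor's class.
#'
#' @param labels 3D integer label array (codes as in [label_codes()]), with no
#'   pre-existing edge voxels.
#' @param cfg An [edge_config()].
#' @return The label array with edge voxels added.
#' @export
generate_edges <- function(labels, cfg = edge_config()) {
  codes <- label_codes()
  if (any(labels == codes[["edge"]]))
    stop("labels already contain edge voxels; refusing to re-apply edge generation",
         call. = FALSE)
  axon <- labels == codes[["axon"]]
  nb <- neighbor_mask(axon, edge_offsets(cfg$connectivity))
  turn <- nb & !axon & labels != codes[["unlabeled"]]
  labels[turn] <- codes[["edge"]]
  labels
}

#' Validate a label volume
#'
#' Checks the two label invariants: every voxel code is one of the five known
#' codes, and every z-slice is either entirely unlabeled or contains no
#' unlabeled voxels ("slice-atomic" annotation).
#'
#' @param labels 3D integer label array.
#' @return A list with `ok` (logical), `out_of_range` (data.frame of z, y, x,
#'   code for offending voxels) and `mixed_slices` (z indices of slices mixing
#'   unlabeled with labeled voxels).
#' @export
validate_labels <- function(labels) {
  codes <- label_codes()
  bad <- which(array(!(labels %in% codes), dim(labels)), arr.ind = TRUE)
  out_of_range <- data.frame(
    z = bad[, 1], y = bad[, 2], x = bad[, 3],
    code = labels[bad[, , drop = FALSE]]
  )
  d <- dim(labels)
  mixed <- integer(0)
  for (z in seq_len(d[1])) {
    sl <- labels[z, , ]
    n0 <- sum(sl == codes[["unlabeled"]])
    if (n0 > 0 && n0 < length(sl)) mixed <- c(mixed, z)
  }
  list(ok = nrow(out_of_range) == 0L && length(mixed) == 0L,
       out_of_range = out_of_range, mixed_slices = mixed)
}
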