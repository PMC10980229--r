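# Independent oracles, deliberately written as scalar loops so they share no
# code path with the vectorized implementations they check.

# per-window, per-voxel scalar re-computation of weighted-overlap stitching
stitch_oracle <- function(volume, predict_fn, geom, wmat, stride) {
  ext <- dim(volume) - 2L * geom$offset
  num <- array(0, ext); den <- array(0, ext)
  starts <- lapply(ext, function(e) axontune:::tile_starts(e, geom$out_side, stride))
  for (c1 in starts[[1]]) for (c2 in starts[[2]]) for (c3 in starts[[3]]) {
    win <- volume[c1 + seq_len(geom$in_side), c2 + seq_len(geom$in_side),
                  c3 + seq_len(geom$in_side)]
    pred <- predict_fn(win)
    for (i in seq_len(geom$out_side)) for (j in seq_len(geom$out_side))
      for (k in seq_len(geom$out_side)) {
        num[c1 + i, c2 + j, c3 + k] <- num[c1 + i, c2 + j, c3 + k] +
          wmat[i, j, k] * pred[i, j, k]
        den[c1 + i, c2 + j, c3 + k] <- den[c1 + i, c2 + j, c3 + k] + wmat[i, j, k]
      }
  }
  num / den
}

# scalar per-voxel confusion counting
confusion_oracle <- function(pred, labels) {
  tp <- tn <- fp <- fn <- ea <- 0L
  for (i in seq_along(labels)) {
    l <- labels[i]; p <- pred[i] > 0
    if (l == 0L) next
    if (l == 2L) { if (p) tp <- tp + 1L else fn <- fn + 1L }
    else {
      if (p) { fp <- fp + 1L; if (l == 3L) ea <- ea + 1L }
      else tn <- tn + 1L
    }
  }
  list(TP = tp, TN = tn, FP = fp, FN = fn, EA = ea)
}
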