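# Shared fixtures: all synthetic, generated in code at test time.

# small fully-annotated label volume with a few hand-placed axon voxels
tiny_labels <- function(d = c(7, 7, 7), axons = rbind(c(4, 4, 4))) {
  lab <- array(label_codes()[["background"]], d)
  for (i in seq_len(nrow(axons))) lab[axons[i, 1], axons[i, 2], axons[i, 3]] <-
    label_codes()[["axon"]]
  lab
}

# small cube + sparse edge-class labels via the standard preprocessing chain
make_test_cube <- function(label_side = 64, pad_offset = 8, period = 10,
                           start = 5, ...) {
  cube <- generate_axon_cube(synthetic_spec(label_side = label_side,
                                            pad_offset = pad_offset, ...))
  labels <- sparsify_labels(generate_edges(dense_labels(cube)),
                            period = period, start = start)
  list(int = cube$intensity, lab = labels, cube = cube)
}

# evaluation pairs whose target window is centered on an axon voxel, so the
# target always contains annotated foreground
centered_pairs <- function(tc, n, cfg, pad) {
  ax <- which(tc$lab == label_codes()[["axon"]], arr.ind = TRUE)
  side <- dim(tc$int)[1]
  pick <- ax[sample.int(nrow(ax), n, replace = nrow(ax) < n), , drop = FALSE]
  lapply(seq_len(n), function(i) {
    corner <- pmin(pmax(pick[i, ] - 1 + pad - cfg$in_side %/% 2, 0),
                   side - cfg$in_side)
    pr <- extract_training_pair(tc$int, tc$lab, as.integer(corner), cfg, pad)
    pr$input <- normalize_intensity(pr$input)
    pr
  })
}

# random label volume exercising every code, slice-atomic by construction
random_labels <- function(d = c(8, 8, 8), p_unlabeled = 0.3) {
  lab <- array(sample(1:4, prod(d), replace = TRUE,
                      prob = c(0.7, 0.15, 0.1, 0.05)), d)
  drop_z <- which(runif(d[1]) < p_unlabeled)
  if (length(drop_z)) lab[drop_z, , ] <- label_codes()[["unlabeled"]]
  lab
}
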