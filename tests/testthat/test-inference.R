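test_that("window offset arithmetic matches the inference geometry", {
  g <- window_geometry(64, 36)
  expect_identical(g$offset, 14L)
  expect_identical(output_extent(c(188, 188, 188), g), rep(160L, 3))
  expect_identical(output_extent(c(64, 64, 64), g), rep(36L, 3))
  gid <- window_geometry(32, 32)
  expect_identical(output_extent(c(50, 60, 70), gid), c(50L, 60L, 70L))
  expect_error(output_extent(c(63, 188, 188), g), ">=")
  expect_error(window_geometry(64, 33), "even")
})

test_that("the Gaussian weight matrix is center-peaked, symmetric, positive", {
  for (os in c(8, 9)) {
    w <- gaussian_matrix(os)
    expect_true(all(w > 0))
    ctr <- ceiling((os + 1) / 2)
    expect_equal(max(w), w[ctr, ctr, ctr])
    expect_gte(w[ctr, ctr, ctr], w[1, 1, 1])
    expect_equal(w, w[os:1, , ]); expect_equal(w, w[, os:1, ])
    expect_equal(w, w[, , os:1])
  }
  # huge sigma: weights flatten toward uniform
  wflat <- gaussian_matrix(8, sigma = 1000 * 8)
  expect_lt(max(wflat) / min(wflat), 1 + 1e-6)
  expect_error(gaussian_matrix(8, sigma = 0), "positive")
})

test_that("a constant stub model yields a constant stitched volume", {
  vol <- array(runif(40^3), c(40, 40, 40))
  g <- window_geometry(16, 8)
  stub <- function(win) array(0.37, rep(8L, 3))
  for (mode in c("uniform", "gaussian")) {
    out <- sliding_window_inference(vol, stub, g, mode = mode)
    expect_identical(dim(out), rep(32L, 3)) # 40 - 2 * 4
    expect_equal(out, array(0.37, rep(32L, 3)), tolerance = 1e-12)
  }
})

test_that("gaussian stitching matches the brute-force per-voxel oracle", {
  set.seed(1)
  vol <- array(runif(36^3), c(36, 36, 36))
  g <- window_geometry(16, 8)
  # window-dependent stub so that overlapping windows genuinely disagree
  stub <- function(win) {
    ctr <- win[5:12, 5:12, 5:12]
    1 / (1 + exp(-(ctr - mean(win) * 2)))
  }
  wg <- gaussian_matrix(8)
  fast <- sliding_window_inference(vol, stub, g, mode = "gaussian")
  slow <- stitch_oracle(vol, stub, g, wg, stride = 4L)
  expect_lt(max(abs(fast - slow)), 1e-6)
  # uniform mode against the same oracle with all-ones weights
  fastu <- sliding_window_inference(vol, stub, g, mode = "uniform")
  slowu <- stitch_oracle(vol, stub, g, array(1, rep(8, 3)), stride = 8L)
  expect_lt(max(abs(fastu - slowu)), 1e-6)
})

test_that("stitched values stay within the covering predictions' range", {
  set.seed(2)
  vol <- array(runif(28^3), c(28, 28, 28))
  g <- window_geometry(12, 8)
  stub <- function(win) array(mean(win), rep(8L, 3)) # one constant per window
  out <- sliding_window_inference(vol, stub, g, mode = "gaussian")
  consts <- c()
  for (c1 in axontune:::tile_starts(24, 8, 4))
    for (c2 in axontune:::tile_starts(24, 8, 4))
      for (c3 in axontune:::tile_starts(24, 8, 4))
        consts <- c(consts, mean(vol[c1 + 1:12, c2 + 1:12, c3 + 1:12]))
  expect_gte(min(out), min(consts) - 1e-12)
  expect_lte(max(out), max(consts) + 1e-12)
})

test_that("inference geometry is consistent with the training crop", {
  cfg <- sample_config(in_side = 16, out_side = 8)
  int <- array(runif(16^3), c(16, 16, 16))
  lab <- array(1L, c(16, 16, 16))
  pr <- extract_training_pair(int, lab, c(0L, 0L, 0L), cfg)
  g <- window_geometry(16, 8)
  expect_identical(dim(pr$target), output_extent(dim(pr$input), g))
})

test_that("thresholding is strict at the boundary", {
  prob <- array(c(0, 0.25, 0.5, 0.75, 1), c(5, 1, 1))
  expect_identical(as.vector(threshold_segmentation(prob, 0.5)),
                   c(FALSE, FALSE, FALSE, TRUE, TRUE))
  expect_false(any(threshold_segmentation(array(0, c(2, 2, 2)))))
  expect_identical(threshold_segmentation(prob, 0), prob > 0)
})

test_that("volumes smaller than the window are rejected", {
  expect_error(sliding_window_inference(array(0, c(10, 40, 40)),
                                        function(w) w, window_geometry(16, 8)),
               ">=")
})
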