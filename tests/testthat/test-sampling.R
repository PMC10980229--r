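test_that("uniform corners stay inside the valid region", {
  lab <- tiny_labels(c(100, 100, 100))
  cfg <- sample_config(in_side = 64, out_side = 32, oversample_prob = 0)
  set.seed(1)
  for (i in 1:200) {
    sc <- sample_corner(lab, cfg = cfg)
    expect_false(sc$oversampled)
    expect_true(all(sc$corner >= 0 & sc$corner <= 100 - 64))
  }
})

test_that("forced oversampling anchors the corner on the lone axon voxel", {
  lab <- tiny_labels(c(80, 80, 80), rbind(c(11, 11, 11))) # 0-based (10,10,10)
  cfg <- sample_config(in_side = 64, out_side = 32, oversample_prob = 1)
  set.seed(2)
  for (i in 1:20) {
    sc <- sample_corner(lab, cfg = cfg)
    expect_true(sc$oversampled)
    expect_identical(sc$corner, c(10L, 10L, 10L))
  }
})

test_that("oversampling falls back to uniform when no axon is reachable", {
  lab <- tiny_labels(c(80, 80, 80), rbind(c(79, 79, 79))) # outside valid region
  cfg <- sample_config(in_side = 64, oversample_prob = 1)
  set.seed(3)
  pkg_state <- axontune:::.axontune
  pkg_state$warned_no_axon <- NULL # re-arm the one-shot warning
  expect_warning(sc <- sample_corner(lab, cfg = cfg), "falling back")
  expect_false(sc$oversampled)
  expect_true(all(sc$corner <= 16))
  # warned once only
  expect_silent(sample_corner(lab, cfg = cfg))
})

test_that("empirical axon-list draw rate converges to the configured 30%", {
  tc <- make_test_cube(label_side = 160, pad_offset = 0, period = 20, start = 15,
                       density_class = "dense", seed = 8)
  cfg <- sample_config() # oversample_prob = 0.3
  set.seed(11)
  hits <- vapply(1:10000, function(i)
    sample_corner(tc$lab, cfg = cfg)$oversampled, logical(1))
  # 99% binomial CI around 0.30 at n = 10000 is about +/- 0.012
  expect_gt(mean(hits), 0.30 - 0.012)
  expect_lt(mean(hits), 0.30 + 0.012)
})

test_that("train/validation split reserves the far x strip", {
  cfg <- sample_config()
  sp <- split_train_val(160, cfg)
  expect_identical(sp$train, c(0L, 96L))
  expect_identical(sp$val, c(96L, 160L))
  sp0 <- split_train_val(160, sample_config(val_strip = 0))
  expect_identical(sp0$train, c(0L, 160L))
  expect_error(split_train_val(64, cfg), "must exceed")
})

test_that("region-restricted windows never cross the split boundary", {
  tc <- make_test_cube(label_side = 96, pad_offset = 0, density_class = "dense",
                       seed = 4)
  cfg <- sample_config(in_side = 32, out_side = 16, val_strip = 32,
                       oversample_prob = 0.5)
  sp <- split_train_val(96, cfg)
  set.seed(5)
  for (i in 1:100) {
    tr <- sample_corner(tc$lab, cfg = cfg, region = sp$train)
    expect_lte(tr$corner[3] + cfg$in_side, sp$train[2])
    va <- sample_corner(tc$lab, cfg = cfg, region = sp$val)
    expect_gte(va$corner[3], sp$val[1])
    expect_lte(va$corner[3] + cfg$in_side, sp$val[2])
  }
})

test_that("training pairs are center-cropped with the right offset", {
  set.seed(6)
  int <- array(runif(64^3), c(64, 64, 64))
  lab <- array(sample(0:4, 64^3, replace = TRUE), c(64, 64, 64))
  cfg <- sample_config(in_side = 32, out_side = 16)
  pr <- extract_training_pair(int, lab, c(0L, 0L, 0L), cfg)
  expect_identical(pr$input, int[1:32, 1:32, 1:32])
  expect_identical(pr$target, lab[9:24, 9:24, 9:24]) # offset (32-16)/2 = 8
  # equal sides: target footprint equals input footprint
  cfg2 <- sample_config(in_side = 16, out_side = 16)
  pr2 <- extract_training_pair(int, lab, c(3L, 4L, 5L), cfg2)
  expect_identical(pr2$target, lab[4:19, 5:20, 6:21])
  expect_error(extract_training_pair(int, lab, c(40L, 0L, 0L), cfg), "exceeds")
})

test_that("padded-frame corners map onto label-cube targets", {
  # padded intensity (side 48, pad 8) over a 32-side label cube
  int <- array(runif(48^3), c(48, 48, 48))
  lab <- array(sample(1:2, 32^3, replace = TRUE), c(32, 32, 32))
  cfg <- sample_config(in_side = 32, out_side = 16)
  pr <- extract_training_pair(int, lab, c(0L, 0L, 0L), cfg, pad_offset = 8)
  expect_identical(pr$input, int[1:32, 1:32, 1:32])
  expect_identical(pr$target, lab[1:16, 1:16, 1:16]) # 0 + 8 - 8 = 0
})

test_that("normalization divides by the 16-bit maximum", {
  expect_identical(normalize_intensity(65535), 1)
  expect_identical(normalize_intensity(0), 0)
  expect_equal(normalize_intensity(32768), 0.5000076295, tolerance = 1e-8)
})
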