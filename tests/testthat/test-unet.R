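test_that("forward pass yields a centered probability crop of the right size", {
  m <- build_unet(model_spec(depth = 3, base_channels = 2, in_side = 16,
                             out_side = 8), seed = 1)
  p <- unet_predict(m, array(runif(16^3), c(16, 16, 16)))
  expect_identical(dim(p), rep(8L, 3))
  expect_true(all(p > 0 & p < 1))
  # in = out: no crop
  m2 <- build_unet(model_spec(depth = 2, base_channels = 2, in_side = 8,
                              out_side = 8), seed = 1)
  expect_identical(dim(unet_predict(m2, array(0.5, c(8, 8, 8)))), rep(8L, 3))
})

test_that("geometry violations are rejected with the required sides", {
  expect_error(model_spec(depth = 3, in_side = 30), "divisible")
  expect_error(model_spec(in_side = 16, out_side = 32), "must be <=")
})

test_that("initialization is seed-deterministic", {
  a <- build_unet(model_spec(2, 2, 8, 4), seed = 5)
  b <- build_unet(model_spec(2, 2, 8, 4), seed = 5)
  expect_identical(axontune:::flatten_params(a), axontune:::flatten_params(b))
  c2 <- build_unet(model_spec(2, 2, 8, 4), seed = 6)
  expect_false(identical(axontune:::flatten_params(a),
                         axontune:::flatten_params(c2)))
})

test_that("freezing modes leave frozen conv kernels bit-identical under training", {
  set.seed(2)
  pairs <- lapply(1:2, function(i)
    list(input = array(runif(8^3), c(8, 8, 8)),
         target = array(sample(1:2, 4^3, replace = TRUE), c(4, 4, 4))))
  for (mode in c("first", "middle", "last")) {
    m <- build_unet(model_spec(2, 2, 8, 4), seed = 4)
    before <- axontune:::flatten_params(m)
    fit <- train_unet(m, pairs, val_set = pairs[1],
                      cfg = train_config(epochs = 2, batch_size = 1,
                                         trainable_mode = mode, seed = 1),
                      n_train = 2)
    after <- axontune:::flatten_params(fit$final_model)
    frozen <- fit$final_model$frozen
    expect_gt(length(frozen), 0)
    for (nm in frozen) expect_identical(after[[nm]], before[[nm]])
    # the designated conv layers moved
    moved <- setdiff(grep("conv", names(after), value = TRUE), frozen)
    expect_true(any(vapply(moved, function(nm)
      !identical(after[[nm]], before[[nm]]), logical(1))))
    # normalization layers always update
    gam <- grep("gamma", names(after), value = TRUE)
    expect_true(any(vapply(gam, function(nm)
      !identical(after[[nm]], before[[nm]]), logical(1))))
  }
})

test_that("full mode trains every parameter", {
  m <- set_trainable(build_unet(model_spec(2, 2, 8, 4), seed = 1), "full")
  cp <- count_params(m)
  expect_identical(cp$trainable, cp$total)
  m2 <- set_trainable(m, "first")
  expect_lt(count_params(m2)$trainable, cp$total)
})

test_that("the designated trainable pairs sit at the head, middle and tail", {
  m <- build_unet(model_spec(depth = 3, base_channels = 2, in_side = 8,
                             out_side = 4), seed = 1)
  paths <- axontune:::conv_paths(m)
  n <- length(paths)
  frozen_of <- function(mode) set_trainable(m, mode)$frozen
  key <- function(p) paste(p, collapse = ".")
  expect_false(any(grepl(key(paths[[1]]), frozen_of("first"))))
  expect_false(any(grepl(key(paths[[2]]), frozen_of("first"))))
  expect_true(any(grepl(key(paths[[3]]), frozen_of("first"))))
  expect_false(any(grepl(key(paths[[n]]), frozen_of("last"))))
  expect_true(any(grepl(key(paths[[1]]), frozen_of("last"))))
})
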