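test_that("confusion counting matches a per-voxel loop exactly", {
  set.seed(1)
  for (rep in 1:5) {
    lab <- random_labels(c(12, 12, 12))
    pred <- array(runif(12^3) < 0.3, c(12, 12, 12))
    cc <- confusion_counts(pred, lab)
    oc <- confusion_oracle(pred, lab)
    expect_identical(unclass(cc)[names(oc)],
                     lapply(oc, function(x) as.integer(x)))
  }
})

test_that("hand-built slice gives the expected counts", {
  # 10 voxels: 3 axon (2 hit, 1 miss); 2 edge (1 predicted +); 5 background
  # (1 predicted +)
  lab <- array(c(2, 2, 2, 3, 3, 1, 1, 1, 1, 1), c(10, 1, 1))
  pred <- array(c(1, 1, 0, 1, 0, 1, 0, 0, 0, 0), c(10, 1, 1))
  cc <- confusion_counts(pred, lab)
  expect_identical(cc$TP, 2L); expect_identical(cc$FN, 1L)
  expect_identical(cc$FP, 2L); expect_identical(cc$EA, 1L)
  expect_identical(cc$TN, 5L) # 4 background negatives + 1 edge negative
})

test_that("unlabeled slices are invisible to the counts", {
  set.seed(2)
  lab <- random_labels(c(10, 6, 6), p_unlabeled = 0.4)
  pred <- array(runif(10 * 36) < 0.4, c(10, 6, 6))
  cc <- confusion_counts(pred, lab)
  pred2 <- pred
  unl <- lab == 0L
  pred2[unl] <- !pred2[unl] # flip every unlabeled prediction
  expect_identical(confusion_counts(pred2, lab), cc)
  # perfect prediction
  cc3 <- confusion_counts(lab == 2L, lab)
  expect_identical(cc3$FP, 0L); expect_identical(cc3$FN, 0L)
  expect_identical(cc3$EA, 0L)
})

test_that("EA never exceeds FP and edge precision dominates plain precision", {
  set.seed(3)
  for (rep in 1:10) {
    lab <- random_labels(c(8, 8, 8), p_unlabeled = 0.2)
    pred <- array(runif(8^3) < runif(1, 0.1, 0.6), c(8, 8, 8))
    cc <- confusion_counts(pred, lab)
    expect_lte(cc$EA, cc$FP)
    m <- compute_metrics(cc)
    if (!is.na(m$edge_precision) && !is.na(m$precision) && cc$EA > 0)
      expect_gte(m$edge_precision, m$precision)
  }
})

test_that("metric formulas agree with direct evaluation on a hand table", {
  cc <- axontune:::confusion_struct(TP = 50, TN = 900, FP = 30, FN = 20, EA = 10)
  m <- compute_metrics(cc)
  expect_equal(m$precision, 0.625)
  expect_equal(m$edge_precision, 50 / 70)
  expect_equal(m$recall, 50 / 70)
  expect_equal(m$accuracy, 950 / 1000)
  expect_equal(m$adjusted_accuracy, 950 / 990)
  expect_equal(m$f1, 2 * 0.625 * (50 / 70) / (0.625 + 50 / 70))
  expect_equal(m$edge_f1, 50 / 70) # harmonic mean of two equal ratios
  # EA = 0 collapses the edge-adjusted metrics onto the plain ones
  m0 <- compute_metrics(axontune:::confusion_struct(50, 900, 30, 20, 0))
  expect_equal(m0$edge_precision, m0$precision)
  expect_equal(m0$edge_f1, m0$f1)
  # perfect segmentation
  mp <- compute_metrics(axontune:::confusion_struct(10, 90, 0, 0, 0))
  expect_equal(mp$f1, 1); expect_equal(mp$edge_f1, 1)
  # undefined ratios propagate as NA, never as 0
  mn <- compute_metrics(axontune:::confusion_struct(0, 10, 0, 0, 0))
  expect_true(is.na(mn$precision))
})

test_that("edge F1 is non-decreasing in EA at fixed TP/FP/FN", {
  vals <- vapply(0:5, function(ea)
    compute_metrics(axontune:::confusion_struct(20, 100, 10, 5, ea))$edge_f1,
    numeric(1))
  expect_true(all(diff(vals) >= 0))
})

test_that("two-level aggregation averages sections then models", {
  df <- data.frame(section = rep(1:2, each = 2), model = rep(1:2, 2),
                   edge_f1 = c(0.8, 0.8, 0.9, 0.9))
  ag <- aggregate_fold_metrics(df)
  expect_equal(unname(ag$overall[["edge_f1"]]), 0.85)
  # identical reports: overall equals the common value
  dfc <- data.frame(section = rep(1:3, each = 5), edge_f1 = 0.7)
  expect_equal(unname(aggregate_fold_metrics(dfc)$overall[["edge_f1"]]), 0.7)
  # uneven grid against an independently hand-computed two-level mean
  set.seed(4)
  dfr <- data.frame(section = rep(1:6, each = 5),
                    edge_f1 = runif(30), recall = runif(30))
  ag2 <- aggregate_fold_metrics(dfr)
  hand <- mean(vapply(1:6, function(s)
    mean(dfr$edge_f1[dfr$section == s]), numeric(1)))
  expect_equal(unname(ag2$overall[["edge_f1"]]), hand)
  # linearity: scaling every metric scales both levels
  dfs <- dfr; dfs$edge_f1 <- 3 * dfs$edge_f1
  expect_equal(unname(aggregate_fold_metrics(dfs)$overall[["edge_f1"]]),
               3 * unname(ag2$overall[["edge_f1"]]))
})

test_that("difference summaries behave anti-symmetrically", {
  v <- data.frame(section = 1:2, edge_f1 = c(0.81, 0.93))
  d <- data.frame(section = 1:2, edge_f1 = c(0.80, 0.90))
  cs <- compare_to_default(v, d)
  expect_equal(unname(cs$avg_diff[["edge_f1"]]), 0.02)
  expect_equal(unname(cs$std_diff[["edge_f1"]]), sd(c(0.01, 0.03)))
  expect_equal(unname(cs$std_diff[["edge_f1"]]), 0.01414214, tolerance = 1e-6)
  rev <- compare_to_default(d, v)
  expect_equal(rev$avg_diff[["edge_f1"]], -cs$avg_diff[["edge_f1"]])
  expect_equal(rev$std_diff[["edge_f1"]], cs$std_diff[["edge_f1"]])
  same <- compare_to_default(d, d)
  expect_equal(unname(same$avg_diff[["edge_f1"]]), 0)
  expect_equal(unname(same$std_diff[["edge_f1"]]), 0)
  expect_error(compare_to_default(v, data.frame(section = 2:3, edge_f1 = 0)),
               "different validation sections")
})

test_that("the half-standard-deviation rule reproduces the study's decisions", {
  mk <- function(avg, std) list(avg_diff = c(edge_f1 = avg),
                                std_diff = c(edge_f1 = std))
  expect_true(as.logical(selection_rule(mk(0.020, 0.027))))  # kept
  expect_false(as.logical(selection_rule(mk(0.003, 0.021)))) # default retained
  expect_true(as.logical(selection_rule(mk(0.025, 0.015))))  # kept
  expect_error(selection_rule(mk(0.1, NA)), "std_diff")
  best <- select_best_variant(list(a = mk(0.012, 0.010), b = mk(0.020, 0.027),
                                   c = mk(0.003, 0.021)))
  expect_identical(best, "b")
  expect_null(select_best_variant(list(c = mk(0.003, 0.021))))
})

test_that("each axon-bearing cube is held out exactly once", {
  fp <- fold_plan(n_cubes = 9, axon_cubes = 1:6)
  expect_length(fp, 6)
  expect_identical(sort(vapply(fp, `[[`, integer(1), "test_cube")), 1:6)
  for (f in fp) {
    expect_length(f$train_cubes, 8)
    expect_false(f$test_cube %in% f$train_cubes)
  }
})
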