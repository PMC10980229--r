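confusion_struct <- function(TP, TN, FP, FN, EA) {
  structure(list(TP = TP, TN = TN, FP = FP, FN = FN, EA = EA),
            class = "confusion_counts")
}

#' Confusion counts on labeled voxels, tracking edge hits
#'
#' Unlabeled voxels are excluded entirely. Positives are axon-coded voxels;
#' background, artifact and edge voxels are all negatives. `EA` counts
#' edge-coded voxels with a positive prediction — by construction a subset of
#' the false positives — which the edge-tolerant metrics discount.
#'
#' @param pred Logical (or 0/1) prediction array.
#' @param labels Integer label array of the same shape.
#' @return A `confusion_counts` list: `TP`, `TN`, `FP`, `FN`, `EA`.
#' @export
confusion_counts <- function(pred, labels) {
  if (!identical(dim(pred), dim(labels)))
    stop("prediction and label shapes differ", call. = FALSE)
  codes <- label_codes()
  pred <- pred > 0
  labeled <- labels != codes[["unlabeled"]]
  pos <- labels == codes[["axon"]]
  confusion_struct(
    TP = sum(pred & pos),
    TN = sum(!pred & labeled & !pos),
    FP = sum(pred & labeled & !pos),
    FN = sum(!pred & pos),
    EA = sum(pred & labels == codes[["edge"]])
  )
}

safe_ratio <- function(num, den) if (den <= 0) NA_real_ else num / den

#' Edge-tolerant metric suite from confusion counts
#'
#' Standard accuracy, precision, recall and F1, plus the edge-adjusted
#' variants in which edge voxels predicted as axon (`EA`) are removed from
#' the false positives: `edge_precision = TP / (TP + FP - EA)` and `edge_f1`
#' the harmonic mean of recall and edge precision. `adjusted_accuracy`
#' removes `EA` from the error total by the same logic,
#' `(TP + TN) / (TP + TN + FP + FN - EA)`. Undefined ratios (zero
#' denominators) propagate as `NA` rather than being imputed as 0.
#'
#' @param cc A `confusion_counts` object from [confusion_counts()].
#' @return Named list: `accuracy`, `adjusted_accuracy`, `precision`,
#'   `edge_precision`, `recall`, `f1`, `edge_f1`.
#' @export
compute_metrics <- function(cc) {
  stopifnot(inherits(cc, "confusion_counts"))
  with(cc, {
    precision <- safe_ratio(TP, TP + FP)
    edge_precision <- safe_ratio(TP, TP + FP - EA)
    recall <- safe_ratio(TP, TP + FN)
    hmean <- function(a, b) {
      if (is.na(a) || is.na(b)) return(NA_real_)
      if (a + b == 0) return(NA_real_)
      2 * a * b / (a + b)
    }
    list(accuracy = safe_ratio(TP + TN, TP + TN + FP + FN),
         adjusted_accuracy = safe_ratio(TP + TN, TP + TN + FP + FN - EA),
         precision = precision,
         edge_precision = edge_precision,
         recall = recall,
         f1 = hmean(recall, precision),
         edge_f1 = hmean(recall, edge_precision))
  })
}

metric_names <- function() c("accuracy", "adjusted_accuracy", "precision",
                             "edge_precision", "recall", "f1", "edge_f1")

#' Leave-one-cube-out fold plan
#'
#' Each axon-bearing cube is the held-out test cube in exactly one fold; all
#' remaining cubes train that fold's model (with a per-cube train/validation
#' split along x). Metrics are only ever computed on axon-bearing cubes.
#'
#' @param n_cubes Total number of annotated cubes.
#' @param axon_cubes Indices of cubes that contain axons.
#' @return List of folds, each with `test_cube` and `train_cubes`.
#' @export
fold_plan <- function(n_cubes = 9L, axon_cubes = 1:6) {
  stopifnot(all(axon_cubes %in% seq_len(n_cubes)))
  lapply(axon_cubes, function(tc)
    list(test_cube = tc, train_cubes = setdiff(seq_len(n_cubes), tc)))
}

#' Two-level averaging of per-model metrics by validation section
#'
#' Each validation section is scored by every model that used it for
#' validation; metrics are averaged per section, and the overall value is the
#' mean of the per-section means. `NA` metric values (undefined ratios) are
#' dropped from averages; the number dropped is reported.
#'
#' @param df data.frame with a `section` column and one column per metric.
#' @return List with `per_section` (data.frame of per-section means),
#'   `overall` (named numeric), and `n_dropped` (NA values excluded).
#' @export
aggregate_fold_metrics <- function(df) {
  stopifnot("section" %in% names(df))
  metrics <- setdiff(names(df), c("section", "model"))
  sections <- sort(unique(df$section))
  if (length(sections) == 0L) stop("no sections to aggregate", call. = FALSE)
  per <- data.frame(section = sections)
  n_dropped <- 0L
  for (m in metrics) {
    vals <- vapply(sections, function(s) {
      v <- df[df$section == s, m]
      if (!length(v)) stop("empty section group: ", s, call. = FALSE)
      n_dropped <<- n_dropped + sum(is.na(v))
      mean(v, na.rm = TRUE)
    }, numeric(1))
    per[[m]] <- vals
  }
  overall <- vapply(metrics, function(m) mean(per[[m]], na.rm = TRUE), numeric(1))
  list(per_section = per, overall = overall, n_dropped = n_dropped)
}

#' Per-section metric differences of a variant against the default
#'
#' Computes (variant - default) per validation section per metric, then the
#' average and sample (n-1) standard deviation of the differences across
#' sections.
#'
#' @param variant,default Per-section data.frames (the `per_section` element
#'   of [aggregate_fold_metrics()]), sharing the same section set.
#' @return A `comparison_summary` list with `diffs`, `avg_diff`, `std_diff`.
#' @export
compare_to_default <- function(variant, default) {
  if (!setequal(variant$section, default$section))
    stop("variant and default cover different validation sections", call. = FALSE)
  variant <- variant[order(variant$section), ]
  default <- default[order(default$section), ]
  metrics <- setdiff(intersect(names(variant), names(default)), "section")
  diffs <- data.frame(section = variant$section)
  for (m in metrics) diffs[[m]] <- variant[[m]] - default[[m]]
  structure(list(
    diffs = diffs,
    avg_diff = vapply(metrics, function(m) mean(diffs[[m]], na.rm = TRUE), numeric(1)),
    std_diff = vapply(metrics, function(m) sd(diffs[[m]], na.rm = TRUE), numeric(1))
  ), class = "comparison_summary")
}

#' Half-standard-deviation modification selection rule
#'
#' A modification is kept only if it improves the chosen metric's average
#' difference over the default by at least half the standard deviation of
#' those differences: keep iff `avg_diff >= 0.5 * std_diff`.
#'
#' @param s A `comparison_summary` from [compare_to_default()], or a list
#'   with `avg_diff`/`std_diff` named vectors.
#' @param metric Metric driving the decision (the primary evaluator is
#'   `edge_f1`).
#' @return `TRUE` (keep) or `FALSE` (reject), with attributes `avg_diff`,
#'   `std_diff`.
#' @export
#' @examples
#' s <- list(avg_diff = c(edge_f1 = 0.020), std_diff = c(edge_f1 = 0.027))
#' selection_rule(s) # TRUE: 0.020 >= 0.0135
selection_rule <- function(s, metric = "edge_f1") {
  avg <- s$avg_diff[[metric]]
  std <- s$std_diff[[metric]]
  if (is.null(std) || is.na(std))
    stop("std_diff unavailable for metric '", metric, "'", call. = FALSE)
  keep <- avg >= 0.5 * std
  structure(keep, avg_diff = avg, std_diff = std)
}

#' Pick the best kept variant of one modification type
#'
#' Applies [selection_rule()] to each candidate; among those kept, the one
#' with the largest average difference wins. Returns `NULL` when none pass
#' (the default is retained).
#'
#' @param summaries Named list of `comparison_summary` objects.
#' @param metric Decision metric.
#' @return Name of the winning variant, or `NULL`.
#' @export
select_best_variant <- function(summaries, metric = "edge_f1") {
  kept <- Filter(function(s) isTRUE(as.logical(selection_rule(s, metric))), summaries)
  if (!length(kept)) return(NULL)
  avgs <- vapply(kept, function(s) s$avg_diff[[metric]], numeric(1))
  names(which.max(avgs))
}
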