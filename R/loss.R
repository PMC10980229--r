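#' Per-class loss weights
#'
#' Misclassification is weighted by the annotated class of each voxel: axons
#' 1.5, background 0.2, artifacts 0.8, edges 0.05 by default. Unlabeled voxels
#' carry weight exactly 0, which removes unannotated slices from the loss.
#' The tiny edge weight makes a positive prediction one voxel off an axon
#' nearly free, absorbing annotator boundary ambiguity. Setting the
#' background weight to 1.5 makes all labeled classes equally weighted.
#'
#' @param w_axon,w_background,w_artifact,w_edge Non-negative class weights.
#' @return A `class_weights` list.
#' @export
class_weights <- function(w_axon = 1.5, w_background = 0.2,
                          w_artifact = 0.8, w_edge = 0.05) {
  w <- list(w_axon = w_axon, w_background = w_background,
            w_artifact = w_artifact, w_edge = w_edge)
  if (any(unlist(w) < 0)) stop("class weights must be non-negative", call. = FALSE)
  structure(w, class = "class_weights")
}

#' Build the binary target and per-voxel weight grids
#'
#' The target is 1 at axon voxels and 0 elsewhere; the weight grid carries the
#' class weight of each voxel's annotation (0 on unlabeled voxels).
#'
#' @param labels 3D integer label array (codes 0--4).
#' @param w A [class_weights()].
#' @return List with `target` (0/1 array) and `weight` (numeric array).
#' @export
make_weight_target <- function(labels, w = class_weights()) {
  if (any(!(labels %in% label_codes())))
    stop("labels contain codes outside 0..4: ",
         paste(unique(labels[!(labels %in% label_codes())]), collapse = ", "),
         call. = FALSE)
  lookup <- c(0, w$w_background, w$w_axon, w$w_edge, w$w_artifact)
  weight <- array(lookup[labels + 1L], dim(labels))
  target <- array(as.numeric(labels == label_codes()[["axon"]]), dim(labels))
  list(target = target, weight = weight)
}

bce_eps <- 1e-7

#' Class-weighted masked binary cross-entropy
#'
#' `sum(weight * (-target*log(p) - (1-target)*log(1-p))) / N` with `N` the
#' total voxel count of the block. The denominator is a constant, so voxels
#' with weight 0 (unlabeled slices) contribute exactly nothing: the loss and
#' its gradient are invariant to predictions there. Probabilities are clamped
#' to `[1e-7, 1 - 1e-7]` inside the logs.
#'
#' @param pred Predicted probability array.
#' @param target 0/1 target array (same shape).
#' @param weight Per-voxel weight array (same shape).
#' @return Scalar loss.
#' @export
weighted_bce <- function(pred, target, weight) {
  if (!identical(dim(pred), dim(target)) || !identical(dim(pred), dim(weight)))
    stop("pred, target and weight must share a shape", call. = FALSE)
  p <- pmin(pmax(pred, bce_eps), 1 - bce_eps)
  sum(weight * (-target * log(p) - (1 - target) * log1p(-p))) / length(pred)
}

# gradient of weighted_bce w.r.t. the logits (pred = sigmoid(logit))
weighted_bce_grad_logits <- function(pred, target, weight) {
  weight * (pred - target) / length(pred)
}
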