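#' Training configuration
#'
#' Defaults mirror the fine-tuning recipe this package implements: 50 epochs
#' of Adam at learning rate 1e-3 with batch size 6, optional
#' reduce-on-plateau scheduling (factor 0.1 once the validation loss stops
#' improving), and the checkpoint taken at the validation-loss minimum.
#'
#' @param epochs Number of epochs (>= 1).
#' @param batch_size Gradient-accumulation batch size (>= 1).
#' @param learning_rate Initial Adam step size (study grid: 1e-3, 5e-4, 1e-4).
#' @param plateau Enable reduce-on-plateau learning-rate scheduling.
#' @param plateau_factor Multiplicative factor applied on plateau (in (0, 1)).
#' @param plateau_patience Epochs without validation improvement before the
#'   rate is reduced.
#' @param min_delta Minimum validation-loss decrease that counts as
#'   improvement.
#' @param trainable_mode Layer-freezing mode, see [set_trainable()].
#' @param seed Optional seed fixing the sampling/augmentation stream.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 50L, batch_size = 6L, learning_rate = 1e-3,
                         plateau = FALSE, plateau_factor = 0.1,
                         plateau_patience = 5L, min_delta = 1e-4,
                         trainable_mode = "full", seed = NULL) {
  stopifnot(epochs >= 1, batch_size >= 1,
            plateau_factor > 0, plateau_factor < 1)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, plateau = plateau,
                 plateau_factor = plateau_factor,
                 plateau_patience = as.integer(plateau_patience),
                 min_delta = min_delta, trainable_mode = trainable_mode,
                 seed = seed),
            class = "train_config")
}

# loss and flat gradients for one (input, target) pair
sample_loss_grad <- function(model, input, target, w, want_grad = TRUE) {
  fw <- unet_forward(model, input)
  out_side <- dim(target)[1]
  logits <- center_crop(fw$logits, out_side)
  pred <- 1 / (1 + exp(-logits))
  tw <- make_weight_target(target, w)
  loss <- weighted_bce(pred, tw$target, tw$weight)
  if (!want_grad) return(list(loss = loss))
  gcrop <- weighted_bce_grad_logits(pred, tw$target, tw$weight)
  gfull <- array(0, dim(fw$logits))
  off <- crop_offset(dim(fw$logits)[1], out_side)
  idx <- seq_len(out_side) + off
  gfull[idx, idx, idx] <- gcrop
  grads <- unet_backward(model, fw$cache, gfull)
  list(loss = loss, grads = flatten_grads(model, grads))
}

adam_init <- function(flat) {
  list(m = lapply(flat, function(p) p * 0), v = lapply(flat, function(p) p * 0),
       t = 0L)
}

adam_step <- function(flat, grads, state, lr, frozen,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(flat)) {
    if (nm %in% frozen) next
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    flat[[nm]] <- flat[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = flat, state = state)
}

#' Fine-tune a U-Net with class-weighted masked loss
#'
#' Runs `epochs` epochs of `n_train / batch_size` Adam steps (integer
#' division), each step averaging per-sample gradients over a batch drawn
#' from `train_sampler`. After every epoch the (unaugmented) validation pairs
#' are scored; the parameters at the validation-loss minimum are kept as the
#' returned checkpoint. With plateau scheduling enabled, the learning rate is
#' multiplied by `plateau_factor` after `plateau_patience` epochs without
#' improvement.
#'
#' @param model An `axon_unet` from [build_unet()].
#' @param train_sampler A sampler from [make_sampler()] (augmented draws), or
#'   a list of fixed pairs to cycle through.
#' @param val_set A list of fixed, unaugmented input/target pairs
#'   (see [sample_pairs()]).
#' @param cfg A [train_config()].
#' @param w A [class_weights()].
#' @param n_train Number of training volumes per epoch; defaults to the
#'   sampler's `n`.
#' @param verbose Print one line per epoch.
#' @return List with `model` (best checkpoint), `final_model` (last-epoch
#'   parameters), `history` (per-epoch data.frame of losses and learning
#'   rate), and `best_epoch`.
#' @export
train_unet <- function(model, train_sampler, val_set, cfg = train_config(),
                       w = class_weights(), n_train = NULL, verbose = FALSE) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  fixed_pairs <- NULL
  if (!is.function(train_sampler$draw)) {
    fixed_pairs <- train_sampler # plain list of pairs
    if (is.null(n_train)) n_train <- length(fixed_pairs)
  } else if (is.null(n_train)) n_train <- train_sampler$n
  if (n_train < 1L || length(val_set) < 1L)
    stop("training and validation samplers must be non-empty", call. = FALSE)
  steps <- max(1L, n_train %/% cfg$batch_size)
  model <- set_trainable(model, cfg$trainable_mode)
  flat <- flatten_params(model)
  state <- adam_init(flat)
  lr <- cfg$learning_rate
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0), lr = numeric(0))
  best_val <- Inf; best_flat <- flat; best_epoch <- NA_integer_
  since_improve <- 0L
  draw_i <- 0L
  next_pair <- function() {
    if (is.null(fixed_pairs)) return(train_sampler$draw())
    draw_i <<- draw_i + 1L
    fixed_pairs[[(draw_i - 1L) %% length(fixed_pairs) + 1L]]
  }
  for (epoch in seq_len(cfg$epochs)) {
    tr_losses <- numeric(0)
    for (s in seq_len(steps)) {
      acc <- NULL; bl <- numeric(cfg$batch_size)
      for (b in seq_len(cfg$batch_size)) {
        pair <- next_pair()
        sg <- sample_loss_grad(model, pair$input, pair$target, w)
        bl[b] <- sg$loss
        acc <- if (is.null(acc)) sg$grads else
          Map(function(a, g) a + g, acc, sg$grads)
      }
      acc <- lapply(acc, function(g) g / cfg$batch_size)
      upd <- adam_step(flat, acc, state, lr, model$frozen)
      flat <- upd$params; state <- upd$state
      model <- set_params(model, flat)
      tr_losses <- c(tr_losses, mean(bl))
    }
    vl <- vapply(val_set, function(pair)
      sample_loss_grad(model, pair$input, pair$target, w, want_grad = FALSE)$loss,
      numeric(1))
    val_loss <- mean(vl)
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = mean(tr_losses),
                                         val_loss = val_loss, lr = lr))
    if (val_loss < best_val - cfg$min_delta) {
      best_val <- val_loss; best_flat <- flat; best_epoch <- epoch
      since_improve <- 0L
    } else {
      since_improve <- since_improve + 1L
      if (cfg$plateau && since_improve >= cfg$plateau_patience) {
        lr <- lr * cfg$plateau_factor
        since_improve <- 0L
      }
    }
    if (verbose)
      message(sprintf("epoch %3d  train %.5f  val %.5f  lr %.2e",
                      epoch, mean(tr_losses), val_loss, lr))
  }
  list(model = set_params(model, best_flat),
       final_model = model,
       history = history,
       best_epoch = best_epoch)
}

#' Score a model on fixed pairs with edge-tolerant metrics
#'
#' Predicts each pair's target window, thresholds at `tau`, pools the
#' confusion counts over all pairs and returns the metric suite.
#'
#' @param model An `axon_unet`.
#' @param pairs List of input/target pairs.
#' @param tau Segmentation threshold (mask is `prob > tau`).
#' @return A [compute_metrics()] report.
#' @export
evaluate_pairs <- function(model, pairs, tau = 0.5) {
  cc <- NULL
  for (pair in pairs) {
    pred <- threshold_segmentation(
      unet_predict(model, pair$input, dim(pair$target)[1]), tau)
    ci <- confusion_counts(pred, pair$target)
    cc <- if (is.null(cc)) ci else Map(`+`, cc, ci)
  }
  compute_metrics(do.call(confusion_struct, cc))
}
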