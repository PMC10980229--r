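#' Model geometry for the 3D U-Net
#'
#' A compact encoder--decoder with skip connections: each resolution level is
#' two 3x3x3 convolution + normalization + ReLU blocks; levels are joined by
#' 2x max-pooling on the way down and nearest-neighbor upsampling plus channel
#' concatenation on the way up. A 1x1x1 convolution with a sigmoid produces a
#' per-voxel axon probability. The network computes full-size logits and the
#' prediction is center-cropped to `out_side`, so the model only commits to
#' voxels that have full surrounding context.
#'
#' @param depth Number of resolution levels (>= 1); `in_side` must be
#'   divisible by `2^(depth - 1)`.
#' @param base_channels Channel width of the first level; doubles per level.
#' @param in_side Input window side in voxels.
#' @param out_side Side of the centered output crop (<= `in_side`, even
#'   difference).
#' @return A `model_spec` list.
#' @export
model_spec <- function(depth = 2L, base_channels = 4L, in_side = 64L,
                       out_side = 32L) {
  depth <- as.integer(depth); base_channels <- as.integer(base_channels)
  in_side <- as.integer(in_side); out_side <- as.integer(out_side)
  stopifnot(depth >= 1, base_channels >= 1)
  div <- 2L^(depth - 1L)
  if (in_side %% div != 0L)
    stop("in_side (", in_side, ") must be divisible by 2^(depth-1) = ", div,
         "; nearest valid sides are ", div * (in_side %/% div), " and ",
         div * (in_side %/% div + 1L), call. = FALSE)
  crop_offset(in_side, out_side) # validates parity
  structure(list(depth = depth, base_channels = base_channels,
                 in_side = in_side, out_side = out_side),
            class = "model_spec")
}

he_init <- function(k, cin, cout) {
  array(rnorm(k^3 * cin * cout, 0, sqrt(2 / (k^3 * cin))), c(k, k, k, cin, cout))
}

new_conv <- function(k, cin, cout) list(w = he_init(k, cin, cout), b = numeric(cout))
new_norm <- function(c) list(gamma = rep(1, c), beta = numeric(c))
new_block <- function(cin, cout) {
  list(conv1 = new_conv(3L, cin, cout), norm1 = new_norm(cout),
       conv2 = new_conv(3L, cout, cout), norm2 = new_norm(cout))
}

#' Build a seeded 3D U-Net
#'
#' Parameters use He initialization; identical seeds give identical initial
#' parameters. All layers start trainable; see [set_trainable()].
#'
#' @param spec A [model_spec()].
#' @param seed Integer seed for parameter initialization.
#' @return An `axon_unet` model object.
#' @export
build_unet <- function(spec = model_spec(), seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  B <- spec$base_channels; D <- spec$depth
  with_seed(seed, {
    enc <- list(); dec <- list()
    if (D > 1) {
      for (l in seq_len(D - 1L)) {
        cin <- if (l == 1L) 1L else B * 2L^(l - 2L)
        enc[[l]] <- new_block(cin, B * 2L^(l - 1L))
      }
    }
    mid_in <- if (D > 1) B * 2L^(D - 2L) else 1L
    mid <- new_block(mid_in, B * 2L^(D - 1L))
    if (D > 1) {
      for (l in seq_len(D - 1L)) {
        below <- if (l == D - 1L) B * 2L^(D - 1L) else B * 2L^l
        dec[[l]] <- new_block(below + B * 2L^(l - 1L), B * 2L^(l - 1L))
      }
    }
    head_in <- if (D > 1) B else B * 2L^(D - 1L)
    structure(list(spec = spec, enc = enc, mid = mid, dec = dec,
                   head = list(conv = new_conv(1L, head_in, 1L)),
                   frozen = character(0), trainable_mode = "full",
                   seed = as.integer(seed)),
              class = "axon_unet")
  })
}

# ---- layer primitives -------------------------------------------------------

norm_eps <- 1e-5

conv_fwd <- function(x, layer) cpp_conv3d_fwd(x, layer$w, layer$b)

norm_fwd <- function(y, layer) {
  d <- dim(y); C <- d[4]; n <- prod(d[1:3])
  m <- y; dim(m) <- c(n, C)
  mu <- colMeans(m)
  va <- colMeans(m^2) - mu^2
  sdv <- sqrt(va + norm_eps)
  xhat <- m
  out <- m
  for (c in seq_len(C)) {
    xhat[, c] <- (m[, c] - mu[c]) / sdv[c]
    out[, c] <- layer$gamma[c] * xhat[, c] + layer$beta[c]
  }
  dim(out) <- d
  list(out = out, xhat = xhat, sdv = sdv, dims = d)
}

norm_bwd <- function(gout, cache, layer) {
  d <- cache$dims; C <- d[4]; n <- prod(d[1:3])
  g <- gout; dim(g) <- c(n, C)
  gx <- g
  dgamma <- numeric(C); dbeta <- numeric(C)
  for (c in seq_len(C)) {
    gc <- g[, c]; xh <- cache$xhat[, c]
    dgamma[c] <- sum(gc * xh)
    dbeta[c] <- sum(gc)
    dxh <- gc * layer$gamma[c]
    gx[, c] <- (dxh - mean(dxh) - xh * mean(dxh * xh)) / cache$sdv[c]
  }
  dim(gx) <- d
  list(gx = gx, gamma = dgamma, beta = dbeta)
}

upsample2 <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2),
    rep(seq_len(d[3]), each = 2), , drop = FALSE]
}

upsample2_bwd <- function(g) {
  d <- dim(g); h <- d[1:3] %/% 2L; C <- d[4]
  dim(g) <- c(2L, h[1], 2L, h[2], 2L, h[3], C)
  r <- colSums(g, dims = 1)                          # (h1,2,h2,2,h3,C)
  r <- colSums(aperm(r, c(2, 1, 3, 4, 5, 6)), dims = 1) # (h1,h2,2,h3,C)
  r <- colSums(aperm(r, c(3, 1, 2, 4, 5)), dims = 1)    # (h1,h2,h3,C)
  array(r, c(h, C))
}

concat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  array(c(a, b), c(da[1:3], da[4] + db[4]))
}

block_fwd <- function(x, blk) {
  y1 <- conv_fwd(x, blk$conv1)
  n1 <- norm_fwd(y1, blk$norm1)
  a1 <- pmax(n1$out, 0)
  y2 <- conv_fwd(a1, blk$conv2)
  n2 <- norm_fwd(y2, blk$norm2)
  a2 <- pmax(n2$out, 0)
  list(out = a2,
       cache = list(x = x, n1 = n1, a1 = a1, pos1 = n1$out > 0,
                    n2 = n2, pos2 = n2$out > 0))
}

block_bwd <- function(gout, blk, cache) {
  g <- gout * cache$pos2
  nb2 <- norm_bwd(g, cache$n2, blk$norm2)
  wb2 <- cpp_conv3d_bwd_weights(cache$a1, nb2$gx, 3L)
  g <- cpp_conv3d_bwd_input(nb2$gx, blk$conv2$w)
  g <- g * cache$pos1
  nb1 <- norm_bwd(g, cache$n1, blk$norm1)
  wb1 <- cpp_conv3d_bwd_weights(cache$x, nb1$gx, 3L)
  gin <- cpp_conv3d_bwd_input(nb1$gx, blk$conv1$w)
  list(gin = gin,
       grads = list(conv1 = list(w = wb1$gw, b = wb1$gb),
                    norm1 = list(gamma = nb1$gamma, beta = nb1$beta),
                    conv2 = list(w = wb2$gw, b = wb2$gb),
                    norm2 = list(gamma = nb2$gamma, beta = nb2$beta)))
}

# ---- full network -----------------------------------------------------------

unet_forward <- function(model, x) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  D <- model$spec$depth
  skips <- vector("list", max(D - 1L, 0L))
  enc_caches <- vector("list", max(D - 1L, 0L))
  pools <- vector("list", max(D - 1L, 0L))
  h <- x
  if (D > 1) for (l in seq_len(D - 1L)) {
    bf <- block_fwd(h, model$enc[[l]])
    skips[[l]] <- bf$out
    enc_caches[[l]] <- bf$cache
    pl <- cpp_maxpool3d_fwd(bf$out)
    pools[[l]] <- list(idx = pl$idx, xdim = dim(bf$out))
    h <- pl$y
  }
  bf <- block_fwd(h, model$mid)
  mid_cache <- bf$cache
  h <- bf$out
  dec_caches <- vector("list", max(D - 1L, 0L))
  if (D > 1) for (l in seq.int(D - 1L, 1L)) {
    u <- upsample2(h)
    cc <- concat_ch(u, skips[[l]])
    bf <- block_fwd(cc, model$dec[[l]])
    dec_caches[[l]] <- bf$cache
    h <- bf$out
  }
  logits <- conv_fwd(h, model$head$conv)
  list(logits = array(logits, dim(logits)[1:3]),
       cache = list(enc = enc_caches, pools = pools, mid = mid_cache,
                    dec = dec_caches, head_in = h))
}

unet_backward <- function(model, cache, glogits) {
  D <- model$spec$depth
  g4 <- glogits; dim(g4) <- c(dim(glogits), 1L)
  wbh <- cpp_conv3d_bwd_weights(cache$head_in, g4, 1L)
  g <- cpp_conv3d_bwd_input(g4, model$head$conv$w)
  grads <- list(enc = vector("list", max(D - 1L, 0L)),
                dec = vector("list", max(D - 1L, 0L)),
                head = list(conv = list(w = wbh$gw, b = wbh$gb)))
  gskip <- vector("list", max(D - 1L, 0L))
  if (D > 1) for (l in seq_len(D - 1L)) {
    bb <- block_bwd(g, model$dec[[l]], cache$dec[[l]])
    grads$dec[[l]] <- bb$grads
    cu <- dim(bb$gin)[4] - model$spec$base_channels * 2L^(l - 1L)
    gu <- bb$gin[, , , seq_len(cu), drop = FALSE]
    gskip[[l]] <- bb$gin[, , , cu + seq_len(dim(bb$gin)[4] - cu), drop = FALSE]
    g <- upsample2_bwd(gu)
  }
  bb <- block_bwd(g, model$mid, cache$mid)
  grads$mid <- bb$grads
  g <- bb$gin
  if (D > 1) for (l in seq.int(D - 1L, 1L)) {
    gpool <- cpp_maxpool3d_bwd(g, cache$pools[[l]]$idx, cache$pools[[l]]$xdim)
    bb <- block_bwd(gpool + gskip[[l]], model$enc[[l]], cache$enc[[l]])
    grads$enc[[l]] <- bb$grads
    g <- bb$gin
  }
  grads
}

#' Predict axon probabilities for one input window
#'
#' Runs the forward pass, center-crops the logits and applies the sigmoid.
#'
#' @param model An `axon_unet`.
#' @param input Normalized 3D input window (side `in_side`).
#' @param out_side Side of the output crop; defaults to the model's training
#'   `out_side` but may differ (e.g. 36 for inference vs 32 for training) since
#'   the crop is applied to full-size logits.
#' @return 3D array of probabilities in (0, 1), side `out_side`.
#' @export
unet_predict <- function(model, input, out_side = NULL) {
  if (is.null(out_side)) out_side <- model$spec$out_side
  fw <- unet_forward(model, input)
  1 / (1 + exp(-center_crop(fw$logits, out_side)))
}

# ---- parameter bookkeeping --------------------------------------------------

# ordered conv-layer paths, following forward execution order
conv_paths <- function(model) {
  D <- model$spec$depth
  paths <- list()
  if (D > 1) for (l in seq_len(D - 1L))
    paths <- c(paths, list(c("enc", l, "conv1"), c("enc", l, "conv2")))
  paths <- c(paths, list(c("mid", "conv1"), c("mid", "conv2")))
  if (D > 1) for (l in seq.int(D - 1L, 1L))
    paths <- c(paths, list(c("dec", l, "conv1"), c("dec", l, "conv2")))
  c(paths, list(c("head", "conv")))
}

norm_paths <- function(model) {
  D <- model$spec$depth
  paths <- list()
  if (D > 1) for (l in seq_len(D - 1L))
    paths <- c(paths, list(c("enc", l, "norm1"), c("enc", l, "norm2")))
  paths <- c(paths, list(c("mid", "norm1"), c("mid", "norm2")))
  if (D > 1) for (l in seq.int(D - 1L, 1L))
    paths <- c(paths, list(c("dec", l, "norm1"), c("dec", l, "norm2")))
  paths
}

get_by_path <- function(obj, path) {
  for (p in path) obj <- obj[[if (grepl("^[0-9]+$", p)) as.integer(p) else p]]
  obj
}

path_key <- function(path) paste(path, collapse = ".")

# flat named list of every parameter tensor
flatten_params <- function(model) {
  out <- list()
  for (p in conv_paths(model)) {
    layer <- get_by_path(model, as.character(p))
    out[[paste0(path_key(p), ".w")]] <- layer$w
    out[[paste0(path_key(p), ".b")]] <- layer$b
  }
  for (p in norm_paths(model)) {
    layer <- get_by_path(model, as.character(p))
    out[[paste0(path_key(p), ".gamma")]] <- layer$gamma
    out[[paste0(path_key(p), ".beta")]] <- layer$beta
  }
  out
}

assign_by_path <- function(model, path, field, value) {
  p <- as.character(path)
  expr <- "model"
  for (q in p) expr <- paste0(expr, "[[", if (grepl("^[0-9]+$", q)) q
                              else paste0("\"", q, "\""), "]]")
  expr <- paste0(expr, "[[\"", field, "\"]]")
  eval(parse(text = paste0(expr, " <- value")))
  model
}

set_params <- function(model, flat) {
  for (p in conv_paths(model)) {
    model <- assign_by_path(model, p, "w", flat[[paste0(path_key(p), ".w")]])
    model <- assign_by_path(model, p, "b", flat[[paste0(path_key(p), ".b")]])
  }
  for (p in norm_paths(model)) {
    model <- assign_by_path(model, p, "gamma", flat[[paste0(path_key(p), ".gamma")]])
    model <- assign_by_path(model, p, "beta", flat[[paste0(path_key(p), ".beta")]])
  }
  model
}

flatten_grads <- function(model, grads) {
  out <- list()
  for (p in conv_paths(model)) {
    layer <- get_by_path(grads, as.character(p))
    out[[paste0(path_key(p), ".w")]] <- layer$w
    out[[paste0(path_key(p), ".b")]] <- layer$b
  }
  for (p in norm_paths(model)) {
    layer <- get_by_path(grads, as.character(p))
    out[[paste0(path_key(p), ".gamma")]] <- layer$gamma
    out[[paste0(path_key(p), ".beta")]] <- layer$beta
  }
  out
}

#' Choose which layers fine-tuning may update
#'
#' `"full"` trains everything. `"first"`, `"middle"` and `"last"` train only
#' the designated two 3D convolution layers (in forward-execution order over
#' all convolution layers, including the output head) while every
#' normalization layer stays trainable, mirroring the practice of not
#' freezing batch-normalization during partial fine-tuning. All other
#' parameters are frozen exactly: optimizer steps leave them bit-identical.
#'
#' @param model An `axon_unet`.
#' @param mode One of `"full"`, `"first"`, `"middle"`, `"last"`.
#' @return The model with updated freezing state.
#' @export
set_trainable <- function(model, mode = c("full", "first", "middle", "last")) {
  mode <- match.arg(mode)
  paths <- conv_paths(model)
  n <- length(paths)
  keep <- switch(mode,
                 full = seq_len(n),
                 first = 1:2,
                 middle = floor(n / 2) + c(0L, 1L),
                 last = c(n - 1L, n))
  if (mode != "full" && n < 2L) stop("model has fewer than two conv layers", call. = FALSE)
  frozen <- character(0)
  for (i in seq_len(n)) {
    if (!(i %in% keep)) {
      frozen <- c(frozen, paste0(path_key(paths[[i]]), ".w"),
                  paste0(path_key(paths[[i]]), ".b"))
    }
  }
  model$frozen <- frozen
  model$trainable_mode <- mode
  model
}

#' Count trainable parameters
#' @param model An `axon_unet`.
#' @return Named list with `total` and `trainable` parameter counts.
#' @export
count_params <- function(model) {
  flat <- flatten_params(model)
  total <- sum(vapply(flat, length, integer(1)))
  trainable <- sum(vapply(names(flat), function(nm)
    if (nm %in% model$frozen) 0L else length(flat[[nm]]), integer(1)))
  list(total = total, trainable = trainable)
}
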