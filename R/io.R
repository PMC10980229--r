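#' Read a multi-page TIFF stack as a volume
#'
#' Pages become z-slices; the returned array has axis order (z, y, x).
#' 16-bit stacks are read as intensity volumes; 8-bit stacks as label volumes
#' whose codes must all belong to [label_codes()] (or to a supplied
#' remapping).
#'
#' @param path TIFF file path.
#' @param type `"auto"` infers from bit depth; or force `"intensity"` /
#'   `"labels"`.
#' @param code_map Optional named integer vector remapping foreign label
#'   codes to the package's codes, e.g. `c("0" = 1, "255" = 2)`.
#' @return Numeric (intensity) or integer (labels) 3D array.
#' @export
read_stack <- function(path, type = c("auto", "intensity", "labels"),
                       code_map = NULL) {
  type <- match.arg(type)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  shapes <- vapply(pages, function(p) paste(dim(p), collapse = "x"), character(1))
  if (length(unique(shapes)) != 1L)
    stop("ragged TIFF: page ", which(shapes != shapes[1])[1],
         " has shape ", shapes[shapes != shapes[1]][1], " vs ", shapes[1],
         call. = FALSE)
  bits <- attr(pages[[1]], "bits.per.sample")
  if (type == "auto")
    type <- if (!is.null(bits) && bits <= 8) "labels" else "intensity"
  d <- dim(pages[[1]])
  vol <- aperm(array(unlist(pages), c(d[1], d[2], length(pages))), c(3, 1, 2))
  if (type == "labels") {
    vol <- array(as.integer(vol), dim(vol))
    if (!is.null(code_map)) {
      out <- array(NA_integer_, dim(vol))
      for (from in names(code_map))
        out[vol == as.integer(from)] <- as.integer(code_map[[from]])
      if (anyNA(out))
        stop("label stack contains codes missing from code_map: ",
             paste(setdiff(unique(vol), as.integer(names(code_map))), collapse = ", "),
             call. = FALSE)
      vol <- out
    }
    bad <- setdiff(unique(as.vector(vol)), label_codes())
    if (length(bad))
      stop("label stack contains unknown codes: ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  vol
}

#' Write a volume as a multi-page TIFF stack
#'
#' Intensity volumes are written as 16-bit pages, label volumes as 8-bit.
#'
#' @param volume 3D array, axis order (z, y, x).
#' @param path Output file path.
#' @param bits 16 (intensity) or 8 (labels).
#' @export
write_stack <- function(volume, path, bits = 16L) {
  stopifnot(bits %in% c(8L, 16L))
  maxv <- 2^bits - 1
  if (any(volume < 0) || any(volume > maxv))
    stop("volume values outside [0, ", maxv, "]", call. = FALSE)
  pages <- lapply(seq_len(dim(volume)[1]), function(z)
    matrix(volume[z, , ] / maxv, dim(volume)[2], dim(volume)[3]))
  tiff::writeTIFF(pages, path, bits.per.sample = bits)
  invisible(path)
}

#' Full run configuration
#'
#' Bundles every stage's configuration plus a global seed; round-trips
#' losslessly through YAML with all defaulted fields written explicitly.
#'
#' @param synthetic A [synthetic_spec()] (or list of them, one per cube).
#' @param sampling A [sample_config()].
#' @param augment An [augment_config()].
#' @param weights A [class_weights()].
#' @param training A [train_config()].
#' @param model A [model_spec()].
#' @param inference A [window_geometry()].
#' @param seed Global seed.
#' @return A `run_config` list.
#' @export
run_config <- function(synthetic = synthetic_spec(), sampling = sample_config(),
                       augment = augment_config(), weights = class_weights(),
                       training = train_config(), model = model_spec(),
                       inference = window_geometry(), seed = 1L) {
  structure(list(synthetic = synthetic, sampling = sampling, augment = augment,
                 weights = weights, training = training, model = model,
                 inference = inference, seed = as.integer(seed)),
            class = "run_config")
}

config_classes <- function() {
  c(synthetic = "synthetic_spec", sampling = "sample_config",
    augment = "augment_config", weights = "class_weights",
    training = "train_config", model = "model_spec",
    inference = "window_geometry")
}

#' Save a run configuration as YAML
#' @param cfg A [run_config()].
#' @param path Output path.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(lapply(unclass(cfg), function(x)
    if (is.list(x)) unclass(x) else x), path)
  invisible(path)
}

#' Load a run configuration from YAML
#' @param path YAML path written by [write_run_config()].
#' @return A `run_config` with section classes restored.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cls <- config_classes()
  for (nm in names(cls)) {
    if (!is.null(raw[[nm]])) {
      sec <- raw[[nm]]
      # yaml scalarizes length-1 vectors; restore known numeric pairs
      for (f in c("radius_range", "intensity_scale", "intensity_shift"))
        if (!is.null(sec[[f]])) sec[[f]] <- as.numeric(unlist(sec[[f]]))
      raw[[nm]] <- structure(sec, class = cls[[nm]])
    }
  }
  structure(raw, class = "run_config")
}

#' Write a reproducibility sidecar next to an artifact
#'
#' Records the stage name, the seed, a digest of the run configuration and a
#' timestamp as JSON, so every on-disk artifact is attributable.
#'
#' @param artifact_path Path of the artifact the sidecar describes.
#' @param cfg The `run_config` used.
#' @param stage Pipeline stage name.
#' @return The sidecar path, invisibly.
#' @export
write_sidecar <- function(artifact_path, cfg, stage) {
  side <- paste0(artifact_path, ".json")
  jsonlite::write_json(list(
    stage = stage,
    seed = cfg$seed,
    config_hash = sum(utf8ToInt(paste(deparse(unclass(cfg)), collapse = ""))),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  ), side, auto_unbox = TRUE)
  invisible(side)
}
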