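# Dense prediction mapping by mirror-padded sliding-window classification.
#
# The image is first extended by reflecting `pad = patch_size/2` pixels
# on every side (so lesions at the frame border survive the later vote),
# then a `patch_size` window slides in `step`-pixel strides; each window
# is normalized, classified, binarized at the decision threshold, and
# the bit is written at the grid cell of the window's center. For the
# native 2,592 x 2,048 frame with a 278 window and 10-px step this gives
# a 260 x 205 grid = 53,300 window predictions.
#
# Grid-size convention: the window start positions are 0, step, 2*step,
# ..., giving floor((L - patch)/step) + 1 cells per axis (the inclusive
# fencepost count). This is the convention that reproduces the 53,300
# figure; the alternative `"truncate"` convention, floor((L-patch)/step),
# is available for comparison but is not the default.

#' Mapper configuration
#'
#' @param patch_size sliding-window edge in pixels (even; default 278).
#' @param pad mirror-padding width; must equal `patch_size / 2`.
#' @param step window stride in pixels.
#' @param decision_threshold probability at/above which a window is
#'   called positive (default 0.5, the round-off rule with ties going to
#'   positive).
#' @param convention `"fencepost"` (default) or `"truncate"`; see module
#'   notes.
#' @return a `mapper_config`.
#' @export
mapper_config <- function(patch_size = 278L, pad = patch_size / 2L,
                          step = 10L, decision_threshold = 0.5,
                          convention = c("fencepost", "truncate")) {
  convention <- match.arg(convention)
  patch_size <- as.integer(patch_size)
  pad <- as.integer(pad)
  if (patch_size %% 2L != 0L) stopf("mapper_config: patch_size must be even")
  if (pad != patch_size %/% 2L) {
    stopf("mapper_config: pad must equal patch_size / 2")
  }
  if (step < 1L) stopf("mapper_config: step must be >= 1")
  structure(list(patch_size = patch_size, pad = pad, step = as.integer(step),
                 decision_threshold = decision_threshold,
                 convention = convention),
            class = "mapper_config")
}

#' Mirror-pad a raster
#'
#' Reflects `pad` pixels about each border without repeating the edge
#' pixel (a row `1 2 3` padded by 2 becomes `3 2 | 1 2 3 | 2 1`), so a
#' 2,592 x 2,048 frame padded by 139 becomes 2,870 x 2,326.
#'
#' @param image matrix or H x W x C array.
#' @param pad padding width in pixels; must be smaller than each image
#'   dimension.
#' @return the padded raster.
#' @export
mirror_pad <- function(image, pad) {
  pad <- as.integer(pad)
  if (pad < 0L) stopf("mirror_pad: pad must be >= 0")
  if (pad == 0L) return(image)
  if (is.null(dim(image))) {             # 1-D signal
    n <- length(image)
    if (pad >= n) {
      stopf("mirror_pad: pad %d too large for length %d (edge pixel is not repeated)",
            pad, n)
    }
    return(image[c((pad + 1L):2L, 1:n, (n - 1L):(n - pad))])
  }
  d <- dim(image)
  h <- d[1]; w <- d[2]
  if (pad >= h || pad >= w) {
    stopf("mirror_pad: pad %d too large for a %d x %d image (edge pixel is not repeated)",
          pad, w, h)
  }
  ridx <- c((pad + 1L):2L, 1:h, (h - 1L):(h - pad))
  cidx <- c((pad + 1L):2L, 1:w, (w - 1L):(w - pad))
  if (length(d) == 2L) {
    image[ridx, cidx, drop = FALSE]
  } else {
    image[ridx, cidx, , drop = FALSE]
  }
}

#' Number of sliding-window positions along one axis
#'
#' @param length padded axis length in pixels.
#' @param patch_size window edge in pixels.
#' @param step stride in pixels.
#' @param convention `"fencepost"` (floor((L - patch)/step) + 1, default)
#'   or `"truncate"` (without the + 1).
#' @return integer count of window positions.
#' @export
grid_shape <- function(length, patch_size = 278L, step = 10L,
                       convention = c("fencepost", "truncate")) {
  convention <- match.arg(convention)
  if (length < patch_size) {
    stopf("grid_shape: length %d smaller than patch size %d",
          length, patch_size)
  }
  n <- (length - patch_size) %/% step
  if (convention == "fencepost") as.integer(n + 1L) else as.integer(n)
}

#' Prediction-map container
#'
#' @param grid binary matrix (n_rows x n_cols) of window calls.
#' @param config the [mapper_config()] used.
#' @param source_dim `(height, width)` of the unpadded source image.
#' @return a `prediction_map`. The window whose grid index is `(i, j)`
#'   (0-based) starts at padded-image pixel `(i*step, j*step)` and its
#'   center -- defined for the even window as offset `patch_size/2` from
#'   the window's top-left -- falls on original-image pixel
#'   `(i*step, j*step)` (0-based), i.e. `origin_offset` equals
#'   `pad + patch_size/2` in padded coordinates.
#' @export
prediction_map <- function(grid, config, source_dim) {
  stopifnot(all(grid %in% c(0L, 1L)))
  structure(list(grid = grid, step = config$step,
                 patch_size = config$patch_size,
                 origin_offset = config$pad + config$patch_size %/% 2L,
                 source_dim = as.integer(source_dim),
                 convention = config$convention),
            class = "prediction_map")
}

#' @export
print.prediction_map <- function(x, ...) {
  cat(sprintf("<prediction_map> %d x %d grid, step %d, %d positive px (source %d x %d)\n",
              nrow(x$grid), ncol(x$grid), x$step, sum(x$grid),
              x$source_dim[2], x$source_dim[1]))
  invisible(x)
}

map_grid_dims <- function(image_dim, config) {
  padded <- image_dim[1:2] + 2L * config$pad
  c(grid_shape(padded[1], config$patch_size, config$step, config$convention),
    grid_shape(padded[2], config$patch_size, config$step, config$convention))
}

# Tumor fraction of every sliding window, via a summed-area table over
# the mirror-padded mask. Returns an n_rows x n_cols matrix.
window_tumor_fractions <- function(mask, config) {
  padded_mask <- mirror_pad(mask, config$pad)
  nd <- map_grid_dims(dim(mask), config)
  rows0 <- (seq_len(nd[1]) - 1L) * config$step
  cols0 <- (seq_len(nd[2]) - 1L) * config$step
  box_sums(padded_mask > 0, config$patch_size, rows0, cols0) /
    config$patch_size^2
}

#' Build the dense binary prediction map of an image
#'
#' @param image a [labeled_image()].
#' @param classifier a patch classifier (see [predict_proba()]).
#' @param config a [mapper_config()].
#' @param batch ignored hook for future batching; classification is
#'   per-window.
#' @return a [prediction_map()].
#'
#' @details For a [noisy_oracle()] classifier a fast whole-grid path is
#'   used: ground-truth window labels are computed with a summed-area
#'   table and flipped with the oracle's seeded uniform stream. The
#'   result is identical to the per-window path (tested), just without
#'   materializing 278 x 278 windows tens of thousands of times.
#' @export
build_map <- function(image, classifier, config = mapper_config(),
                      use_fast_path = TRUE) {
  d <- dim(image$rgb)
  nd <- map_grid_dims(d, config)
  if (use_fast_path && inherits(classifier, "noisy_oracle")) {
    frac <- window_tumor_fractions(image$mask, config)
    truth <- matrix(
      as.integer(window_is_positive_vec(frac, classifier$min_tumor_fraction)),
      nd[1], nd[2])
    u <- oracle_uniforms(classifier, nd[1], nd[2])
    prob <- ifelse(truth == 1L,
                   ifelse(u < classifier$fn_rate, 0, 1),
                   ifelse(u < classifier$fp_rate, 1, 0))
    grid <- (prob >= config$decision_threshold) * 1L
    return(prediction_map(grid, config, d[1:2]))
  }
  padded <- mirror_pad(image$rgb, config$pad)
  oracle_truth <- NULL
  if (inherits(classifier, "noisy_oracle")) {
    frac <- window_tumor_fractions(image$mask, config)
    oracle_truth <- matrix(
      as.integer(window_is_positive_vec(frac, classifier$min_tumor_fraction)),
      nd[1], nd[2])
  }
  grid <- matrix(0L, nd[1], nd[2])
  for (i in seq_len(nd[1])) {
    y0 <- (i - 1L) * config$step
    ys <- (y0 + 1L):(y0 + config$patch_size)
    for (j in seq_len(nd[2])) {
      x0 <- (j - 1L) * config$step
      xs <- (x0 + 1L):(x0 + config$patch_size)
      win <- normalize_patch(padded[ys, xs, , drop = FALSE])
      p <- tryCatch(
        predict_proba(classifier, win,
                      grid_pos = c(i - 1L, j - 1L), grid_dim = nd,
                      truth = if (is.null(oracle_truth)) NULL else
                        oracle_truth[i, j]),
        error = function(e) {
          stopf("build_map: classifier failed at window (%d, %d): %s",
                i - 1L, j - 1L, conditionMessage(e))
        })
      if (is.null(p) || is.na(p) || p < 0 || p > 1) {
        stopf("build_map: invalid probability at window (%d, %d)",
              i - 1L, j - 1L)
      }
      grid[i, j] <- (p >= config$decision_threshold) * 1L
    }
  }
  prediction_map(grid, config, d[1:2])
}

window_is_positive_vec <- function(fraction, min_tumor_fraction) {
  if (min_tumor_fraction <= 0) fraction > 0 else fraction >= min_tumor_fraction
}

#' Ground-truth prediction map from the mask
#'
#' Same grid geometry as [build_map()], but every window is labeled from
#' the image's tumor mask with the [label_patch()] rule instead of a
#' classifier. Used as the reference grid for map-level evaluation.
#'
#' @param image a [labeled_image()].
#' @param config a [mapper_config()].
#' @param min_tumor_fraction window labeling threshold.
#' @return a [prediction_map()].
#' @export
ground_truth_map <- function(image, config = mapper_config(),
                             min_tumor_fraction = 0) {
  frac <- window_tumor_fractions(image$mask, config)
  grid <- matrix(as.integer(window_is_positive_vec(frac, min_tumor_fraction)),
                 nrow(frac), ncol(frac))
  prediction_map(grid, config, dim(image$rgb)[1:2])
}

#' Write a prediction map as a 0/255 PNG plus a JSON geometry sidecar
#'
#' @param map a [prediction_map()].
#' @param path output PNG path; the sidecar is written at `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  write_png(map$grid * 255L, path)
  meta <- list(step = map$step, patch_size = map$patch_size,
               origin_offset = map$origin_offset,
               source_dim = map$source_dim, convention = map$convention)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a prediction map written by [write_map()]
#'
#' @param path PNG path with a `<path>.json` sidecar.
#' @return a [prediction_map()].
#' @export
read_map <- function(path) {
  grid <- (read_png(path) > 127L) * 1L
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  cfg <- mapper_config(patch_size = meta$patch_size, step = meta$step,
                       convention = meta$convention)
  prediction_map(grid, cfg, meta$source_dim)
}
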