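# Patch extraction, normalization, labeling and node-grouped splits.
#
# Frames are tiled into non-overlapping 278 x 278 patches from the
# top-left origin; residual right/bottom margins are discarded, so the
# native 2,592 x 2,048 frame yields a 9 x 7 = 63-patch grid. Grid indices
# are 0-based, row-major.

#' Divide an image into non-overlapping patches
#'
#' @param image a [labeled_image()] (or any list with `rgb`, `mask`,
#'   `node_id`, `status` fields).
#' @param patch_size tile edge length in pixels (default 278).
#' @return a list of patch records, each with fields `pixels` (raw 8-bit
#'   values as an array, un-normalized), `grid_row`/`grid_col` (0-based),
#'   `mask` (the aligned mask tile), `node_id`, `source_status`,
#'   `tumor_fraction`, and `label` (unset, see [label_patch()]).
#' @export
divide_into_patches <- function(image, patch_size = 278L) {
  d <- dim(image$rgb)
  h <- d[1]; w <- d[2]
  if (h < patch_size || w < patch_size) {
    stopf("divide_into_patches: image (%d x %d) smaller than patch size %d",
          w, h, patch_size)
  }
  n_rows <- h %/% patch_size
  n_cols <- w %/% patch_size
  out <- vector("list", n_rows * n_cols)
  k <- 1L
  for (gr in 0:(n_rows - 1L)) {
    for (gc in 0:(n_cols - 1L)) {
      ys <- (gr * patch_size + 1L):((gr + 1L) * patch_size)
      xs <- (gc * patch_size + 1L):((gc + 1L) * patch_size)
      mask_tile <- image$mask[ys, xs, drop = FALSE]
      out[[k]] <- list(
        pixels = image$rgb[ys, xs, , drop = FALSE],
        grid_row = gr, grid_col = gc,
        mask = mask_tile,
        node_id = image$node_id,
        source_status = image$status,
        tumor_fraction = sum(mask_tile > 0) / (patch_size^2),
        label = NA_character_
      )
      k <- k + 1L
    }
  }
  out
}

#' Normalize a patch by its global RGB maximum
#'
#' Every channel is divided by the single scalar maximum taken over all
#' pixels and all three channels, so the brightest value maps to exactly
#' 1 and relative channel ratios are preserved. An all-zero patch is
#' returned unchanged with a warning (documented degenerate case).
#'
#' @param raw numeric/integer H x W x 3 array.
#' @return a double array in `[0, 1]`.
#' @export
normalize_patch <- function(raw) {
  if (length(dim(raw)) != 3 || dim(raw)[3] != 3) {
    stopf("normalize_patch: expected an H x W x 3 array")
  }
  m <- max(raw)
  if (m <= 0) {
    warning("normalize_patch: all-zero patch left unchanged")
    storage.mode(raw) <- "double"
    return(raw)
  }
  raw / m
}

#' Label a patch from its aligned tumor mask
#'
#' Labeling policy: patches from metastasis-negative nodes are always
#' `"negative"`; patches from positive nodes are `"positive"` when their
#' tumor fraction clears `min_tumor_fraction` and otherwise `"excluded"`
#' (never recycled as negatives, since non-tumor tissue from a positive
#' node is not a vetted negative example).
#'
#' @param patch a record from [divide_into_patches()].
#' @param min_tumor_fraction labeling threshold on the tumor-pixel
#'   fraction. The default `0` means "any positive pixel" (strictly
#'   greater than zero); a positive value `f` means `fraction >= f`.
#' @return the patch with `label` (and `tumor_fraction`) filled in.
#' @export
label_patch <- function(patch, min_tumor_fraction = 0) {
  frac <- sum(patch$mask > 0) / length(patch$mask)
  patch$tumor_fraction <- frac
  patch$label <- if (patch$source_status == "negative") {
    "negative"
  } else if (window_is_positive(frac, min_tumor_fraction)) {
    "positive"
  } else {
    "excluded"
  }
  patch
}

# Shared labeling rule for patches and sliding windows: with threshold 0
# any tumor pixel makes the window positive; with a positive threshold
# the fraction must reach it.
window_is_positive <- function(fraction, min_tumor_fraction) {
  if (min_tumor_fraction <= 0) fraction > 0 else fraction >= min_tumor_fraction
}

#' Extract and label all patches of a set of images
#'
#' @param images list of [labeled_image()].
#' @param patch_size tile size in pixels.
#' @param min_tumor_fraction see [label_patch()].
#' @return flat list of labeled patch records.
#' @export
extract_labeled_patches <- function(images, patch_size = 278L,
                                    min_tumor_fraction = 0) {
  out <- list()
  for (img in images) {
    patches <- divide_into_patches(img, patch_size)
    out <- c(out, lapply(patches, label_patch,
                         min_tumor_fraction = min_tumor_fraction))
  }
  out
}

#' Split labeled patches into train/validation/test by lymph node
#'
#' All patches sharing a `node_id` land in exactly one split, preventing
#' leakage of within-node correlation across datasets. Nodes are
#' partitioned per class (positive nodes and negative nodes separately)
#' so each split receives both classes whenever enough nodes exist.
#' Patches labeled `"excluded"` are dropped.
#'
#' @param patches labeled patch records.
#' @param fractions length-3 numeric summing to 1: train, validation, test.
#' @param seed RNG seed for the node shuffle.
#' @return list with `train`, `validation`, `test` (patch lists) and
#'   `group_map` (named character: node_id -> split).
#' @export
split_by_node <- function(patches, fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  if (length(fractions) != 3 || abs(sum(fractions) - 1) > 1e-8) {
    stopf("split_by_node: fractions must be three values summing to 1")
  }
  used <- Filter(function(p) p$label %in% c("positive", "negative"), patches)
  if (length(used) == 0) stopf("split_by_node: no usable patches")
  node_of <- vapply(used, `[[`, "", "node_id")
  class_of <- vapply(used, `[[`, "", "source_status")
  node_class <- tapply(class_of, node_of, function(x) x[1])
  n_splits_wanted <- sum(fractions > 0)
  group_map <- character(0)
  for (cls in unique(node_class)) {
    nodes <- names(node_class)[node_class == cls]
    if (length(nodes) < n_splits_wanted) {
      stopf("split_by_node: class '%s' has %d node(s); need >= %d to fill every requested split without leakage",
            cls, length(nodes), n_splits_wanted)
    }
    nodes <- with_seed(derive_seed(seed, match(cls, unique(node_class))),
                       sample(nodes))
    # largest-remainder allocation of nodes to splits, min 1 per used split
    n <- length(nodes)
    alloc <- floor(fractions * n)
    alloc[fractions > 0] <- pmax(alloc[fractions > 0], 1L)
    while (sum(alloc) > n) alloc[which.max(alloc)] <- alloc[which.max(alloc)] - 1L
    while (sum(alloc) < n) {
      i <- which.max(fractions * n - alloc)
      alloc[i] <- alloc[i] + 1L
    }
    splits <- rep(c("train", "validation", "test"), times = alloc)
    gm <- stats::setNames(splits, nodes)
    group_map <- c(group_map, gm)
  }
  pick <- function(split_name) {
    used[group_map[node_of] == split_name]
  }
  list(train = pick("train"), validation = pick("validation"),
       test = pick("test"), group_map = group_map)
}
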