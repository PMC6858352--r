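# Shared fixtures and independent oracles for the test suite.
# Everything is generated in code; nothing is read from disk.

# A small, quick scene: ~300 px frames with one modest lesion.
small_scene <- function(seed = 1L, n_lesions = 1L, width = 320L,
                        height = 300L, pattern = "glandular", ...) {
  scene_spec(width = width, height = height, n_lesions = n_lesions,
             lesion_diameter_range = c(40, 70),
             n_histiocyte_nodules = 1L,
             histiocyte_nodule_diameter_range = c(40, 70),
             lesion_pattern = pattern, seed = seed, ...)
}

# Connected-component count by breadth-first flood fill (4-connectivity);
# deliberately naive and independent of any package code.
flood_fill_components <- function(mask) {
  seen <- matrix(FALSE, nrow(mask), ncol(mask))
  n <- 0L
  for (start_r in seq_len(nrow(mask))) {
    for (start_c in seq_len(ncol(mask))) {
      if (mask[start_r, start_c] > 0 && !seen[start_r, start_c]) {
        n <- n + 1L
        queue <- list(c(start_r, start_c))
        seen[start_r, start_c] <- TRUE
        while (length(queue) > 0) {
          p <- queue[[length(queue)]]
          queue[[length(queue)]] <- NULL
          for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
            q <- p + d
            if (q[1] >= 1 && q[1] <= nrow(mask) &&
                q[2] >= 1 && q[2] <= ncol(mask) &&
                mask[q[1], q[2]] > 0 && !seen[q[1], q[2]]) {
              seen[q[1], q[2]] <- TRUE
              queue[[length(queue) + 1L]] <- q
            }
          }
        }
      }
    }
  }
  n
}

# Brute-force majority vote: per-output-pixel double loop with an
# explicit count, the counting oracle the optimized box-sum is checked
# against.
brute_majority <- function(grid, vote_window, threshold) {
  nr <- nrow(grid) - vote_window + 1L
  nc <- ncol(grid) - vote_window + 1L
  out <- matrix(0L, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      frac <- sum(grid[i:(i + vote_window - 1L),
                       j:(j + vote_window - 1L)]) / vote_window^2
      out[i, j] <- (frac > threshold) * 1L
    }
  }
  out
}

# Brute-force ground-truth grid: crop every padded-mask window and apply
# the any-tumor-pixel rule directly.
brute_truth_grid <- function(image, config, min_tumor_fraction = 0) {
  padded <- mirror_pad(image$mask, config$pad)
  nr <- (nrow(padded) - config$patch_size) %/% config$step + 1L
  nc <- (ncol(padded) - config$patch_size) %/% config$step + 1L
  out <- matrix(0L, nr, nc)
  for (i in seq_len(nr)) {
    ys <- ((i - 1L) * config$step + 1L):((i - 1L) * config$step + config$patch_size)
    for (j in seq_len(nc)) {
      xs <- ((j - 1L) * config$step + 1L):((j - 1L) * config$step + config$patch_size)
      frac <- sum(padded[ys, xs] > 0) / config$patch_size^2
      pos <- if (min_tumor_fraction <= 0) frac > 0 else frac >= min_tumor_fraction
      out[i, j] <- pos * 1L
    }
  }
  out
}

# Toy patches for classifier tests. Per-patch max normalization erases
# absolute brightness, so the classes differ in channel RATIO:
# green-dominant (positive, cytoplasm-like) vs blue-dominant (negative,
# lymphocyte-like). A threshold on mean normalized green separates them
# perfectly.
make_toy_patches <- function(n_per_class, size = 32L, seed = 1L) {
  set.seed(seed)
  mk <- function(label) {
    lapply(seq_len(n_per_class), function(i) {
      base <- matrix(pmin(pmax(round(rnorm(size^2, 180, 15)), 1), 255),
                     size, size)
      px <- array(0L, dim = c(size, size, 3))
      if (label == "positive") {
        px[, , 2] <- base; px[, , 3] <- base %/% 3L
      } else {
        px[, , 3] <- base; px[, , 2] <- base %/% 3L
      }
      px[, , 1] <- base %/% 4L
      list(pixels = px, label = label,
           node_id = sprintf("%s%02d", label, i %% 4L),
           source_status = if (label == "positive") "positive" else "negative",
           mask = matrix(0L, size, size), tumor_fraction = 0)
    })
  }
  c(mk("positive"), mk("negative"))
}

# A labeled image with an all-zero frame (geometry carrier for
# paper-frame map tests; content is irrelevant on the oracle fast path).
blank_image <- function(height, width) {
  labeled_image(array(0L, dim = c(height, width, 3)),
                matrix(0L, height, width))
}
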