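# Synthetic deep-UV fluorescence lymph-node scenes with ground truth.
#
# The generator renders the three tissue elements whose contrasts drive
# metastasis diagnosis in DNA/RNA-stained DUV excitation images:
#   * lymphocytes      - dense small round nuclei, blue (DAPI/DNA channel),
#                        almost no cytoplasm;
#   * metastatic cells - enlarged nuclei with bright green nucleoli and
#                        abundant green (RNA channel) cytoplasm, arranged
#                        in glandular, cribriform or solid growth patterns;
#   * histiocytes      - the hard-negative confounder: intermediate-size
#                        cells with green cytoplasm but no prominent
#                        nucleoli, clustered into nodules.
# Rendering is parametric-geometric (soft-edged discs and annuli), not
# physics-based: only the classifier-relevant contrasts need to be
# controllable. Gaussian sensor noise and a multiplicative illumination
# gradient are applied last.

#' Scene specification for the synthetic generator
#'
#' Defaults describe the native imaging geometry of the target system:
#' 2,592 x 2,048 pixel frames at 0.46 um/pixel. Tests typically shrink
#' `width`/`height`; all sizes in micrometres are converted through
#' `pixel_size` so morphology is scale-consistent.
#'
#' @param width,height frame size in pixels.
#' @param pixel_size micrometres per pixel.
#' @param n_lesions number of metastatic lesions to place.
#' @param lesion_diameter_range min/max lesion footprint diameter, um.
#' @param lesion_pattern one of `"glandular"`, `"cribriform"`, `"solid"`.
#' @param n_histiocyte_nodules number of histiocyte-nodule confounders.
#' @param histiocyte_nodule_diameter_range min/max nodule footprint
#'   diameter, um.
#' @param lymphocyte_density nuclei per 100 x 100 um of tissue.
#' @param noise_sd additive Gaussian noise, as a fraction of full scale.
#' @param illumination_gradient fractional peak-to-peak range of the
#'   multiplicative illumination ramp (0 disables it).
#' @param seed RNG seed; identical specs give bit-identical images.
#' @param lymphocyte_nucleus_um,lesion_cell_nucleus_um,histiocyte_nucleus_um
#'   nuclear diameters of the three cell types, um.
#' @param placement_retries rejection-sampling cap for non-overlapping
#'   lesion/nodule placement.
#' @return an object of class `scene_spec`.
#' @export
scene_spec <- function(width = 2592, height = 2048, pixel_size = 0.46,
                       n_lesions = 2,
                       lesion_diameter_range = c(100, 400),
                       lesion_pattern = c("glandular", "cribriform", "solid"),
                       n_histiocyte_nodules = 1,
                       histiocyte_nodule_diameter_range = c(60, 150),
                       lymphocyte_density = 80,
                       noise_sd = 0.02,
                       illumination_gradient = 0.10,
                       seed = 1L,
                       lymphocyte_nucleus_um = 7,
                       lesion_cell_nucleus_um = 12,
                       histiocyte_nucleus_um = 10,
                       placement_retries = 1000L) {
  lesion_pattern <- match.arg(lesion_pattern)
  spec <- list(
    width = as.integer(width), height = as.integer(height),
    pixel_size = pixel_size, n_lesions = as.integer(n_lesions),
    lesion_diameter_range = as.numeric(lesion_diameter_range),
    lesion_pattern = lesion_pattern,
    n_histiocyte_nodules = as.integer(n_histiocyte_nodules),
    histiocyte_nodule_diameter_range = as.numeric(histiocyte_nodule_diameter_range),
    lymphocyte_density = lymphocyte_density,
    noise_sd = noise_sd, illumination_gradient = illumination_gradient,
    seed = as.integer(seed),
    lymphocyte_nucleus_um = lymphocyte_nucleus_um,
    lesion_cell_nucleus_um = lesion_cell_nucleus_um,
    histiocyte_nucleus_um = histiocyte_nucleus_um,
    placement_retries = as.integer(placement_retries)
  )
  class(spec) <- "scene_spec"
  validate_scene_spec(spec)
  spec
}

validate_scene_spec <- function(spec) {
  with(spec, {
    if (width <= 0 || height <= 0) {
      stopf("scene_spec: width and height must be positive",
            class = "duvmap_spec_error")
    }
    if (length(lesion_diameter_range) != 2 ||
        lesion_diameter_range[1] > lesion_diameter_range[2]) {
      stopf("scene_spec: lesion_diameter_range must be (min, max)",
            class = "duvmap_spec_error")
    }
    if (n_lesions > 0 &&
        lesion_diameter_range[1] < 2 * lymphocyte_nucleus_um) {
      stopf("scene_spec: minimum lesion diameter must be at least twice the lymphocyte nucleus diameter",
            class = "duvmap_spec_error")
    }
    if (lymphocyte_density < 0 || n_lesions < 0 || n_histiocyte_nodules < 0 ||
        noise_sd < 0 || illumination_gradient < 0) {
      stopf("scene_spec: densities, counts and noise must be non-negative",
            class = "duvmap_spec_error")
    }
  })
  invisible(spec)
}

#' Construct a labeled image
#'
#' @param rgb H x W x 3 integer array, 0..255.
#' @param mask H x W binary matrix, 1 = tumor.
#' @param node_id opaque lymph-node group key.
#' @return an object of class `labeled_image`; `status` is derived from the
#'   mask (`"positive"` iff it has at least one foreground pixel).
#' @export
labeled_image <- function(rgb, mask, node_id = NA_character_) {
  stopifnot(length(dim(rgb)) == 3, dim(rgb)[3] == 3,
            all(dim(mask) == dim(rgb)[1:2]))
  structure(
    list(rgb = rgb, mask = mask, node_id = node_id,
         status = if (any(mask > 0)) "positive" else "negative"),
    class = "labeled_image"
  )
}

#' @export
print.labeled_image <- function(x, ...) {
  cat(sprintf("<labeled_image> %d x %d px, node=%s, status=%s, tumor px=%d\n",
              dim(x$rgb)[2], dim(x$rgb)[1], x$node_id, x$status,
              sum(x$mask > 0)))
  invisible(x)
}

# --- rendering primitives ---------------------------------------------------

# Alpha-over stamp of a soft-edged disc onto the channel matrices held in
# environment `e` (fields R, G, B, h, w). `clip`, if given, is a function
# (x, y) -> multiplicative alpha evaluated on the local window.
stamp_disc <- function(e, cx, cy, radius, color, edge = 1.5, alpha = 1,
                       clip = NULL) {
  r_out <- radius + edge
  x0 <- max(1L, floor(cx - r_out)); x1 <- min(e$w, ceiling(cx + r_out))
  y0 <- max(1L, floor(cy - r_out)); y1 <- min(e$h, ceiling(cy + r_out))
  if (x0 > x1 || y0 > y1) return(invisible())
  xs <- x0:x1; ys <- y0:y1
  dx2 <- (xs - cx)^2
  dy2 <- (ys - cy)^2
  d <- sqrt(outer(dy2, dx2, `+`))
  a <- clamp01((radius + edge - d) / edge) * alpha
  if (!is.null(clip)) a <- a * clip(xs, ys)
  if (all(a == 0)) return(invisible())
  e$R[ys, xs] <- color[1] * a + e$R[ys, xs] * (1 - a)
  e$G[ys, xs] <- color[2] * a + e$G[ys, xs] * (1 - a)
  e$B[ys, xs] <- color[3] * a + e$B[ys, xs] * (1 - a)
  invisible()
}

# Indicator of an axis-aligned ellipse, usable as a `clip` function.
ellipse_clip <- function(cx, cy, rx, ry) {
  function(xs, ys) {
    u2 <- ((xs - cx) / rx)^2
    v2 <- ((ys - cy) / ry)^2
    (outer(v2, u2, `+`) <= 1) * 1
  }
}

# Jittered hexagonal packing of points covering an ellipse.
hex_points <- function(cx, cy, rx, ry, spacing, jitter) {
  xs <- seq(cx - rx, cx + rx, by = spacing)
  ys <- seq(cy - ry, cy + ry, by = spacing * 0.87)
  if (length(xs) == 0) xs <- cx
  if (length(ys) == 0) ys <- cy
  pts <- expand.grid(x = xs, y = ys)
  odd <- (match(pts$y, ys) %% 2) == 1
  pts$x <- pts$x + ifelse(odd, spacing / 2, 0)
  pts$x <- pts$x + stats::runif(nrow(pts), -jitter, jitter)
  pts$y <- pts$y + stats::runif(nrow(pts), -jitter, jitter)
  keep <- ((pts$x - cx) / rx)^2 + ((pts$y - cy) / ry)^2 <= 1
  pts[keep, , drop = FALSE]
}

# One epithelial-like cell: green cytoplasm disc, blue nucleus, optional
# bright-green nucleoli. Radii in pixels.
stamp_cell <- function(e, cx, cy, r_nuc, r_cyt, colors, n_nucleoli = 0,
                       r_nucleolus = 0, clip = NULL) {
  stamp_disc(e, cx, cy, r_cyt, colors$cytoplasm, edge = 2, clip = clip)
  stamp_disc(e, cx, cy, r_nuc, colors$nucleus, edge = 1.5, clip = clip)
  if (n_nucleoli > 0) {
    for (k in seq_len(n_nucleoli)) {
      ang <- stats::runif(1, 0, 2 * pi)
      rad <- stats::runif(1, 0, 0.45 * r_nuc)
      stamp_disc(e, cx + rad * cos(ang), cy + rad * sin(ang),
                 r_nucleolus, colors$nucleolus, edge = 1, clip = clip)
    }
  }
}

# Rejection-sample `n` non-overlapping ellipse footprints (diameters in
# pixels drawn from `diam_range_px`) fully inside the frame.
place_footprints <- function(n, w, h, diam_range_px, retries, existing = NULL) {
  placed <- existing %||% list()
  n_existing <- length(placed)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(retries)) {
      rx <- stats::runif(1, diam_range_px[1], diam_range_px[2]) / 2
      ry <- stats::runif(1, diam_range_px[1], diam_range_px[2]) / 2
      if (2 * rx + 4 > w || 2 * ry + 4 > h) next
      cx <- stats::runif(1, rx + 2, w - rx - 2)
      cy <- stats::runif(1, ry + 2, h - ry - 2)
      r_eff <- max(rx, ry)
      clash <- FALSE
      for (p in placed) {
        if (sqrt((cx - p$cx)^2 + (cy - p$cy)^2) <
            r_eff + max(p$rx, p$ry) + 6) { clash <- TRUE; break }
      }
      if (!clash) {
        placed[[length(placed) + 1L]] <- list(cx = cx, cy = cy, rx = rx, ry = ry)
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stopf("placement failed after %d retries: frame too small for the requested footprints",
            retries, class = "duvmap_placement_error")
    }
  }
  placed[seq.int(n_existing + 1L, length.out = n)]
}

render_lesion <- function(e, fp, pattern, r_nuc, px) {
  clip <- ellipse_clip(fp$cx, fp$cy, fp$rx, fp$ry)
  r_cyt <- 1.8 * r_nuc
  r_nucleolus <- max(1.5, 1.5 / px)
  colors <- list(cytoplasm = c(60, 150, 40), nucleus = c(40, 70, 170),
                 nucleolus = c(90, 230, 60))
  cell <- function(x, y) {
    stamp_cell(e, x, y, r_nuc * stats::runif(1, 0.9, 1.1), r_cyt,
               colors, n_nucleoli = sample(1:2, 1),
               r_nucleolus = r_nucleolus, clip = clip)
  }
  if (pattern == "solid") {
    pts <- hex_points(fp$cx, fp$cy, fp$rx, fp$ry, spacing = 1.7 * r_cyt,
                      jitter = 0.25 * r_nuc)
    for (i in seq_len(nrow(pts))) cell(pts$x[i], pts$y[i])
  } else if (pattern == "glandular") {
    # rings of cells around empty lumina
    lum <- hex_points(fp$cx, fp$cy, fp$rx, fp$ry, spacing = 5.2 * r_cyt,
                      jitter = 0.5 * r_nuc)
    if (nrow(lum) == 0) lum <- data.frame(x = fp$cx, y = fp$cy)
    for (i in seq_len(nrow(lum))) {
      ring_r <- 1.9 * r_cyt
      n_cells <- max(6L, round(2 * pi * ring_r / (1.6 * r_cyt)))
      angs <- seq(0, 2 * pi, length.out = n_cells + 1)[-1] +
        stats::runif(1, 0, 2 * pi)
      for (a in angs) {
        cell(lum$x[i] + ring_r * cos(a), lum$y[i] + ring_r * sin(a))
      }
    }
  } else { # cribriform: solid sheet punctured by round lumina
    holes <- hex_points(fp$cx, fp$cy, fp$rx * 0.8, fp$ry * 0.8,
                        spacing = 4.5 * r_cyt, jitter = r_nuc)
    pts <- hex_points(fp$cx, fp$cy, fp$rx, fp$ry, spacing = 1.7 * r_cyt,
                      jitter = 0.25 * r_nuc)
    hole_r <- 1.3 * r_cyt
    for (i in seq_len(nrow(pts))) {
      if (nrow(holes) > 0) {
        dmin <- min(sqrt((pts$x[i] - holes$x)^2 + (pts$y[i] - holes$y)^2))
        if (dmin < hole_r) next
      }
      cell(pts$x[i], pts$y[i])
    }
  }
}

render_histiocyte_nodule <- function(e, fp, r_nuc) {
  clip <- ellipse_clip(fp$cx, fp$cy, fp$rx, fp$ry)
  r_cyt <- 1.6 * r_nuc
  colors <- list(cytoplasm = c(55, 115, 50), nucleus = c(35, 60, 145),
                 nucleolus = NULL)
  pts <- hex_points(fp$cx, fp$cy, fp$rx, fp$ry, spacing = 1.8 * r_cyt,
                    jitter = 0.3 * r_nuc)
  for (i in seq_len(nrow(pts))) {
    stamp_cell(e, pts$x[i], pts$y[i], r_nuc * stats::runif(1, 0.9, 1.1),
               r_cyt, colors, n_nucleoli = 0, clip = clip)
  }
}

# --- main entry points ------------------------------------------------------

#' Generate one synthetic fluorescence lymph-node image
#'
#' Deterministic: the same spec (including its seed) always produces a
#' bit-identical image and mask. The tumor mask is exactly the union of
#' the placed lesion footprints; histiocyte nodules never contribute mask
#' pixels.
#'
#' @param spec a [scene_spec()].
#' @param node_id group key stored on the result.
#' @return a [labeled_image()].
#' @export
generate_image <- function(spec, node_id = NA_character_) {
  validate_scene_spec(spec)
  with_seed(spec$seed, {
    h <- spec$height; w <- spec$width; px <- spec$pixel_size
    e <- new.env(parent = emptyenv())
    e$h <- h; e$w <- w
    e$R <- matrix(10, h, w); e$G <- matrix(14, h, w); e$B <- matrix(22, h, w)

    # background lymphocytes: small blue nuclei, negligible cytoplasm
    area_units <- (w * px / 100) * (h * px / 100)
    n_lymph <- round(spec$lymphocyte_density * area_units)
    r_lymph <- spec$lymphocyte_nucleus_um / 2 / px
    if (n_lymph > 0) {
      lx <- stats::runif(n_lymph, 1, w)
      ly <- stats::runif(n_lymph, 1, h)
      lr <- r_lymph * stats::runif(n_lymph, 0.85, 1.15)
      lb <- stats::runif(n_lymph, 0.85, 1.15)
      for (i in seq_len(n_lymph)) {
        stamp_disc(e, lx[i], ly[i], lr[i],
                   c(28, 42, 185) * lb[i], edge = 1.2)
      }
    }

    # non-overlapping footprints: lesions first, then confounder nodules
    diam_px <- spec$lesion_diameter_range / px
    lesions <- place_footprints(spec$n_lesions, w, h, diam_px,
                                spec$placement_retries)
    nod_diam_px <- spec$histiocyte_nodule_diameter_range / px
    nodules <- place_footprints(spec$n_histiocyte_nodules, w, h, nod_diam_px,
                                spec$placement_retries, existing = lesions)

    mask <- matrix(0L, h, w)
    r_nuc_lesion <- spec$lesion_cell_nucleus_um / 2 / px
    for (fp in lesions) {
      render_lesion(e, fp, spec$lesion_pattern, r_nuc_lesion, px)
      x0 <- max(1L, floor(fp$cx - fp$rx)); x1 <- min(w, ceiling(fp$cx + fp$rx))
      y0 <- max(1L, floor(fp$cy - fp$ry)); y1 <- min(h, ceiling(fp$cy + fp$ry))
      xs <- x0:x1; ys <- y0:y1
      ind <- ellipse_clip(fp$cx, fp$cy, fp$rx, fp$ry)(xs, ys)
      mask[ys, xs] <- pmax(mask[ys, xs], ind)
    }
    r_nuc_hist <- spec$histiocyte_nucleus_um / 2 / px
    for (fp in nodules) render_histiocyte_nodule(e, fp, r_nuc_hist)

    # multiplicative illumination ramp along a random direction
    if (spec$illumination_gradient > 0) {
      ang <- stats::runif(1, 0, 2 * pi)
      tx <- cos(ang) * (seq_len(w) - 1) / max(w - 1, 1)
      ty <- sin(ang) * (seq_len(h) - 1) / max(h - 1, 1)
      t01 <- outer(ty, tx, `+`)
      rng <- range(t01)
      t01 <- if (diff(rng) > 0) (t01 - rng[1]) / diff(rng) else t01 * 0 + 0.5
      fac <- 1 + spec$illumination_gradient * (t01 - 0.5)
      e$R <- e$R * fac; e$G <- e$G * fac; e$B <- e$B * fac
    }

    # sensor noise
    if (spec$noise_sd > 0) {
      sd <- spec$noise_sd * 255
      e$R <- e$R + stats::rnorm(h * w, 0, sd)
      e$G <- e$G + stats::rnorm(h * w, 0, sd)
      e$B <- e$B + stats::rnorm(h * w, 0, sd)
    }

    rgb <- array(0L, dim = c(h, w, 3))
    rgb[, , 1] <- as.integer(round(pmin(pmax(e$R, 0), 255)))
    rgb[, , 2] <- as.integer(round(pmin(pmax(e$G, 0), 255)))
    rgb[, , 3] <- as.integer(round(pmin(pmax(e$B, 0), 255)))
    storage.mode(mask) <- "integer"
    labeled_image(rgb, mask, node_id = node_id)
  })
}

#' Generate a labeled dataset of positive and negative images
#'
#' Per-image seeds are derived deterministically from the base spec's seed
#' and the image index, so datasets are reproducible and images can be
#' regenerated independently. Node identifiers are assigned round-robin
#' within each class, guaranteeing every node contributes at least one
#' image; negative images are generated with `n_lesions = 0` and contain
#' no tumor pixels.
#'
#' @param n_positive,n_negative image counts per class (each >= 1).
#' @param nodes_per_class number of distinct lymph-node identifiers per
#'   class; must not exceed the image count of that class.
#' @param base_spec a [scene_spec()] shared by all images (seed field used
#'   as the base seed). Positives use its `n_lesions` (minimum 1).
#' @return a list of [labeled_image()] objects, positives first.
#' @export
generate_dataset <- function(n_positive, n_negative, nodes_per_class,
                             base_spec = scene_spec()) {
  if (!is_count(n_positive) || !is_count(n_negative) ||
      n_positive < 1 || n_negative < 1) {
    stopf("generate_dataset: image counts must be positive integers")
  }
  if (!is_count(nodes_per_class) || nodes_per_class < 1 ||
      nodes_per_class > min(n_positive, n_negative)) {
    stopf("generate_dataset: nodes_per_class must be in 1..min(class counts)")
  }
  images <- vector("list", n_positive + n_negative)
  for (i in seq_len(n_positive)) {
    sp <- base_spec
    sp$n_lesions <- max(1L, base_spec$n_lesions)
    sp$seed <- derive_seed(base_spec$seed, i)
    node <- sprintf("P%02d", ((i - 1L) %% nodes_per_class) + 1L)
    images[[i]] <- generate_image(sp, node_id = node)
  }
  for (j in seq_len(n_negative)) {
    sp <- base_spec
    sp$n_lesions <- 0L
    sp$seed <- derive_seed(base_spec$seed, n_positive + j)
    node <- sprintf("N%02d", ((j - 1L) %% nodes_per_class) + 1L)
    images[[n_positive + j]] <- generate_image(sp, node_id = node)
  }
  images
}

#' Write a dataset to disk (PNG frames, PNG masks, CSV manifest)
#'
#' @param images list of [labeled_image()].
#' @param dir output directory (created if needed).
#' @return the manifest as a data frame (columns `path`, `mask_path`,
#'   `node_id`, `status`), invisibly; also written to `manifest.csv`.
#' @export
write_dataset <- function(images, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(images), function(i) {
    img <- images[[i]]
    p <- file.path(dir, sprintf("img_%03d.png", i))
    mp <- file.path(dir, sprintf("mask_%03d.png", i))
    write_png(img$rgb, p)
    write_png(img$mask * 255L, mp)
    data.frame(path = p, mask_path = mp, node_id = img$node_id,
               status = img$status, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Load a dataset written by [write_dataset()]
#'
#' @param dir directory containing `manifest.csv`.
#' @return list of [labeled_image()].
#' @export
load_dataset <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  lapply(seq_len(nrow(manifest)), function(i) {
    rgb <- read_png(manifest$path[i])
    mask <- read_png(manifest$mask_path[i])
    mask <- (mask > 127L) * 1L
    img <- labeled_image(rgb, mask, node_id = manifest$node_id[i])
    stopifnot(img$status == manifest$status[i])
    img
  })
}
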