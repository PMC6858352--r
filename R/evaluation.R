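# Error-budget arithmetic, overlay rendering, and end-to-end orchestration.

#' Expected misclassification count over a prediction grid
#'
#' With `n_windows` independent window predictions at a given patch-level
#' accuracy, the expected number of misclassified map pixels per image is
#' `n_windows * (1 - accuracy)`; e.g. 53,300 windows at accuracy 0.988
#' give 639.6, i.e. about 640 expected misclassification points.
#'
#' @param n_windows number of window predictions in one image.
#' @param accuracy patch-level classification accuracy in `[0, 1]`.
#' @return expected error count (real, not rounded).
#' @export
expected_error_count <- function(n_windows, accuracy) {
  if (!is.numeric(accuracy) || accuracy < 0 || accuracy > 1) {
    stopf("expected_error_count: accuracy must be in [0, 1]")
  }
  n_windows * (1 - accuracy)
}

#' Render a prediction map as a colored overlay on the source image
#'
#' Positive map pixels are blended pink, negative pixels green, on the
#' image region the map covers; every source pixel is assigned the map
#' pixel whose window center is nearest. For a majority-filtered map,
#' pass the crop offset (in map pixels) so the overlay footprint
#' respects the border reduction; pixels outside the filtered footprint
#' keep their original color.
#'
#' @param image a [labeled_image()] or an H x W x 3 array.
#' @param grid binary matrix (a raw or filtered map grid), or a
#'   [prediction_map()].
#' @param step mapping stride in image pixels (taken from the map object
#'   when one is given).
#' @param map_offset offset of the grid's (0,0) pixel relative to the
#'   unfiltered grid, in map pixels (e.g. `(vote_window - 1) / 2`).
#' @param alpha blend weight of the overlay color.
#' @return H x W x 3 integer array.
#' @export
render_overlay <- function(image, grid, step = NULL, map_offset = 0,
                           alpha = 0.35) {
  rgb <- if (inherits(image, "labeled_image")) image$rgb else image
  if (inherits(grid, "prediction_map")) {
    step <- grid$step
    grid <- grid$grid
  }
  if (is.null(step)) stopf("render_overlay: step is required")
  d <- dim(rgb)
  # nearest map index for every source pixel (0-based arithmetic)
  iy <- round((seq_len(d[1]) - 1) / step) - map_offset
  ix <- round((seq_len(d[2]) - 1) / step) - map_offset
  vy <- iy >= 0 & iy <= nrow(grid) - 1L
  vx <- ix >= 0 & ix <= ncol(grid) - 1L
  pink <- c(255, 105, 180); green <- c(60, 200, 110)
  out <- rgb
  sub_val <- grid[iy[vy] + 1L, ix[vx] + 1L, drop = FALSE]
  for (k in 1:3) {
    layer <- out[vy, vx, k]
    color <- ifelse(sub_val > 0, pink[k], green[k])
    out[vy, vx, k] <- round((1 - alpha) * layer + alpha * color)
  }
  storage.mode(out) <- "integer"
  out
}

#' Default end-to-end run configuration
#'
#' A nested list mirroring the pipeline stages. `classifier$type` selects
#' between the trainable CNN (`"cnn"`) and the ground-truth-with-noise
#' oracle (`"oracle"`, fields `fp_rate`/`fn_rate`). The scene section
#' accepts any [scene_spec()] argument. Step size and vote window are
#' validated as a pair at load time.
#'
#' @param seed global seed; every stage derives its own stream from it.
#' @return a `run_config` list.
#' @export
default_run_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    scene = list(width = 834, height = 834, n_lesions = 1,
                 lesion_diameter_range = c(150, 250),
                 n_histiocyte_nodules = 1,
                 histiocyte_nodule_diameter_range = c(60, 100)),
    data = list(n_train_positive = 4, n_train_negative = 4,
                nodes_per_class = 4, n_eval_positive = 4,
                n_eval_negative = 4),
    patching = list(patch_size = 278, min_tumor_fraction = 0),
    classifier = list(type = "oracle", fp_rate = 0.01, fn_rate = 0.01),
    training = list(phase1_epochs = 5, phase2_epochs = 5,
                    learning_rate = 0.01, dropout = 0.5),
    mapper = list(step = 70, decision_threshold = 0.5),
    majority = list(threshold = 0.7, vote_window = NULL),
    sweep = list(thresholds = seq(0.4, 0.9, by = 0.1))
  ), class = "run_config")
}

validate_run_config <- function(config) {
  step <- config$mapper$step
  vw <- config$majority$vote_window
  if (!is.null(vw)) {
    expected <- vote_window_for_step(step, config$patching$patch_size %||% 278)
    if (as.integer(vw) != expected) {
      stopf("run config: vote_window %s does not match step %s (expected %d)",
            vw, step, expected)
    }
  }
  if (!config$classifier$type %in% c("cnn", "oracle")) {
    stopf("run config: classifier type must be 'cnn' or 'oracle'")
  }
  invisible(config)
}

# Merge user overrides (e.g. parsed JSON) over the default run config.
merge_run_config <- function(overrides, base = default_run_config()) {
  for (sec in names(overrides)) {
    if (is.list(overrides[[sec]]) && is.list(base[[sec]])) {
      for (k in names(overrides[[sec]])) base[[sec]][[k]] <- overrides[[sec]][[k]]
    } else {
      base[[sec]] <- overrides[[sec]]
    }
  }
  validate_run_config(base)
  base
}

run_log <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf(paste0("[duvmap] ", fmt), ...))
}

#' Run the full pipeline: synthesize, train, map, vote, report
#'
#' Executes every stage with deterministic per-stage seeds derived from
#' `config$seed` and writes all artifacts under `out_dir`: the evaluation
#' dataset (`data/`), per-image maps (`maps/`), overlays for the first
#' images (`overlays/`), `decisions.csv`, the threshold-sweep table
#' (`sweep.csv`) and a `report.json` summary. Re-running with the same
#' config and seed reproduces the decisions exactly.
#'
#' @param config a run configuration (see [default_run_config()]).
#' @param out_dir output directory.
#' @param quiet suppress progress messages.
#' @return list with `decisions` (data frame), `sweep`
#'   (an evaluation table), `classifier_summary`, and `paths`.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir,
                         quiet = FALSE) {
  config <- validate_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed

  scene_args <- config$scene
  scene_args$lesion_diameter_range <-
    as.numeric(unlist(scene_args$lesion_diameter_range))
  base_spec <- do.call(scene_spec, c(scene_args, list(seed = derive_seed(seed, 1))))

  dat <- config$data
  run_log(quiet, "stage synth: %d+%d eval images (%d x %d px)",
          dat$n_eval_positive, dat$n_eval_negative,
          base_spec$width, base_spec$height)
  eval_spec <- base_spec
  eval_spec$seed <- derive_seed(seed, 2)
  eval_images <- generate_dataset(dat$n_eval_positive, dat$n_eval_negative,
                                  min(dat$nodes_per_class, dat$n_eval_positive,
                                      dat$n_eval_negative),
                                  eval_spec)
  manifest <- write_dataset(eval_images, file.path(out_dir, "data"))

  classifier <- NULL
  classifier_summary <- list(type = config$classifier$type)
  if (config$classifier$type == "cnn") {
    run_log(quiet, "stage synth: %d+%d training images",
            dat$n_train_positive, dat$n_train_negative)
    train_images <- generate_dataset(dat$n_train_positive,
                                     dat$n_train_negative,
                                     dat$nodes_per_class, base_spec)
    patches <- extract_labeled_patches(
      train_images, patch_size = config$patching$patch_size,
      min_tumor_fraction = config$patching$min_tumor_fraction)
    run_log(quiet, "stage patchify: %d patches (%d positive, %d negative)",
            length(patches),
            sum(vapply(patches, `[[`, "", "label") == "positive"),
            sum(vapply(patches, `[[`, "", "label") == "negative"))
    # two-way split here: train + validation (test role is played by the
    # held-out eval images)
    split <- split_by_node(patches, fractions = c(0.7, 0.3, 0),
                           seed = derive_seed(seed, 3))
    tc <- train_config(
      phase1_epochs = config$training$phase1_epochs,
      phase2_epochs = config$training$phase2_epochs,
      learning_rate = config$training$learning_rate,
      dropout = config$training$dropout,
      seed = derive_seed(seed, 4))
    run_log(quiet, "stage train: %d train / %d validation patches",
            length(split$train), length(split$validation))
    classifier <- train_small_cnn(split$train, split$validation, tc)
    val_metrics <- evaluate_patches(classifier, split$validation)
    classifier_summary$best_val_loss <- classifier$best_val_loss
    classifier_summary$validation_accuracy <- val_metrics$accuracy
    run_log(quiet, "stage train: best val loss %.4f, val accuracy %.3f",
            classifier$best_val_loss, val_metrics$accuracy)
  }

  mcfg <- mapper_config(patch_size = config$patching$patch_size,
                        step = config$mapper$step,
                        decision_threshold = config$mapper$decision_threshold)
  vw <- config$majority$vote_window %||%
    vote_window_for_step(mcfg$step, mcfg$patch_size)
  vote_cfg <- majority_config(vote_window = vw,
                              threshold = config$majority$threshold)
  dir.create(file.path(out_dir, "maps"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "overlays"), showWarnings = FALSE)
  maps <- vector("list", length(eval_images))
  decisions <- vector("list", length(eval_images))
  for (i in seq_along(eval_images)) {
    img <- eval_images[[i]]
    clf <- classifier %||% noisy_oracle(
      img, noisy_oracle_config(fp_rate = config$classifier$fp_rate,
                               fn_rate = config$classifier$fn_rate,
                               seed = derive_seed(seed, 100 + i)),
      min_tumor_fraction = config$patching$min_tumor_fraction)
    m <- build_map(img, clf, mcfg)
    maps[[i]] <- m
    write_map(m, file.path(out_dir, "maps", sprintf("map_%03d.png", i)))
    filtered <- majority_vote(m, vote_cfg)
    dec <- decide_image(filtered)
    decisions[[i]] <- data.frame(
      image = sprintf("img_%03d.png", i), node_id = img$node_id,
      true_status = img$status, call = dec$image_call,
      positive_pixels = dec$positive_pixel_count,
      raw_positive_pixels = sum(m$grid))
    if (i <= 2) {
      ov <- render_overlay(img, filtered, step = m$step,
                           map_offset = (vw - 1) / 2)
      write_png(ov, file.path(out_dir, "overlays",
                              sprintf("overlay_%03d.png", i)))
    }
    run_log(quiet, "stage map+vote [%d/%d]: %s -> %s (%d positive px)",
            i, length(eval_images), img$status, dec$image_call,
            dec$positive_pixel_count)
  }
  decisions <- do.call(rbind, decisions)
  utils::write.csv(decisions, file.path(out_dir, "decisions.csv"),
                   row.names = FALSE)

  statuses <- vapply(eval_images, `[[`, "", "status")
  sweep <- threshold_sweep(maps, statuses,
                           thresholds = unlist(config$sweep$thresholds),
                           vote_window = vw)
  utils::write.csv(sweep, file.path(out_dir, "sweep.csv"), row.names = FALSE)

  report <- list(
    seed = seed, classifier = classifier_summary,
    step = mcfg$step, vote_window = vw,
    majority_threshold = config$majority$threshold,
    n_images = nrow(decisions),
    accuracy_by_class = list(
      positive = mean(decisions$call[decisions$true_status == "positive"] ==
                        "positive"),
      negative = mean(decisions$call[decisions$true_status == "negative"] ==
                        "negative"))
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(decisions = decisions, sweep = sweep,
                 classifier_summary = classifier_summary,
                 classifier = classifier,
                 paths = list(out_dir = out_dir)))
}
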