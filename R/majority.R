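# Majority-decision smoothing of prediction maps and per-image calls.
#
# A vote window slides over the binary map one map-pixel at a time
# (valid positions only, no padding); the output pixel is positive iff
# the fraction of positive input pixels in the window STRICTLY exceeds
# the threshold. The window size is tied to the mapping stride: a
# sufficiently small lesion spans about patch_size/step map pixels, so
# the defaults are 27 (step 10), 8 (step 35) and 4 (step 70), taken as a
# lookup table because simple rounding of 278/step does not reproduce
# all three. The output shrinks by (vote_window - 1) per axis, which at
# step 10 corresponds to roughly half the 278-px analysis window per
# side of the source frame -- the border the mirror padding was added to
# protect.

vote_window_table <- c("10" = 27L, "35" = 8L, "70" = 4L)

#' Default vote-window size for a mapping stride
#'
#' @param step mapping stride in pixels.
#' @param patch_size analysis-window edge in pixels.
#' @return the tabulated window size for steps 10/35/70, otherwise
#'   `round(patch_size / step)`.
#' @export
vote_window_for_step <- function(step, patch_size = 278L) {
  key <- as.character(step)
  if (key %in% names(vote_window_table)) return(vote_window_table[[key]])
  max(1L, as.integer(round(patch_size / step)))
}

#' Majority-vote configuration
#'
#' @param vote_window square window edge in map pixels.
#' @param threshold positive-fraction threshold in (0, 1); the comparison
#'   is strictly greater.
#' @param step convenience: when `vote_window` is missing it is looked up
#'   from the stride with [vote_window_for_step()].
#' @return a `majority_config`.
#' @export
majority_config <- function(vote_window = NULL, threshold = 0.7,
                            step = 10L) {
  if (is.null(vote_window)) vote_window <- vote_window_for_step(step)
  vote_window <- as.integer(vote_window)
  if (vote_window < 1L) stopf("majority_config: vote_window must be >= 1")
  if (threshold <= 0 || threshold >= 1) {
    stopf("majority_config: threshold must be in (0, 1)")
  }
  structure(list(vote_window = vote_window, threshold = threshold),
            class = "majority_config")
}

#' Apply the majority vote to a prediction map
#'
#' @param map a [prediction_map()] or a plain binary matrix.
#' @param config a [majority_config()].
#' @return binary matrix of size
#'   `(n_rows - vote_window + 1) x (n_cols - vote_window + 1)`; output
#'   index `(i, j)` corresponds to the vote window whose top-left input
#'   pixel is `(i, j)`.
#' @export
majority_vote <- function(map, config = majority_config()) {
  grid <- if (inherits(map, "prediction_map")) map$grid else map
  vw <- config$vote_window
  if (nrow(grid) < vw || ncol(grid) < vw) {
    stopf("majority_vote: map %d x %d smaller than vote window %d",
          nrow(grid), ncol(grid), vw)
  }
  rows0 <- 0:(nrow(grid) - vw)
  cols0 <- 0:(ncol(grid) - vw)
  counts <- box_sums(grid > 0, vw, rows0, cols0)
  (counts / vw^2 > config$threshold) * 1L
}

#' Final per-image diagnosis from a filtered map
#'
#' An image is called metastasis-positive iff at least one pixel of the
#' (filtered) map is positive.
#'
#' @param filtered binary matrix (or [prediction_map()]).
#' @return list with `image_call` (`"positive"`/`"negative"`),
#'   `positive_pixel_count`, and the raster as `filtered_map`.
#' @export
decide_image <- function(filtered) {
  grid <- if (inherits(filtered, "prediction_map")) filtered$grid else filtered
  n_pos <- sum(grid > 0)
  list(filtered_map = grid,
       image_call = if (n_pos >= 1) "positive" else "negative",
       positive_pixel_count = as.integer(n_pos))
}

#' Threshold sweep over a set of prediction maps
#'
#' Reproduces the layout of the per-threshold true-prediction-rate table:
#' one row per vote threshold plus a "no filter" row where the raw map
#' decides directly, with the fraction of positive images called
#' positive and of negative images called negative.
#'
#' @param maps list of [prediction_map()] objects.
#' @param statuses character vector of true image classes
#'   (`"positive"`/`"negative"`), parallel to `maps`.
#' @param thresholds vote thresholds to evaluate.
#' @param vote_window window size in map pixels (default from the first
#'   map's stride).
#' @return data frame with columns `threshold` (`NA` for the no-filter
#'   row), `positive_rate`, `negative_rate`, `n_positive`, `n_negative`,
#'   `true_positive_calls`, `true_negative_calls`.
#' @export
threshold_sweep <- function(maps, statuses,
                            thresholds = seq(0.4, 0.9, by = 0.1),
                            vote_window = NULL) {
  stopifnot(length(maps) == length(statuses))
  if (length(maps) == 0) stopf("threshold_sweep: empty input")
  is_pos <- statuses == "positive"
  if (!any(is_pos) || !any(!is_pos)) {
    stopf("threshold_sweep: need at least one map per class")
  }
  if (is.null(vote_window)) {
    vote_window <- vote_window_for_step(maps[[1]]$step,
                                        maps[[1]]$patch_size)
  }
  call_of <- function(grid) decide_image(grid)$image_call
  raw_calls <- vapply(maps, function(m) call_of(m$grid), "")
  row_for <- function(thr, calls) {
    data.frame(
      threshold = thr,
      positive_rate = mean(calls[is_pos] == "positive"),
      negative_rate = mean(calls[!is_pos] == "negative"),
      n_positive = sum(is_pos), n_negative = sum(!is_pos),
      true_positive_calls = sum(calls[is_pos] == "positive"),
      true_negative_calls = sum(calls[!is_pos] == "negative")
    )
  }
  rows <- list(row_for(NA_real_, raw_calls))
  for (thr in thresholds) {
    cfg <- majority_config(vote_window = vote_window, threshold = thr)
    calls <- vapply(maps, function(m) call_of(majority_vote(m, cfg)), "")
    rows[[length(rows) + 1L]] <- row_for(thr, calls)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("evaluation_table", "data.frame")
  out
}
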