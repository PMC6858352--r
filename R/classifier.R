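# The pluggable patch-classifier contract and its test instruments.
#
# A patch classifier is any object with a `predict_proba()` method that
# maps a normalized 278 x 278 x 3 patch to the probability of the
# metastasis-positive class, always in [0, 1] and deterministic given the
# trained state. Two implementations ship with the package: a trainable
# small CNN (see cnn.R) and the seeded noisy oracle below, which knows
# the ground truth of one image and flips it with configured false
# positive / false negative rates -- the instrument used to study how
# per-window error rates propagate through dense mapping and voting.

#' Predict the metastasis-positive probability of one patch
#'
#' @param classifier a patch classifier object.
#' @param patch normalized H x W x 3 array in `[0, 1]`.
#' @param ... implementation-specific extras (e.g. window position for
#'   position-aware oracles).
#' @return a probability in `[0, 1]`.
#' @export
predict_proba <- function(classifier, patch, ...) {
  UseMethod("predict_proba")
}

#' Constant-output classifier (testing aid)
#'
#' @param p the probability emitted for every patch.
#' @return a patch classifier.
#' @export
constant_classifier <- function(p) {
  stopifnot(p >= 0, p <= 1)
  structure(list(p = p), class = c("constant_classifier", "patch_classifier"))
}

#' @export
predict_proba.constant_classifier <- function(classifier, patch, ...) {
  classifier$p
}

#' Wrap a plain function as a patch classifier
#'
#' @param f function taking a normalized patch array and returning a
#'   probability in `[0, 1]`.
#' @return a patch classifier.
#' @export
function_classifier <- function(f) {
  stopifnot(is.function(f))
  structure(list(f = f), class = c("function_classifier", "patch_classifier"))
}

#' @export
predict_proba.function_classifier <- function(classifier, patch, ...) {
  classifier$f(patch)
}

#' Noisy-oracle classifier configuration
#'
#' @param fp_rate probability that a truly negative window is called
#'   positive.
#' @param fn_rate probability that a truly positive window is called
#'   negative.
#' @param seed RNG seed; the flip decisions are deterministic given the
#'   seed and the window's grid position.
#' @return a `noisy_oracle_config`.
#' @export
noisy_oracle_config <- function(fp_rate = 0, fn_rate = 0, seed = 1L) {
  stopifnot(fp_rate >= 0, fp_rate <= 1, fn_rate >= 0, fn_rate <= 1)
  structure(list(fp_rate = fp_rate, fn_rate = fn_rate,
                 seed = as.integer(seed)),
            class = "noisy_oracle_config")
}

#' Noisy-oracle patch classifier for one image
#'
#' Emits the window's ground-truth label (computed from the image's mask
#' with the same rule as [label_patch()]) flipped with the configured
#' error rates. Flip decisions are drawn from a single seeded uniform
#' stream laid out over the prediction grid in row-major order, so a
#' given (seed, grid geometry, window position) always produces the same
#' call, and per-image error counts are exactly Binomial(n_windows, rate).
#'
#' @param image a [labeled_image()] (must carry a mask).
#' @param config a [noisy_oracle_config()].
#' @param min_tumor_fraction ground-truth rule threshold (see
#'   [label_patch()]).
#' @return a patch classifier; it additionally implements the fast
#'   whole-grid path used by [build_map()].
#' @export
noisy_oracle <- function(image, config = noisy_oracle_config(),
                         min_tumor_fraction = 0) {
  stopifnot(inherits(config, "noisy_oracle_config"), !is.null(image$mask))
  structure(list(mask = image$mask, fp_rate = config$fp_rate,
                 fn_rate = config$fn_rate, seed = config$seed,
                 min_tumor_fraction = min_tumor_fraction),
            class = c("noisy_oracle", "patch_classifier"))
}

# Uniform deviates for every grid cell, row-major, fixed by seed.
oracle_uniforms <- function(classifier, n_rows, n_cols) {
  with_seed(classifier$seed,
            matrix(stats::runif(n_rows * n_cols), n_rows, n_cols,
                   byrow = TRUE))
}

#' @describeIn noisy_oracle per-window prediction; `grid_pos` is the
#'   0-based `(row, col)` of the window in the prediction grid and
#'   `grid_dim` its `(n_rows, n_cols)`; `truth` is the window's
#'   ground-truth label (0/1), normally supplied by the mapper.
#' @param classifier,patch,grid_pos,grid_dim,truth,... see description.
#' @export
predict_proba.noisy_oracle <- function(classifier, patch, grid_pos, grid_dim,
                                       truth, ...) {
  u <- oracle_uniforms(classifier, grid_dim[1], grid_dim[2])
  ui <- u[grid_pos[1] + 1L, grid_pos[2] + 1L]
  if (truth == 1L) {
    if (ui < classifier$fn_rate) 0 else 1
  } else {
    if (ui < classifier$fp_rate) 1 else 0
  }
}

#' Evaluate a classifier on labeled patches
#'
#' Probabilities are binarized at 0.5 with ties going to the positive
#' class ("rounding off" is ambiguous at exactly 0.5; the tie rule is
#' fixed here and documented). The ROC curve is computed by sweeping a
#' threshold over the emitted probabilities; AUC is the Mann-Whitney
#' statistic. With a single-class test set the AUC is reported as `NA`
#' rather than a number.
#'
#' @param classifier a patch classifier.
#' @param patches labeled, *normalized-on-demand* patch records (raw
#'   pixel tiles are normalized with [normalize_patch()] before
#'   prediction).
#' @return list with `accuracy`, `confusion` (tp/fp/tn/fn), `roc`
#'   (data frame of threshold/tpr/fpr), `auc`, `n`.
#' @export
evaluate_patches <- function(classifier, patches) {
  patches <- Filter(function(p) p$label %in% c("positive", "negative"),
                    patches)
  if (length(patches) == 0) stopf("evaluate_patches: no labeled patches")
  truth <- vapply(patches, `[[`, "", "label") == "positive"
  probs <- vapply(patches, function(p) {
    predict_proba(classifier, normalize_patch(p$pixels))
  }, numeric(1))
  if (any(probs < 0 | probs > 1)) {
    stopf("evaluate_patches: classifier emitted a probability outside [0,1]")
  }
  pred <- probs >= 0.5
  tp <- sum(pred & truth); fp <- sum(pred & !truth)
  tn <- sum(!pred & !truth); fn <- sum(!pred & truth)
  n <- length(truth)
  acc <- (tp + tn) / n
  if (any(truth) && any(!truth)) {
    thr <- sort(unique(c(0, probs, 1)), decreasing = TRUE)
    roc <- data.frame(
      threshold = thr,
      tpr = vapply(thr, function(t) sum(probs >= t & truth) / sum(truth),
                   numeric(1)),
      fpr = vapply(thr, function(t) sum(probs >= t & !truth) / sum(!truth),
                   numeric(1))
    )
    r <- rank(probs, ties.method = "average")
    n1 <- sum(truth); n0 <- sum(!truth)
    auc <- (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  } else {
    roc <- NULL
    auc <- NA_real_
  }
  list(accuracy = acc,
       confusion = c(tp = tp, fp = fp, tn = tn, fn = fn),
       roc = roc, auc = auc, n = n)
}
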