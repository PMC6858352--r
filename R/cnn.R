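# Desk-scale trainable patch classifier.
#
# Architecture: fixed block-mean downsampling stem, two 3x3 convolution
# blocks (ReLU + 2x2 max-pool), global average pooling, dropout, and a
# 2-node softmax head -- the GAP-plus-2-node-head shape of the reference
# training protocol, at a width that trains in minutes on one CPU.
# Training follows the two-phase transfer-learning schedule: the head is
# fitted first with the feature extractor frozen, then all weights are
# trained jointly; plain SGD with momentum throughout, and the returned
# state is the checkpoint with the minimum validation loss over every
# epoch of both phases.
#
# Everything is implemented with im2col + matrix products in base R; no
# deep-learning runtime is required.

#' Training configuration for the small CNN
#'
#' @param phase1_epochs epochs with only the dense head trainable.
#' @param phase2_epochs epochs with all weights trainable.
#' @param learning_rate SGD learning rate (scalar, or length 2 for the
#'   two phases).
#' @param momentum SGD momentum coefficient.
#' @param dropout dropout rate on the pooled features (default 0.5).
#' @param batch_size minibatch size.
#' @param filters widths of the two convolution blocks.
#' @param downsample integer block-mean downsampling factor applied to
#'   the input patch before the first convolution.
#' @param seed RNG seed for weight init, shuffling and dropout.
#' @return a `train_config`.
#' @export
train_config <- function(phase1_epochs = 10L, phase2_epochs = 40L,
                         learning_rate = c(0.1, 0.05), momentum = 0.9,
                         dropout = 0.5, batch_size = 4L,
                         filters = c(8L, 16L), downsample = 4L,
                         seed = 1L) {
  stopifnot(phase1_epochs >= 1, phase2_epochs >= 0,
            dropout >= 0, dropout < 1, all(learning_rate > 0))
  structure(list(phase1_epochs = as.integer(phase1_epochs),
                 phase2_epochs = as.integer(phase2_epochs),
                 learning_rate = rep_len(learning_rate, 2L),
                 momentum = momentum, dropout = dropout,
                 batch_size = as.integer(batch_size),
                 filters = as.integer(filters),
                 downsample = as.integer(downsample),
                 optimizer = "sgd",
                 checkpoint_policy = "min_validation_loss",
                 seed = as.integer(seed)),
            class = "train_config")
}

# Block-mean downsampling with a centered crop to a multiple of `ds`.
downsample_block_mean <- function(x, ds) {
  if (ds <= 1L) return(x)
  d <- dim(x)
  ho <- d[1] %/% ds; wo <- d[2] %/% ds
  y0 <- (d[1] - ho * ds) %/% 2L
  x0 <- (d[2] - wo * ds) %/% 2L
  x <- x[(y0 + 1L):(y0 + ho * ds), (x0 + 1L):(x0 + wo * ds), , drop = FALSE]
  out <- array(0, dim = c(ho, wo, d[3]))
  for (c in seq_len(d[3])) {
    m <- x[, , c]
    # average rows in blocks, then columns
    m <- matrix(colMeans(matrix(m, nrow = ds)), nrow = ho)
    m <- t(matrix(colMeans(matrix(t(m), nrow = ds)), nrow = wo))
    out[, , c] <- m
  }
  out
}

# Index matrix for 3x3 valid im2col on an H x W x C input (column-major
# linear indices); output rows are the (H-2)(W-2) positions, columns the
# 9C taps ordered (dy, dx, channel).
im2col_index <- function(h, w, ch, k = 3L) {
  ho <- h - k + 1L; wo <- w - k + 1L
  pos_y <- rep.int(seq_len(ho), wo)
  pos_x <- rep(seq_len(wo), each = ho)
  base <- (pos_x - 1L) * h + pos_y          # linear index of window top-left
  taps <- integer(0)
  for (c in 0:(ch - 1L)) {
    for (dx in 0:(k - 1L)) {
      for (dy in 0:(k - 1L)) {
        taps <- c(taps, c * h * w + dx * h + dy)
      }
    }
  }
  outer(base, taps, `+`)                    # npos x (k*k*ch)
}

# 2x2 max-pool spatial index: rows are output positions, 4 columns the
# contributing input positions (column-major linear spatial indices).
pool_index <- function(h, w) {
  ho <- h %/% 2L; wo <- w %/% 2L
  py <- rep.int(seq_len(ho), wo); px <- rep(seq_len(wo), each = ho)
  tl <- (2L * (px - 1L)) * h + (2L * (py - 1L) + 1L)
  cbind(tl, tl + 1L, tl + h, tl + h + 1L)
}

maxpool_forward <- function(A, idx4) {
  n <- nrow(idx4); f <- ncol(A)
  out <- A[idx4[, 1], , drop = FALSE]
  arg <- matrix(1L, n, f)
  for (k in 2:4) {
    cand <- A[idx4[, k], , drop = FALSE]
    upd <- cand > out
    out[upd] <- cand[upd]
    arg[upd] <- k
  }
  list(out = out, arg = arg)
}

maxpool_backward <- function(dOut, arg, idx4, n_in) {
  f <- ncol(dOut)
  dA <- matrix(0, n_in, f)
  for (j in seq_len(f)) {
    tgt <- idx4[cbind(seq_len(nrow(idx4)), arg[, j])]
    dA[tgt, j] <- dOut[, j]
  }
  dA
}

col2im_backward <- function(dM, idx, n_in) {
  acc <- rowsum(as.vector(dM), group = as.vector(idx))
  dx <- numeric(n_in)
  dx[as.integer(rownames(acc))] <- acc[, 1]
  dx
}

cnn_geometry <- function(h, w, ch, filters) {
  h1 <- h - 2L; w1 <- w - 2L                 # conv1 (valid)
  hp1 <- h1 %/% 2L; wp1 <- w1 %/% 2L        # pool1
  h2 <- hp1 - 2L; w2 <- wp1 - 2L            # conv2
  hp2 <- h2 %/% 2L; wp2 <- w2 %/% 2L        # pool2
  if (h2 < 1L || w2 < 1L || hp2 < 1L || wp2 < 1L) {
    stopf("small_cnn: input %d x %d too small after downsampling", h, w)
  }
  list(h = h, w = w, ch = ch,
       idx1 = im2col_index(h, w, ch),
       p1 = pool_index(h1, w1), d1 = c(h1, w1),
       idx2 = im2col_index(hp1, wp1, filters[1]), dp1 = c(hp1, wp1),
       p2 = pool_index(h2, w2), d2 = c(h2, w2),
       dp2 = c(hp2, wp2))
}

cnn_init_params <- function(ch, filters, seed) {
  with_seed(seed, {
    f1 <- filters[1]; f2 <- filters[2]
    list(
      K1 = matrix(stats::rnorm(9 * ch * f1, 0, sqrt(2 / (9 * ch))), 9 * ch, f1),
      b1 = numeric(f1),
      K2 = matrix(stats::rnorm(9 * f1 * f2, 0, sqrt(2 / (9 * f1))), 9 * f1, f2),
      b2 = numeric(f2),
      W = matrix(stats::rnorm(2 * f2, 0, sqrt(2 / f2)), 2, f2),
      b = numeric(2)
    )
  })
}

# Forward pass of one preprocessed input (h*w*ch vector). Returns the
# softmax probabilities and, when `keep = TRUE`, every intermediate
# needed for backprop. `drop_mask` applies inverted dropout to the
# pooled features.
cnn_forward <- function(params, geom, xv, keep = FALSE, drop_mask = NULL) {
  M1 <- matrix(xv[geom$idx1], nrow = nrow(geom$idx1))
  Z1 <- sweep(M1 %*% params$K1, 2, params$b1, `+`)
  A1 <- pmax(Z1, 0)
  mp1 <- maxpool_forward(A1, geom$p1)
  xv2 <- as.vector(mp1$out)                  # (hp1*wp1) x f1, column-major
  M2 <- matrix(xv2[geom$idx2], nrow = nrow(geom$idx2))
  Z2 <- sweep(M2 %*% params$K2, 2, params$b2, `+`)
  A2 <- pmax(Z2, 0)
  mp2 <- maxpool_forward(A2, geom$p2)
  g <- colMeans(mp2$out)
  if (!is.null(drop_mask)) g <- g * drop_mask
  z <- as.vector(params$W %*% g + params$b)
  z <- z - max(z)
  p <- exp(z) / sum(exp(z))
  if (!keep) return(p)
  list(p = p, g = g, M1 = M1, Z1 = Z1, mp1 = mp1, M2 = M2, Z2 = Z2,
       mp2 = mp2, drop_mask = drop_mask)
}

# Gradients of the cross-entropy loss for one sample; `y` is 0 (negative)
# or 1 (positive; class order is c(negative, positive)).
cnn_backward <- function(params, geom, fw, y, head_only = FALSE) {
  target <- c(1 - y, y)
  dz <- fw$p - target
  dW <- dz %o% fw$g
  db <- dz
  if (head_only) return(list(W = dW, b = db))
  dg <- as.vector(t(params$W) %*% dz)
  if (!is.null(fw$drop_mask)) dg <- dg * fw$drop_mask
  n2 <- nrow(fw$mp2$out)
  dPool2 <- matrix(rep(dg / n2, each = n2), n2)
  dA2 <- maxpool_backward(dPool2, fw$mp2$arg, geom$p2, nrow(fw$Z2))
  dZ2 <- dA2 * (fw$Z2 > 0)
  dK2 <- crossprod(fw$M2, dZ2)
  db2 <- colSums(dZ2)
  dM2 <- dZ2 %*% t(params$K2)
  n_in2 <- prod(geom$dp1) * ncol(fw$mp1$out)
  dxv2 <- col2im_backward(dM2, geom$idx2, n_in2)
  dPool1 <- matrix(dxv2, ncol = ncol(fw$mp1$out))
  dA1 <- maxpool_backward(dPool1, fw$mp1$arg, geom$p1, nrow(fw$Z1))
  dZ1 <- dA1 * (fw$Z1 > 0)
  dK1 <- crossprod(fw$M1, dZ1)
  db1 <- colSums(dZ1)
  list(W = dW, b = db, K2 = dK2, b2 = db2, K1 = dK1, b1 = db1)
}

# Normalized patches live in [0, 1] with a dark-background mean, so all
# inputs are positive and gradients through the first convolution are
# strongly correlated; centering at 0.5 removes that and is required for
# SGD to make progress at practical learning rates.
cnn_preprocess <- function(pixels, ds) {
  as.vector(downsample_block_mean(normalize_patch(pixels), ds)) - 0.5
}

cnn_loss <- function(params, geom, inputs, labels) {
  eps <- 1e-12
  l <- vapply(seq_along(inputs), function(i) {
    p <- cnn_forward(params, geom, inputs[[i]])
    -log(p[labels[i] + 1L] + eps)
  }, numeric(1))
  mean(l)
}

#' Train the small CNN patch classifier
#'
#' @param train,validation lists of labeled patch records (fields
#'   `pixels` and `label` in `"positive"`/`"negative"`). Both must be
#'   non-empty and the training set must contain both classes.
#' @param config a [train_config()].
#' @return a `small_cnn` patch classifier holding the
#'   minimum-validation-loss checkpoint and a per-epoch `history`
#'   data frame.
#' @export
train_small_cnn <- function(train, validation, config = train_config()) {
  keep <- function(ps) Filter(function(p) p$label %in% c("positive", "negative"), ps)
  train <- keep(train); validation <- keep(validation)
  if (length(train) == 0 || length(validation) == 0) {
    stopf("train_small_cnn: empty training or validation set")
  }
  ytr <- as.integer(vapply(train, `[[`, "", "label") == "positive")
  yva <- as.integer(vapply(validation, `[[`, "", "label") == "positive")
  if (length(unique(ytr)) < 2) {
    stopf("train_small_cnn: training set must contain both classes")
  }
  ds <- config$downsample
  xtr <- lapply(train, function(p) cnn_preprocess(p$pixels, ds))
  xva <- lapply(validation, function(p) cnn_preprocess(p$pixels, ds))
  d0 <- dim(downsample_block_mean(normalize_patch(train[[1]]$pixels), ds))
  geom <- cnn_geometry(d0[1], d0[2], d0[3], config$filters)
  params <- cnn_init_params(d0[3], config$filters, config$seed)
  vel <- lapply(params, function(p) p * 0)
  n <- length(xtr)
  best <- list(loss = Inf, params = params, phase = 0L, epoch = 0L)
  history <- list()
  keep_prob <- 1 - config$dropout

  with_seed(derive_seed(config$seed, 7L), {
    epoch_counter <- 0L
    for (phase in 1:2) {
      n_epochs <- if (phase == 1L) config$phase1_epochs else config$phase2_epochs
      lr <- config$learning_rate[phase]
      head_only <- phase == 1L
      for (ep in seq_len(n_epochs)) {
        ord <- sample.int(n)
        tr_loss <- 0
        for (start in seq(1, n, by = config$batch_size)) {
          batch <- ord[start:min(start + config$batch_size - 1L, n)]
          grads <- NULL
          for (i in batch) {
            dm <- if (config$dropout > 0) {
              (stats::runif(config$filters[2]) < keep_prob) / keep_prob
            } else NULL
            fw <- cnn_forward(params, geom, xtr[[i]], keep = TRUE,
                              drop_mask = dm)
            tr_loss <- tr_loss - log(fw$p[ytr[i] + 1L] + 1e-12)
            g <- cnn_backward(params, geom, fw, ytr[i],
                              head_only = head_only)
            grads <- if (is.null(grads)) g else
              Map(`+`, grads, g)
          }
          for (nm in names(grads)) {
            vel[[nm]] <- config$momentum * vel[[nm]] -
              lr * grads[[nm]] / length(batch)
            params[[nm]] <- params[[nm]] + vel[[nm]]
          }
        }
        val_loss <- cnn_loss(params, geom, xva, yva)
        epoch_counter <- epoch_counter + 1L
        history[[epoch_counter]] <- data.frame(
          phase = phase, epoch = ep, train_loss = tr_loss / n,
          val_loss = val_loss)
        if (val_loss < best$loss) {
          best <- list(loss = val_loss, params = params,
                       phase = phase, epoch = ep)
        }
      }
    }
  })

  structure(list(params = best$params, geom = geom, config = config,
                 input_dim = d0, best_val_loss = best$loss,
                 best_epoch = c(phase = best$phase, epoch = best$epoch),
                 history = do.call(rbind, history)),
            class = c("small_cnn", "patch_classifier"))
}

#' @export
predict_proba.small_cnn <- function(classifier, patch, ...) {
  x <- downsample_block_mean(patch, classifier$config$downsample) - 0.5
  d <- dim(x)
  if (!all(d == classifier$input_dim)) {
    stopf("small_cnn: patch geometry %dx%d does not match training geometry",
          d[2], d[1])
  }
  p <- cnn_forward(classifier$params, classifier$geom, as.vector(x))
  p[2]
}
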