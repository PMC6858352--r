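test_that("noisy oracle with zero rates reproduces ground-truth window labels", {
  img <- generate_image(small_scene(seed = 17L))
  cfg <- mapper_config(step = 70)
  oracle <- noisy_oracle(img, noisy_oracle_config(0, 0, seed = 1))
  m <- build_map(img, oracle, cfg)
  gt <- ground_truth_map(img, cfg)
  expect_identical(m$grid, gt$grid)

  # fp_rate = 1 on an all-negative image: every map pixel positive
  neg <- generate_image(small_scene(seed = 18L, n_lesions = 0L))
  all_pos <- build_map(neg, noisy_oracle(neg, noisy_oracle_config(1, 0, 1)),
                       cfg)
  expect_true(all(all_pos$grid == 1))
})

test_that("oracle flips are deterministic per seed and window position", {
  img <- generate_image(small_scene(seed = 19L, n_lesions = 0L))
  cfg <- mapper_config(step = 70)
  oc <- noisy_oracle(img, noisy_oracle_config(fp_rate = 0.3, seed = 5))
  m1 <- build_map(img, oc, cfg)
  m2 <- build_map(img, oc, cfg)
  expect_identical(m1$grid, m2$grid)
  # slow per-window path agrees with the vectorized grid path
  m3 <- build_map(img, oc, cfg, use_fast_path = FALSE)
  expect_identical(m1$grid, m3$grid)
  # a different seed changes the flips
  oc2 <- noisy_oracle(img, noisy_oracle_config(fp_rate = 0.3, seed = 6))
  expect_false(identical(build_map(img, oc2, cfg)$grid, m1$grid))
})

test_that("oracle error counts are Binomial(n_windows, rate)", {
  # all-negative frame, 30 seeds: empirical mean FP count within 3 SE
  img <- blank_image(300, 320)
  cfg <- mapper_config(step = 35)
  nd <- dim(ground_truth_map(img, cfg)$grid)
  n_windows <- prod(nd)
  rate <- 0.05
  counts <- vapply(1:30, function(s) {
    oc <- noisy_oracle(img, noisy_oracle_config(fp_rate = rate, seed = s))
    sum(build_map(img, oc, cfg)$grid)
  }, numeric(1))
  expected <- n_windows * rate
  se <- sqrt(n_windows * rate * (1 - rate) / 30)
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("evaluate_patches computes accuracy, confusion, ROC and AUC", {
  patches <- make_toy_patches(12, seed = 3)
  # perfect classifier keyed on mean green intensity
  perfect <- function_classifier(function(p) as.numeric(mean(p[, , 2]) > 0.6))
  ev <- evaluate_patches(perfect, patches)
  expect_equal(ev$accuracy, 1.0)
  expect_equal(ev$auc, 1.0)
  expect_equal(unname(ev$confusion[c("tp", "tn")]), c(12, 12))

  # constant 0.5 on a balanced set: ties go positive -> accuracy 0.5
  ev2 <- evaluate_patches(constant_classifier(0.5), patches)
  expect_equal(ev2$accuracy, 0.5)
  expect_equal(unname(ev2$confusion["fn"]), 0)

  # confusion counts are order-invariant
  ev3 <- evaluate_patches(perfect, rev(patches))
  expect_equal(ev3$confusion, ev$confusion)

  # single-class input: AUC reported absent, not 0
  pos_only <- Filter(function(p) p$label == "positive", patches)
  ev4 <- evaluate_patches(constant_classifier(1), pos_only)
  expect_true(is.na(ev4$auc))
  expect_equal(ev4$accuracy, 1.0)

  # out-of-range probabilities are rejected
  bad <- function_classifier(function(p) 1.2)
  expect_error(evaluate_patches(bad, patches), "outside")
})

test_that("error-rate arithmetic: 47 errors in 3,830 patches is 98.8%", {
  # construct a labeled set with exactly 28 false positives and 19 false
  # negatives out of 1,843 + 1,987 = 3,830 patches and check the accuracy
  # arithmetic end to end
  n_pos <- 1843L; n_neg <- 1987L
  mk <- function(label, n) {
    lapply(seq_len(n), function(i) list(
      pixels = array(if (label == "positive") 200L else 40L, dim = c(2, 2, 3)),
      label = label, node_id = "x", source_status = label,
      tumor_fraction = 0))
  }
  patches <- c(mk("positive", n_pos), mk("negative", n_neg))
  flip_fn <- seq_len(19)                 # positives called negative
  flip_fp <- n_pos + seq_len(28)         # negatives called positive
  i <- 0L
  counter <- function(p) {
    i <<- i + 1L
    truth_pos <- i <= n_pos
    if (i %in% flip_fn) 0 else if (i %in% flip_fp) 1
    else as.numeric(truth_pos)
  }
  ev <- evaluate_patches(function_classifier(counter), patches)
  expect_equal(unname(ev$confusion["fp"]), 28)
  expect_equal(unname(ev$confusion["fn"]), 19)
  expect_equal(ev$accuracy, (3830 - 47) / 3830)
  expect_equal(round(ev$accuracy, 3), 0.988)
})
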