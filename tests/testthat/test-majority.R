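test_that("vote-window lookup table and fallback", {
  expect_equal(vote_window_for_step(10), 27L)
  expect_equal(vote_window_for_step(35), 8L)
  expect_equal(vote_window_for_step(70), 4L)
  # generic fallback for other strides: round(patch/step)
  expect_equal(vote_window_for_step(20), 14L)
  expect_equal(vote_window_for_step(139), 2L)
})

test_that("an isolated positive pixel is eliminated at every standard threshold", {
  grid <- matrix(0L, 40, 40)
  grid[20, 20] <- 1L
  for (thr in seq(0.4, 0.9, by = 0.1)) {
    out <- majority_vote(grid, majority_config(vote_window = 27,
                                               threshold = thr))
    expect_true(all(out == 0))
  }
  # 1/729 is also below any threshold above 0.00138
  expect_true(all(majority_vote(grid, majority_config(27, 0.002)) == 0))
})

test_that("strict-greater comparison at an exact fraction boundary", {
  # one 27 x 27 map with exactly 300 positives: 300/729 = 0.41152...
  grid <- matrix(0L, 27, 27)
  grid[seq_len(300)] <- 1L
  expect_equal(majority_vote(grid, majority_config(27, 0.40)),
               matrix(1L, 1, 1))
  expect_equal(majority_vote(grid, majority_config(27, 0.50)),
               matrix(0L, 1, 1))
  # exact boundary: fraction == threshold emits 0 (strictly greater)
  expect_equal(majority_vote(grid, majority_config(27, 300 / 729)),
               matrix(0L, 1, 1))
})

test_that("all-ones and all-zeros maps are fixed points; output shrinks", {
  ones <- matrix(1L, 30, 25)
  for (thr in c(0.4, 0.9)) {
    out <- majority_vote(ones, majority_config(8, thr))
    expect_equal(dim(out), c(23, 18))
    expect_true(all(out == 1))
  }
  zeros <- matrix(0L, 30, 25)
  expect_true(all(majority_vote(zeros, majority_config(8, 0.4)) == 0))
  expect_error(majority_vote(matrix(0L, 3, 3), majority_config(4, 0.5)),
               "smaller")
})

test_that("box-sum vote equals the brute-force counting oracle", {
  set.seed(99)
  cases <- list(c(30, 30, 4), c(57, 43, 8), c(200, 200, 27))
  for (cs in cases) {
    grid <- matrix(rbinom(cs[1] * cs[2], 1, 0.35), cs[1], cs[2])
    for (thr in seq(0.4, 0.9, by = 0.1)) {
      cfg <- majority_config(vote_window = cs[3], threshold = thr)
      expect_identical(majority_vote(grid, cfg),
                       brute_majority(grid, cs[3], thr))
    }
  }
})

test_that("threshold monotonicity: higher thresholds keep a subset of pixels", {
  set.seed(7)
  for (rep in 1:5) {
    grid <- matrix(rbinom(50 * 60, 1, runif(1, 0.2, 0.7)), 50, 60)
    prev <- NULL
    for (thr in seq(0.4, 0.9, by = 0.1)) {
      out <- majority_vote(grid, majority_config(8, thr))
      if (!is.null(prev)) expect_true(all(out <= prev))
      prev <- out
    }
  }
})

test_that("a solid square at least the window size survives any threshold", {
  for (vw in c(4L, 8L)) {
    grid <- matrix(0L, 40, 40)
    grid[10:(10 + vw + 2), 12:(12 + vw + 2)] <- 1L  # side vw + 3
    out <- majority_vote(grid, majority_config(vw, 0.95))
    expect_gte(sum(out), 1)
  }
})

test_that("decide_image implements the any-positive-pixel rule", {
  expect_equal(decide_image(matrix(0L, 5, 5))$image_call, "negative")
  one <- matrix(0L, 5, 5); one[3, 3] <- 1L
  d <- decide_image(one)
  expect_equal(d$image_call, "positive")
  expect_equal(d$positive_pixel_count, 1L)
  expect_equal(decide_image(matrix(1L, 4, 4))$positive_pixel_count, 16L)
})

test_that("threshold_sweep reports per-class true prediction rates", {
  # perfect-oracle maps: lesions much wider than the vote window
  imgs <- c(
    lapply(1:2, function(s) generate_image(
      scene_spec(width = 480, height = 440, n_lesions = 1,
                 lesion_diameter_range = c(170, 200),
                 n_histiocyte_nodules = 0, seed = s))),
    lapply(3:4, function(s) generate_image(
      scene_spec(width = 480, height = 440, n_lesions = 0,
                 n_histiocyte_nodules = 1, seed = s))))
  cfg <- mapper_config(step = 70)
  maps <- lapply(imgs, function(im) build_map(im, noisy_oracle(im), cfg))
  statuses <- vapply(imgs, `[[`, "", "status")
  tab <- threshold_sweep(maps, statuses, thresholds = c(0.4, 0.7))
  expect_s3_class(tab, "evaluation_table")
  expect_equal(nrow(tab), 3)          # no-filter row + 2 thresholds
  expect_true(is.na(tab$threshold[1]))
  expect_equal(tab$positive_rate, rep(1, 3))
  expect_equal(tab$negative_rate, rep(1, 3))
  expect_equal(tab$n_positive[1], 2)
  expect_error(threshold_sweep(maps, rep("positive", 4)), "per class")
  expect_error(threshold_sweep(list(), character(0)), "empty")
})
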