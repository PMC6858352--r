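make_flat_image <- function(h, w, value = 120L, mask = NULL,
                            node = "n1") {
  rgb <- array(as.integer(value), dim = c(h, w, 3))
  if (is.null(mask)) mask <- matrix(0L, h, w)
  labeled_image(rgb, mask, node_id = node)
}

test_that("tiling yields floor(W/278) x floor(H/278) patches, origin top-left", {
  img <- make_flat_image(2048, 2592)
  patches <- divide_into_patches(img)
  expect_length(patches, 63)  # 9 x 7
  rows <- vapply(patches, `[[`, 0, "grid_row")
  cols <- vapply(patches, `[[`, 0, "grid_col")
  expect_equal(max(rows), 6)
  expect_equal(max(cols), 8)
  expect_equal(dim(patches[[1]]$pixels), c(278, 278, 3))

  expect_length(divide_into_patches(make_flat_image(278, 278)), 1)
  expect_error(divide_into_patches(make_flat_image(278, 277)), "smaller")
})

test_that("normalization divides by the global RGB max and is idempotent", {
  p <- array(0, dim = c(8, 8, 3))
  p[, , 1] <- 50; p[, , 2] <- 200; p[, , 3] <- 100
  n <- normalize_patch(p)
  expect_equal(max(n), 1.0)
  expect_equal(unique(as.vector(n[, , 1])), 0.25)   # ratios preserved
  expect_equal(unique(as.vector(n[, , 3])), 0.5)
  expect_equal(normalize_patch(n), n)               # idempotent

  const <- array(50, dim = c(4, 4, 3))
  expect_true(all(normalize_patch(const) == 1))

  zero <- array(0, dim = c(4, 4, 3))
  expect_warning(z <- normalize_patch(zero), "all-zero")
  expect_true(all(z == 0))

  # property: random patches, max exactly 1, ratios preserved
  set.seed(1)
  for (i in 1:10) {
    raw <- array(sample(1:255, 48, replace = TRUE), dim = c(4, 4, 3))
    n <- normalize_patch(raw)
    expect_equal(max(n), 1.0)
    expect_equal(n * max(raw), raw + 0)
  }
})

test_that("labeling policy: negatives always negative, positives need tumor", {
  h <- 100L
  mask <- matrix(0L, h, h)
  neg <- divide_into_patches(make_flat_image(h, h, mask = mask, node = "neg1"),
                             patch_size = 100L)[[1]]
  expect_equal(label_patch(neg)$label, "negative")

  # image from a positive node: patch without tumor is EXCLUDED, not negative
  mask_pos <- matrix(0L, h, 2 * h)
  mask_pos[10:40, 110:150] <- 1L
  img_pos <- make_flat_image(h, 2 * h, mask = mask_pos, node = "pos1")
  ps <- divide_into_patches(img_pos, patch_size = 100L)
  ps <- lapply(ps, label_patch)
  expect_equal(ps[[1]]$label, "excluded")
  expect_equal(ps[[2]]$label, "positive")
  expect_gt(ps[[2]]$tumor_fraction, 0)
  expect_equal(ps[[1]]$tumor_fraction, 0)

  # a configurable minimum fraction reclassifies small foci as excluded
  frac <- sum(mask_pos[1:100, 101:200]) / 100^2
  strict <- label_patch(divide_into_patches(img_pos, 100L)[[2]],
                        min_tumor_fraction = frac + 0.01)
  expect_equal(strict$label, "excluded")
  loose <- label_patch(divide_into_patches(img_pos, 100L)[[2]],
                       min_tumor_fraction = frac)
  expect_equal(loose$label, "positive")
})

test_that("used-class counts always partition the patch total", {
  imgs <- generate_dataset(2, 2, 2, small_scene(seed = 13L))
  patches <- extract_labeled_patches(imgs, patch_size = 100L)
  labs <- vapply(patches, `[[`, "", "label")
  expect_equal(sum(labs == "positive") + sum(labs == "negative") +
                 sum(labs == "excluded"), length(patches))
  used <- sum(labs %in% c("positive", "negative"))
  expect_equal(used, length(patches) - sum(labs == "excluded"))
})

test_that("split_by_node never leaks a node across splits", {
  mk <- function(node, status, label, n) {
    lapply(seq_len(n), function(i) {
      list(pixels = array(1L, dim = c(4, 4, 3)), node_id = node,
           source_status = status, label = label, tumor_fraction = 0)
    })
  }
  patches <- c(
    mk("p1", "positive", "positive", 5), mk("p2", "positive", "positive", 3),
    mk("p3", "positive", "positive", 4), mk("n1", "negative", "negative", 6),
    mk("n2", "negative", "negative", 2), mk("n3", "negative", "negative", 4),
    mk("p1", "positive", "excluded", 2))
  sp <- split_by_node(patches, c(1/3, 1/3, 1/3), seed = 4L)
  # 6 nodes, equal fractions -> 2 nodes per split
  expect_equal(unname(table(sp$group_map)[c("train", "validation", "test")]),
               c(2L, 2L, 2L), ignore_attr = TRUE)
  nodes_in <- function(ps) unique(vapply(ps, `[[`, "", "node_id"))
  expect_length(Reduce(intersect, list(nodes_in(sp$train),
                                       nodes_in(sp$validation),
                                       nodes_in(sp$test))), 0)
  # excluded patches are dropped
  expect_equal(length(sp$train) + length(sp$validation) + length(sp$test), 24)
  # determinism
  sp2 <- split_by_node(patches, c(1/3, 1/3, 1/3), seed = 4L)
  expect_identical(sp$group_map, sp2$group_map)
  # each split holds both classes
  for (s in list(sp$train, sp$validation, sp$test)) {
    expect_setequal(unique(vapply(s, `[[`, "", "source_status")),
                    c("positive", "negative"))
  }
  # too few nodes for three splits
  few <- c(mk("p1", "positive", "positive", 2), mk("n1", "negative", "negative", 2),
           mk("n2", "negative", "negative", 2), mk("n3", "negative", "negative", 2))
  expect_error(split_by_node(few, c(1/3, 1/3, 1/3)), "need >=")
  expect_error(split_by_node(patches, c(0.5, 0.5, 0.5)), "summing to 1")
})
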