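test_that("generation is deterministic and n_lesions=0 gives a clean negative", {
  spec <- small_scene(seed = 3L)
  a <- generate_image(spec)
  b <- generate_image(spec)
  expect_identical(a$rgb, b$rgb)
  expect_identical(a$mask, b$mask)

  neg <- generate_image(small_scene(seed = 3L, n_lesions = 0L))
  expect_equal(neg$status, "negative")
  expect_true(all(neg$mask == 0))

  # different seed, different frame
  c <- generate_image(small_scene(seed = 4L))
  expect_false(identical(a$rgb, c$rgb))
})

test_that("lesion count and footprint size match the spec (flood-fill oracle)", {
  img <- generate_image(scene_spec(width = 520, height = 480,
                                   n_lesions = 3,
                                   lesion_diameter_range = c(40, 60),
                                   n_histiocyte_nodules = 0, seed = 9))
  expect_equal(img$status, "positive")
  expect_equal(flood_fill_components(img$mask), 3L)

  # 55 um at 0.46 um/px -> bounding box about 55/0.46 = 119.6 px
  one <- generate_image(scene_spec(width = 400, height = 400, n_lesions = 1,
                                   lesion_diameter_range = c(55, 55),
                                   n_histiocyte_nodules = 0, seed = 2))
  rows <- range(which(rowSums(one$mask) > 0))
  cols <- range(which(colSums(one$mask) > 0))
  expect_lt(abs(diff(rows) + 1 - 55 / 0.46), 4)
  expect_lt(abs(diff(cols) + 1 - 55 / 0.46), 4)
})

test_that("histiocyte nodules are confounders only: no mask contribution", {
  spec <- small_scene(seed = 5L, n_lesions = 0L)
  spec$n_histiocyte_nodules <- 3L
  img <- generate_image(spec)
  expect_true(all(img$mask == 0))
  expect_equal(img$status, "negative")
  # but they do render green cytoplasm: the frame has more green than a
  # nodule-free, lymphocyte-only frame
  bare <- spec
  bare$n_histiocyte_nodules <- 0L
  img_bare <- generate_image(bare)
  expect_gt(mean(img$rgb[, , 2]), mean(img_bare$rgb[, , 2]))
})

test_that("channel contract: blue lymphocyte nuclei, green lesion cytoplasm", {
  spec <- small_scene(seed = 11L, n_lesions = 1L, width = 360, height = 360)
  img <- generate_image(spec)
  inside <- img$mask > 0
  # lesion interior: green-dominated relative to background green
  expect_gt(mean(img$rgb[, , 2][inside]), mean(img$rgb[, , 2][!inside]) * 1.5)
  # background (lymphocyte field): blue exceeds green on bright-blue pixels
  bg_blue <- img$rgb[, , 3][!inside]
  bg_green <- img$rgb[, , 2][!inside]
  nuclei <- bg_blue > 100
  expect_true(mean(bg_blue[nuclei]) > mean(bg_green[nuclei]))
})

test_that("over-constrained placement raises the dedicated error", {
  spec <- scene_spec(width = 150, height = 150, n_lesions = 4,
                     lesion_diameter_range = c(60, 68),
                     placement_retries = 50, seed = 1)
  expect_error(generate_image(spec), class = "duvmap_placement_error")
  # invalid spec errors are distinct
  expect_error(scene_spec(width = -1), class = "duvmap_spec_error")
  expect_error(scene_spec(lesion_diameter_range = c(10, 40)),
               class = "duvmap_spec_error")
})

test_that("generate_dataset assigns nodes, seeds and statuses correctly", {
  base <- small_scene(seed = 21L)
  imgs <- generate_dataset(4, 2, 2, base)
  expect_length(imgs, 6)
  statuses <- vapply(imgs, `[[`, "", "status")
  expect_equal(statuses, c(rep("positive", 4), rep("negative", 2)))
  nodes <- vapply(imgs, `[[`, "", "node_id")
  expect_setequal(nodes[1:4], c("P01", "P02"))
  expect_setequal(nodes[5:6], c("N01", "N02"))
  # deterministic regeneration
  imgs2 <- generate_dataset(4, 2, 2, base)
  expect_identical(imgs[[3]]$rgb, imgs2[[3]]$rgb)
  # negative images yield zero positive patches under exhaustive labeling
  for (img in imgs[statuses == "negative"]) {
    labs <- vapply(extract_labeled_patches(list(img), patch_size = 100L),
                   `[[`, "", "label")
    expect_true(all(labs == "negative"))
  }
  expect_error(generate_dataset(0, 1, 1, base))
  expect_error(generate_dataset(2, 2, 3, base))
})

test_that("datasets round-trip through PNG + manifest", {
  imgs <- generate_dataset(1, 1, 1, small_scene(seed = 31L, width = 300,
                                                height = 280))
  dir <- tempfile("ds")
  manifest <- write_dataset(imgs, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_equal(manifest$status, c("positive", "negative"))
  back <- load_dataset(dir)
  expect_identical(back[[1]]$rgb, imgs[[1]]$rgb)
  expect_identical(back[[1]]$mask, imgs[[1]]$mask)
  expect_equal(back[[2]]$node_id, imgs[[2]]$node_id)
})
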