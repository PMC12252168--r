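test_that("scene generation is fully deterministic in (config, seed)", {
  cfg <- scene_config(image_size = 64, n_objects = 4, seed = 21)
  a <- generate_scene(cfg)
  b <- generate_scene(cfg)
  expect_identical(a$image, b$image)
  expect_identical(a$annotations, b$annotations)
  cfg2 <- scene_config(image_size = 64, n_objects = 4, seed = 22)
  expect_false(identical(generate_scene(cfg2)$image, a$image))
})

test_that("empty scenes and label invariants", {
  sc0 <- generate_scene(scene_config(image_size = 64, n_objects = 0, seed = 1))
  expect_equal(nrow(sc0$annotations), 0L)
  sc <- generate_scene(scene_config(image_size = 96, n_objects = 6, seed = 5))
  ann <- sc$annotations
  expect_true(all(ann$w > 0 & ann$h > 0))
  expect_true(all(ann$cx - ann$w / 2 >= -1e-9 & ann$cx + ann$w / 2 <= 1 + 1e-9))
  expect_true(all(ann$cy - ann$h / 2 >= -1e-9 & ann$cy + ann$h / 2 <= 1 + 1e-9))
  expect_true(all(ann$class_id %in% 0:3))
  expect_true(all(sc$image >= 0 & sc$image <= 1))
})

test_that("every silhouette fills at least 60% of its tight box", {
  set.seed(33)
  for (cls in 0:3) {
    for (rep in 1:5) {
      m <- silhouette_mask(cls, r0 = runif(1, 8, 20), rot = runif(1, 0, 2 * pi),
                           wobble = runif(1, 0, 2 * pi))
      ys <- range(which(rowSums(m) > 0)); xs <- range(which(colSums(m) > 0))
      box_area <- diff(ys[1:2] + c(0, 1)) * diff(xs[1:2] + c(0, 1))
      expect_gt(sum(m) / box_area, 0.6)
    }
  }
})

test_that("zero contrast hides the foreground up to the noise floor", {
  diffs <- vapply(1:20, function(i) {
    cfg0 <- scene_config(image_size = 64, n_objects = 5, contrast = 0,
                         blur_sigma = 1, noise_sigma = 0.03, seed = 100 + i,
                         object_scale_range = c(0.2, 0.4))
    sc <- generate_scene(cfg0)
    if (nrow(sc$annotations) == 0) return(0)
    b <- labels_to_boxes(sc$annotations, 64)
    inside <- array(FALSE, c(64, 64))
    for (j in seq_len(nrow(b))) {
      inside[max(1, ceiling(b$y1[j])):min(64, floor(b$y2[j])),
             max(1, ceiling(b$x1[j])):min(64, floor(b$x2[j]))] <- TRUE
    }
    lum <- apply(sc$image, c(2, 3), mean)
    abs(mean(lum[inside]) - mean(lum[!inside]))
  }, 1)
  expect_lte(mean(diffs), 0.03)
})

test_that("datasets round-trip through the YOLO text dialect", {
  dir <- file.path(tempdir(), "udet-roundtrip")
  unlink(dir, recursive = TRUE)
  cfg <- scene_config(image_size = 64, n_objects = 3, seed = 77)
  mf <- make_dataset(5, cfg, dir)
  expect_length(list.files(file.path(dir, "images"), "\\.png$"), 5L)
  expect_length(list.files(file.path(dir, "labels"), "\\.txt$"), 5L)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  ## writer/reader inverse
  sc <- generate_scene(scene_config(image_size = 64, n_objects = 3, seed = scene_seed(77, 3)))
  disk <- read_yolo_labels(file.path(dir, "labels", "img0003.txt"))
  expect_equal(disk, sc$annotations, tolerance = 1e-5)
  ## degradations never move boxes: labels identical across contrast settings
  c1 <- scene_config(image_size = 64, n_objects = 4, seed = 9, contrast = 0.1)
  c2 <- scene_config(image_size = 64, n_objects = 4, seed = 9, contrast = 0.9)
  expect_identical(generate_scene(c1)$annotations, generate_scene(c2)$annotations)
  ## COCO export is parseable and consistent
  coco <- jsonlite::read_json(coco_export(dir))
  expect_length(coco$images, 5L)
  expect_equal(length(coco$categories), 4L)
  expect_equal(sum(unlist(mf$class_counts)), length(coco$annotations))
})

test_that("class frequencies follow the configured mix", {
  mix <- c(0.4, 0.3, 0.2, 0.1)
  counts <- integer(4)
  n_img <- 120
  for (i in seq_len(n_img)) {
    sc <- generate_scene(scene_config(image_size = 48, n_objects = 5, class_mix = mix,
                                      object_scale_range = c(0.15, 0.3),
                                      seed = scene_seed(5, i)))
    tb <- table(factor(sc$annotations$class_id, levels = 0:3))
    counts <- counts + as.integer(tb)
  }
  n <- sum(counts)
  for (k in 1:4) {
    sd_k <- sqrt(n * mix[k] * (1 - mix[k]))
    expect_lt(abs(counts[k] - n * mix[k]), 3 * sd_k + 1)
  }
})
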