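small_cfg <- function(variant, px = 64L) {
  model_config(variant, input_size = px, channels = c(8L, 16L, 16L, 32L, 32L),
               reg_max = 8L)
}

test_that("variant names map bijectively onto the three feature flags", {
  flags <- lapply(VARIANTS, parse_variant)
  keys <- vapply(flags, function(f) paste0(as.integer(c(f$use_bifpn, f$use_sc2f, f$use_ema)),
                                           collapse = ""), "")
  expect_equal(length(unique(keys)), 8L)
  bse <- parse_variant("BSE")
  expect_true(bse$use_bifpn && bse$use_sc2f && bse$use_ema)
  base <- parse_variant("baseline")
  expect_false(base$use_bifpn || base$use_sc2f || base$use_ema)
  expect_error(parse_variant("Q"))
})

test_that("structural census distinguishes the variants", {
  base <- build_model(small_cfg("baseline"), seed = 0)
  bse <- build_model(small_cfg("BSE"), seed = 0)
  n_of <- function(m, k) { cc <- module_census(m); cc$n[cc$kind == k] }
  expect_equal(n_of(base, "masm"), 0L)
  expect_equal(n_of(base, "ema"), 0L)
  expect_equal(n_of(base, "wfuse"), 0L)
  expect_equal(n_of(bse, "masm"), 3L)   # one per S_C2f bottleneck in the neck
  expect_equal(n_of(bse, "ema"), 4L)    # two backbone + two neck insertions
  expect_equal(n_of(bse, "wfuse"), 5L)  # one per fusion node
})

test_that("every variant builds and runs a forward pass at two legal sizes", {
  set.seed(1)
  for (v in VARIANTS) {
    m <- build_model(small_cfg(v), seed = 2)
    for (px in c(64L, 96L)) {
      out <- block_forward(m, array(runif(3 * px * px), c(3, px, px)))
      expect_length(out$o2o, 3L)
      sizes <- vapply(out$o2o, function(l) dim(l$box)[2], 1L)
      expect_equal(sizes, px %/% c(8L, 16L, 32L))
      expect_true(all(vapply(out$o2o, function(l) all(is.finite(l$box)) && all(is.finite(l$cls)), TRUE)))
    }
  }
  expect_error(model_config("BSE", input_size = 100), "divisible")
})

test_that("forward pass is deterministic for fixed weights and input", {
  m <- build_model(small_cfg("BSE"), seed = 5)
  x <- array(runif(3 * 64 * 64), c(3, 64, 64))
  o1 <- block_forward(m, x)
  o2 <- block_forward(m, x)
  expect_identical(o1$o2o[[1]]$box, o2$o2o[[1]]$box)
  expect_identical(o1$o2o[[3]]$cls, o2$o2o[[3]]$cls)
  ## and a fresh build from the same seed reproduces the same weights
  m2 <- build_model(small_cfg("BSE"), seed = 5)
  o3 <- block_forward(m2, x)
  expect_identical(o1$o2o[[2]]$box, o3$o2o[[2]]$box)
})

test_that("detection decode honours thresholds, clipping and determinism", {
  set.seed(10)
  m <- build_model(small_cfg("baseline"), seed = 7)
  img <- array(runif(3 * 48 * 80), c(3, 48, 80))   # non-square: letterboxed
  expect_equal(nrow(forward_detect(m, img, conf_threshold = 1)), 0L)
  expect_equal(nrow(forward_detect(m, img, max_det = 0L)), 0L)
  det <- forward_detect(m, img, conf_threshold = 0)
  expect_true(all(det$score >= 0 & det$score <= 1))
  expect_true(all(det$x1 >= 0 & det$x2 <= 80 & det$y1 >= 0 & det$y2 <= 48))
  expect_true(all(det$x1 < det$x2 & det$y1 < det$y2))
  expect_identical(det, forward_detect(m, img, conf_threshold = 0))
})

test_that("letterbox preserves aspect ratio and pads with grey", {
  img <- array(runif(3 * 20 * 40), c(3, 20, 40))
  lb <- letterbox(img, 64)
  expect_equal(dim(lb$image), c(3, 64, 64))
  expect_equal(lb$scale, 64 / 40)
  expect_equal(lb$image[1, 1, 1], 114 / 255)   # top padding
})

test_that("feature-flag parameter algebra is additive across necks", {
  counts <- vapply(c("baseline", "B", "S", "E", "BS", "BSE"), function(v)
    count_parameters(build_model(small_cfg(v), seed = 0))$total, 1)
  expect_equal(counts[["BS"]] - counts[["B"]], counts[["S"]] - counts[["baseline"]])
  expect_equal(counts[["BSE"]] - counts[["BS"]], counts[["E"]] - counts[["baseline"]])
})
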