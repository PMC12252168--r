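test_that("weighted fusion follows the normalized-sum rule", {
  i1 <- array(2, c(1, 1, 1)); i2 <- array(4, c(1, 1, 1))
  y <- weighted_fuse(list(i1, i2), c(1, 1))
  expect_equal(y[1, 1, 1], 6 / 2.0001, tolerance = 1e-12)
  ## all-zero weights: epsilon guard returns a zero map, not an error
  expect_equal(weighted_fuse(list(i1, i2), c(0, 0)), array(0, c(1, 1, 1)))
  ## negative weights are clamped before use
  expect_equal(weighted_fuse(list(i1, i2), c(-5, 1)), i2 * (1 / 1.0001))
  expect_error(weighted_fuse(list(i1, array(0, c(2, 1, 1))), c(1, 1)), "shape")
})

test_that("fusion output stays in the scaled input envelope and is asymptotically exact", {
  set.seed(8)
  a <- array(rnorm(3 * 4 * 4), c(3, 4, 4))
  b <- array(rnorm(3 * 4 * 4), c(3, 4, 4))
  w <- c(0.3, 0.7)
  y <- weighted_fuse(list(a, b), w)
  shrink <- sum(w) / (1e-4 + sum(w))
  z <- y / shrink   # undo the epsilon shrinkage: a convex combination remains
  expect_true(all(z >= pmin(a, b) - 1e-12))
  expect_true(all(z <= pmax(a, b) + 1e-12))
  expect_lt(shrink, 1)
  ## identical inputs: output = I * sum(w) / (eps + sum(w)); w -> Inf gives I
  yi <- weighted_fuse(list(a, a), c(1e6, 1e6))
  expect_equal(yi, a, tolerance = 1e-9)
  y1 <- weighted_fuse(list(a, a), c(1, 1))
  expect_equal(y1, a * (2 / 2.0001), tolerance = 1e-12)
})

test_that("resampling doubles or halves spatial size; alignment changes channels only", {
  x <- array(rnorm(4 * 6 * 6), c(4, 6, 6))
  expect_equal(dim(resample(x, "up")), c(4L, 12L, 12L))
  expect_equal(dim(resample(x, "down")), c(4L, 3L, 3L))
  xo <- array(rnorm(4 * 7 * 7), c(4, 7, 7))
  expect_equal(dim(resample(xo, "down")), c(4L, 4L, 4L))  # ceiling division
  al <- build_cbs(4, 8, 1, 1)
  expect_equal(dim(resample(x, "up", align = al)), c(8L, 12L, 12L))
})

test_that("the bidirectional fusion graph is acyclic with no single-input nodes", {
  g <- neck_graph()
  expect_equal(nrow(g), 5L)
  expect_true(all(vapply(g$inputs, length, 1L) >= 2L))
  ## output nodes carry skip edges from the raw pyramid inputs
  expect_true("P3" %in% g$inputs[[which(g$node == "P3out")]])
  expect_true("P4" %in% g$inputs[[which(g$node == "P4out")]])
  ## P2 participates in fusion
  expect_true("P2" %in% unlist(g$inputs))
})

test_that("both necks map P2-P5 features to three head levels", {
  set.seed(3)
  ch <- c(8L, 8L, 16L, 16L)
  feats <- list(p2 = array(rnorm(8 * 16 * 16), c(8, 16, 16)),
                p3 = array(rnorm(8 * 8 * 8), c(8, 8, 8)),
                p4 = array(rnorm(16 * 4 * 4), c(16, 4, 4)),
                p5 = array(rnorm(16 * 2 * 2), c(16, 2, 2)))
  for (mk in list(build_neck_fpnpan, build_neck_bifpn)) {
    nk <- mk(ch)
    out <- block_forward(nk, feats)
    expect_named(out, c("p3", "p4", "p5"))
    expect_equal(dim(out$p3), c(8L, 8L, 8L))
    expect_equal(dim(out$p4), c(16L, 4L, 4L))
    expect_equal(dim(out$p5), c(16L, 2L, 2L))
  }
})

test_that("the bidirectional neck is lighter than the base neck it replaces", {
  base <- build_model(model_config("baseline"), seed = 0)
  bi <- build_model(model_config("B"), seed = 0)
  np <- function(m, part) {
    per <- count_parameters(m)$per_module
    sum(per$n[startsWith(per$path, paste0("model/", part))])
  }
  expect_lt(np(bi, "neck"), np(base, "neck"))
  expect_equal(np(bi, "backbone"), np(base, "backbone"))
  expect_equal(np(bi, "head"), np(base, "head"))
})
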