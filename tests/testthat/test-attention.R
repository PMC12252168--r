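zero_params <- function(mod) {
  walk_modules(mod, function(m, path) {
    for (nm in names(m$params)) m$params[[nm]] <- m$params[[nm]] * 0
  })
  mod
}

test_that("channel attention: zero weights give 0.5, outputs always in (0,1)", {
  m0 <- zero_params(masm_module(3))
  x <- array(0, c(3, 4, 4))
  expect_equal(as.vector(channel_attention(x, m0)), rep(0.5, 3))
  set.seed(2)
  m <- masm_module(5, reduction_ratio = 2)
  for (i in 1:5) {
    x <- array(rnorm(5 * 6 * 6, sd = 3), c(5, 6, 6))
    w <- as.vector(channel_attention(x, m))
    expect_true(all(w > 0 & w < 1))
  }
  expect_error(channel_attention(array(0, c(4, 3, 3)), m), "channels")
})

test_that("MASM sub-operators match the scalar oracles to 1e-6 relative", {
  set.seed(42)
  for (C in c(2, 4)) {
    m <- masm_module(C, reduction_ratio = 2)
    x <- array(rnorm(C * 8 * 8), c(C, 8, 8))
    expect_rel_equal(as.vector(channel_attention(x, m)),
                     oracle_channel_attention(x, m))
    ca <- oracle_channel_attention(x, m)
    xw <- x * array(rep(ca, 64), dim(x))
    expect_rel_equal(pixel_attention(xw, m), oracle_pixel_attention(xw, m))
    expect_rel_equal(spatial_attention(xw, m), oracle_spatial_attention(xw, m))
    expect_rel_equal(masm_forward(x, m), oracle_masm(x, m))
  }
})

test_that("pixel attention gates: zero weights halve, zero input stays zero", {
  m0 <- zero_params(masm_module(2))
  x <- array(rnorm(2 * 3 * 3), c(2, 3, 3))
  expect_equal(pixel_attention(x, m0), 0.5 * x)
  expect_equal(pixel_attention(array(0, c(2, 3, 3)), m0), array(0, c(2, 3, 3)))
})

test_that("spatial attention: zero network emits zero, same-padding keeps shape", {
  m0 <- zero_params(masm_module(2))
  x <- array(rnorm(2 * 5 * 5), c(2, 5, 5))
  expect_equal(spatial_attention(x, m0), array(0, dim(x)))
  m <- masm_module(8)
  x8 <- array(rnorm(8 * 20 * 20), c(8, 20, 20))
  expect_equal(dim(spatial_attention(x8, m)), c(8L, 20L, 20L))
  expect_equal(dim(masm_forward(x8, m)), dim(x8))
})

test_that("MASM annihilates with all-zero weights and on zero input", {
  m0 <- zero_params(masm_module(3))
  x <- array(rnorm(3 * 4 * 4), c(3, 4, 4))
  expect_equal(masm_forward(x, m0), array(0, dim(x)))
  m <- masm_module(3)
  expect_equal(masm_forward(array(0, c(3, 4, 4)), m), array(0, c(3, 4, 4)))
})

test_that("directional means: worked example, constants, and Eq-12 consistency", {
  x <- array(c(1, 3, 2, 4), c(1, 2, 2))   # [[1,2],[3,4]] row-major
  dm <- directional_means(x)
  expect_equal(as.vector(dm$row_means), c(1.5, 3.5))
  expect_equal(as.vector(dm$col_means), c(2, 3))
  expect_equal(dm$global_mean, 2.5)
  const <- array(7.5, c(3, 4, 5))
  dmc <- directional_means(const)
  expect_true(all(dmc$row_means == 7.5) && all(dmc$col_means == 7.5) &&
                all(dmc$global_mean == 7.5))
  set.seed(9)
  x <- array(rnorm(3 * 5 * 7), c(3, 5, 7))
  dm <- directional_means(x)
  expect_rel_equal(rowMeans(dm$row_means), dm$global_mean)
  expect_rel_equal(rowMeans(dm$col_means), dm$global_mean)
  direct <- vapply(1:3, function(c) sum(x[c, , ]) / 35, 1)
  expect_rel_equal(dm$global_mean, direct)
})

test_that("EMA: shape contract, group validation, softmax normalization", {
  set.seed(4)
  em <- ema_module(32, 8)
  x <- array(rnorm(32 * 16 * 16), c(32, 16, 16))
  y <- ema_forward(x, em)
  expect_equal(dim(y), dim(x))
  expect_true(all(is.finite(y)))
  expect_error(ema_module(32, 32), "at least 2 channels")
  expect_error(ema_module(30, 8), "divide")
  expect_error(ema_forward(array(0, c(16, 4, 4)), em), "channels")
  ## the cross-branch softmax vectors are probability vectors
  g <- op_softmax_rows(matrix(rnorm(8), 1, 8))
  expect_equal(sum(g), 1, tolerance = 1e-12)
})

test_that("attention operators preserve shape for non-square maps", {
  m <- masm_module(4)
  x <- array(rnorm(4 * 3 * 9), c(4, 3, 9))
  expect_equal(dim(masm_forward(x, m)), dim(x))
  em <- ema_module(4, 2)
  expect_equal(dim(ema_forward(x, em)), dim(x))
})
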