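test_that("engine convolution matches the loop-based oracle", {
  set.seed(101)
  cases <- list(
    list(C = 3, H = 6, W = 5, co = 4, kh = 3, kw = 3, s = 1, g = 1),
    list(C = 4, H = 7, W = 7, co = 4, kh = 1, kw = 7, s = 1, g = 4),  # strip, depthwise
    list(C = 4, H = 7, W = 7, co = 4, kh = 7, kw = 1, s = 1, g = 4),
    list(C = 4, H = 8, W = 8, co = 6, kh = 3, kw = 3, s = 2, g = 2),
    list(C = 2, H = 5, W = 9, co = 3, kh = 1, kw = 1, s = 1, g = 1))
  for (cs in cases) {
    x <- array(rnorm(cs$C * cs$H * cs$W), c(cs$C, cs$H, cs$W))
    w <- matrix(rnorm(cs$co * (cs$C / cs$g) * cs$kh * cs$kw),
                cs$co, (cs$C / cs$g) * cs$kh * cs$kw)
    b <- rnorm(cs$co)
    got <- cpp_conv2d_fw(x, dim(x), w, b, cs$kh, cs$kw, cs$s,
                         cs$kh %/% 2L, cs$kw %/% 2L, cs$g)
    want <- oracle_conv2d(x, w, b, cs$kh, cs$kw, cs$s, cs$kh %/% 2, cs$kw %/% 2, cs$g)
    expect_equal(dim(got), dim(want))
    expect_rel_equal(got, want, 1e-10)
  }
})

test_that("tape gradients agree with central finite differences", {
  set.seed(7)
  x <- array(rnorm(4 * 6 * 6), c(4, 6, 6))
  blk <- build_c2f(4, 4, 1, TRUE, masm = list(reduction_ratio = 2))
  od <- dim(block_forward(blk, x))
  r <- array(rnorm(prod(od)), od)
  run <- function() {
    tape_start()
    on.exit(tape_stop())
    loss <- op_sum(op_mul(block_forward(blk, x), r))
    list(value = vv(loss), node = loss)
  }
  tape_start()
  loss <- op_sum(op_mul(block_forward(blk, x), r))
  backward(loss)
  grads <- collected_grads()
  tape_stop()
  expect_gt(length(grads), 10)
  eps <- 1e-4
  checked <- 0
  for (h in grads[seq(1, length(grads), by = 3)]) {
    pv <- h$mod$params[[h$name]]
    for (i in sample(length(pv), min(4, length(pv)))) {
      h$mod$params[[h$name]][i] <- pv[i] + eps
      lp <- run()$value
      h$mod$params[[h$name]][i] <- pv[i] - eps
      lm <- run()$value
      h$mod$params[[h$name]][i] <- pv[i]
      num <- (lp - lm) / (2 * eps)
      expect_equal(h$grad[i], num, tolerance = 1e-4)
      checked <- checked + 1
    }
  }
  expect_gt(checked, 10)
})

test_that("three cascaded 5x5 max-pools equal single 9x9 and 13x13 pools", {
  set.seed(3)
  x <- array(rnorm(2 * 15 * 15), c(2, 15, 15))
  p1 <- op_maxpool(x, 5L, 1L, 2L)
  p2 <- op_maxpool(p1, 5L, 1L, 2L)
  p3 <- op_maxpool(p2, 5L, 1L, 2L)
  expect_equal(p2, op_maxpool(x, 9L, 1L, 4L))
  expect_equal(p3, op_maxpool(x, 13L, 1L, 6L))
})

test_that("row softmax normalizes and broadcasting multiply reduces correctly", {
  set.seed(5)
  m <- matrix(rnorm(12), 3, 4)
  sm <- op_softmax_rows(m)
  expect_equal(rowSums(sm), rep(1, 3), tolerance = 1e-12)
  x <- array(rnorm(3 * 4 * 5), c(3, 4, 5))
  cvec <- array(runif(3), c(3, 1, 1))
  y <- op_mul(x, cvec)
  expect_equal(y[2, , ], x[2, , ] * cvec[2, 1, 1])
  smap <- array(runif(4 * 5), c(1, 4, 5))
  y2 <- op_mul(x, smap)
  expect_equal(y2[, 3, 2], x[, 3, 2] * smap[1, 3, 2])
})

test_that("nearest upsample doubles each axis and inverts under summed pooling", {
  x <- array(seq_len(2 * 3 * 4), c(2, 3, 4))
  y <- op_upsample2(x)
  expect_equal(dim(y), c(2L, 6L, 8L))
  expect_equal(y[, 1, 1], x[, 1, 1])
  expect_equal(y[, 2, 2], x[, 1, 1])
  g <- cpp_upsample2_bw(y, dim(x))
  expect_equal(g, x * 4)
})
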