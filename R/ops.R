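## Differentiable operations over (C, H, W) arrays.
## Every op accepts plain arrays or tape nodes; ops used on the structural
## profiling path additionally accept `ud_shape` tokens (conv adds to the MAC
## counter, everything else only transforms the shape).

conv_out_hw <- function(hw, k, s, p) (hw + 2L * p - k) %/% s + 1L

## x: (C,H,W); w: (Co) x (C/groups*kh*kw) matrix; b: NULL or length-Co vector.
op_conv <- function(x, w, b = NULL, kh, kw, stride = 1L, ph, pw, groups = 1L) {
  if (is_shape(x)) {
    s <- x$shape
    co <- nrow(vv(w))
    ho <- conv_out_hw(s[2], kh, stride, ph)
    wo <- conv_out_hw(s[3], kw, stride, pw)
    the$macs <- the$macs + as.numeric(co) * ho * wo * (s[1] / groups) * kh * kw
    return(new_shape(c(co, ho, wo)))
  }
  xv <- vv(x); wv <- vv(w); bv <- if (is.null(b)) NULL else vv(b)
  y <- cpp_conv2d_fw(xv, dim(xv), wv, bv, kh, kw, stride, ph, pw, groups)
  if (!is_nd(x) && !is_nd(w)) return(y)
  nd(y, list(x, w, b), function(g) {
    r <- cpp_conv2d_bw(xv, dim(xv), wv, g, kh, kw, stride, ph, pw, groups, !is.null(b))
    list(r$gx, r$gw, if (is.null(b)) NULL else r$gb)
  })
}

## Batch normalization on a single map: per-channel statistics over H x W when
## `use_batch_stats`, running statistics otherwise. Returns the normalized map;
## batch moments are exposed via attribute for the layer to update its state.
op_bn <- function(x, gamma, beta, rmean, rvar, eps = 1e-5, use_batch_stats = TRUE) {
  if (is_shape(x)) return(x)
  xv <- vv(x); gv <- vv(gamma); bv <- vv(beta)
  d <- dim(xv); C <- d[1]; N <- d[2] * d[3]
  xm <- matrix(xv, C, N)
  if (use_batch_stats) {
    mu <- rowMeans(xm)
    va <- rowMeans(xm * xm) - mu * mu
  } else {
    mu <- rmean
    va <- rvar
  }
  istd <- 1 / sqrt(va + eps)
  xhat <- (xm - mu) * istd
  y <- array(xhat * gv + bv, d)
  attr(y, "moments") <- list(mean = mu, var = va)
  if (!is_nd(x) && !is_nd(gamma)) return(y)
  out <- nd(y, list(x, gamma, beta), function(g) {
    gm <- matrix(g, C, N)
    ggamma <- rowSums(gm * xhat)
    gbeta <- rowSums(gm)
    if (use_batch_stats) {
      gx <- (gv * istd) * (gm - gbeta / N - xhat * (ggamma / N))
    } else {
      gx <- gm * (gv * istd)
    }
    list(array(gx, d), ggamma, gbeta)
  })
  out
}

## Per-channel normalization with affine (group count == channel count).
op_channelnorm <- function(x, gamma, beta, eps = 1e-5) {
  op_bn(x, gamma, beta, NULL, NULL, eps = eps, use_batch_stats = TRUE)
}

op_elemwise <- function(x, f, df) {
  if (is_shape(x)) return(x)
  xv <- vv(x)
  y <- f(xv)
  if (!is_nd(x)) return(y)
  nd(y, list(x), function(g) list(g * df(xv, y)))
}

op_silu <- function(x) op_elemwise(x,
  function(v) v * stats::plogis(v),
  function(v, y) { s <- stats::plogis(v); s * (1 + v * (1 - s)) })

op_relu <- function(x) op_elemwise(x,
  function(v) pmax(v, 0),
  function(v, y) (v > 0) + 0)

op_sigmoid <- function(x) op_elemwise(x,
  function(v) stats::plogis(v),
  function(v, y) y * (1 - y))

op_add <- function(x, y) {
  force(y)  # shape mode must still traverse the subgraph that produced y
  if (is_shape(x)) return(x)
  out <- vv(x) + vv(y)
  if (!is_nd(x) && !is_nd(y)) return(out)
  nd(out, list(x, y), function(g) list(g, g))
}

op_scale <- function(x, k) {
  if (is_shape(x)) return(x)
  out <- vv(x) * k
  if (!is_nd(x)) return(out)
  nd(out, list(x), function(g) list(g * k))
}

## Elementwise product with broadcasting: dims of `a` must equal dim(x) or be 1.
op_mul <- function(x, a) {
  force(a)  # shape mode must still traverse the subgraph that produced a
  if (is_shape(x)) return(x)
  xv <- vv(x); av <- vv(a)
  da <- dim(av); dx <- dim(xv)
  bc <- !is.null(da) && any(da == 1L & dx > 1L)
  ae <- if (bc) bcast(av, dx) else av
  y <- xv * ae
  if (!is_nd(x) && !is_nd(a)) return(y)
  nd(y, list(x, a), function(g) {
    ga <- g * xv
    if (bc) ga <- reduce_to(ga, da)
    list(g * ae, ga)
  })
}

bcast <- function(a, dx) {
  da <- dim(a)
  idx <- lapply(seq_along(dx), function(k) if (da[k] == 1L) rep(1L, dx[k]) else seq_len(dx[k]))
  array(a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE], dx)
}

reduce_to <- function(g, da) {
  keep <- which(da != 1L)
  if (length(keep) == 0L) return(array(sum(g), da))
  s <- apply(g, keep, sum)
  array(as.vector(s), da)
}

op_concat <- function(xs) {
  if (is_shape(xs[[1]])) {
    s <- shape_of(xs[[1]])
    return(new_shape(c(sum(vapply(xs, function(z) shape_of(z)[1], 1L)), s[2], s[3])))
  }
  vs <- lapply(xs, vv)
  cs <- vapply(vs, function(z) dim(z)[1], 1L)
  d <- dim(vs[[1]])
  y <- array(0, c(sum(cs), d[2], d[3]))
  at <- 0L
  for (i in seq_along(vs)) {
    y[at + seq_len(cs[i]), , ] <- vs[[i]]
    at <- at + cs[i]
  }
  if (!any(vapply(xs, is_nd, TRUE))) return(y)
  nd(y, xs, function(g) {
    at <- 0L
    out <- vector("list", length(xs))
    for (i in seq_along(xs)) {
      out[[i]] <- g[at + seq_len(cs[i]), , , drop = FALSE]
      at <- at + cs[i]
    }
    out
  })
}

op_slice_c <- function(x, from, len) {
  if (is_shape(x)) { s <- x$shape; return(new_shape(c(len, s[2], s[3]))) }
  xv <- vv(x)
  d <- dim(xv)
  y <- xv[from + seq_len(len) - 1L, , , drop = FALSE]
  if (!is_nd(x)) return(y)
  nd(y, list(x), function(g) {
    gx <- array(0, d)
    gx[from + seq_len(len) - 1L, , ] <- g
    list(gx)
  })
}

op_maxpool <- function(x, k, stride = 1L, pad = 0L) {
  if (is_shape(x)) {
    s <- x$shape
    return(new_shape(c(s[1], conv_out_hw(s[2], k, stride, pad), conv_out_hw(s[3], k, stride, pad))))
  }
  xv <- vv(x)
  r <- cpp_maxpool_fw(xv, dim(xv), k, stride, pad)
  if (!is_nd(x)) return(r$y)
  xdim <- dim(xv)
  nd(r$y, list(x), function(g) list(cpp_maxpool_bw(g, r$arg, xdim)))
}

op_upsample2 <- function(x) {
  if (is_shape(x)) { s <- x$shape; return(new_shape(c(s[1], 2L * s[2], 2L * s[3]))) }
  xv <- vv(x)
  y <- cpp_upsample2_fw(xv, dim(xv))
  if (!is_nd(x)) return(y)
  xdim <- dim(xv)
  nd(y, list(x), function(g) list(cpp_upsample2_bw(g, xdim)))
}

## Mean over both spatial dims -> (C,1,1)
op_gap <- function(x) {
  if (is_shape(x)) return(new_shape(c(x$shape[1], 1L, 1L)))
  xv <- vv(x); d <- dim(xv); N <- d[2] * d[3]
  y <- array(rowMeans(matrix(xv, d[1], N)), c(d[1], 1L, 1L))
  if (!is_nd(x)) return(y)
  nd(y, list(x), function(g) list(array(rep(as.vector(g) / N, N), d)))
}

## Max over both spatial dims -> (C,1,1)
op_gmp <- function(x) {
  if (is_shape(x)) return(new_shape(c(x$shape[1], 1L, 1L)))
  xv <- vv(x); d <- dim(xv); N <- d[2] * d[3]
  m <- matrix(xv, d[1], N)
  j <- max.col(m, ties.method = "first")
  y <- array(m[cbind(seq_len(d[1]), j)], c(d[1], 1L, 1L))
  if (!is_nd(x)) return(y)
  nd(y, list(x), function(g) {
    gx <- matrix(0, d[1], N)
    gx[cbind(seq_len(d[1]), j)] <- as.vector(g)
    list(array(gx, d))
  })
}

## Mean over width -> (C,H,1); mean over height -> (C,1,W)
op_pool_w <- function(x) {
  if (is_shape(x)) return(new_shape(c(x$shape[1], x$shape[2], 1L)))
  xv <- vv(x); d <- dim(xv)
  y <- array(apply(xv, c(1, 2), mean), c(d[1], d[2], 1L))
  if (!is_nd(x)) return(y)
  nd(y, list(x), function(g) list(array(rep(as.vector(g), d[3]), d) / d[3]))
}

op_pool_h <- function(x) {
  if (is_shape(x)) return(new_shape(c(x$shape[1], 1L, x$shape[3])))
  xv <- vv(x); d <- dim(xv)
  y <- array(apply(xv, c(1, 3), mean), c(d[1], 1L, d[3]))
  if (!is_nd(x)) return(y)
  nd(y, list(x), function(g) {
    gv <- array(0, d)
    gm <- matrix(as.vector(g), d[1], d[3])
    for (w in seq_len(d[3])) gv[, , w] <- gm[, w] / d[2]
    list(gv)
  })
}

op_reshape <- function(x, newdim) {
  if (is_shape(x)) return(new_shape(newdim))
  xv <- vv(x); d <- dim(xv)
  y <- xv
  dim(y) <- newdim
  if (!is_nd(x)) return(y)
  nd(y, list(x), function(g) { dim(g) <- d; list(g) })
}

op_aperm <- function(x, perm) {
  xv <- vv(x)
  y <- aperm(xv, perm)
  if (!is_nd(x)) return(y)
  nd(y, list(x), function(g) list(aperm(g, order(perm))))
}

## Plain matrix product of 2-D values.
op_matmul <- function(a, b) {
  av <- vv(a); bv <- vv(b)
  y <- av %*% bv
  if (!is_nd(a) && !is_nd(b)) return(y)
  nd(y, list(a, b), function(g) list(g %*% t(bv), t(av) %*% g))
}

## Row-wise softmax of a 2-D value.
op_softmax_rows <- function(x) {
  xv <- vv(x)
  m <- xv - apply(xv, 1, max)
  e <- exp(m)
  y <- e / rowSums(e)
  if (!is_nd(x)) return(y)
  nd(y, list(x), function(g) list(y * (g - rowSums(g * y))))
}

op_sum <- function(x) {
  xv <- vv(x)
  y <- sum(xv)
  if (!is_nd(x)) return(y)
  d <- dim(xv)
  n <- length(xv)
  nd(y, list(x), function(g) list(array(rep(g, n), if (is.null(d)) n else d)))
}

op_add_scalar_chain <- function(nodes) {
  ## sum a list of scalar nodes/values into one scalar node
  tot <- 0
  for (z in nodes) tot <- if (identical(tot, 0)) z else {
    a <- tot; b <- z
    y <- vv(a) + vv(b)
    if (!is_nd(a) && !is_nd(b)) y else nd(y, list(a, b), function(g) list(g, g))
  }
  tot
}

## Numerically stable binary cross-entropy with logits, summed.
## target and weight are constants with the same length as z.
op_bce_logits_sum <- function(z, target, weight = NULL) {
  zv <- vv(z)
  w <- if (is.null(weight)) 1 else weight
  l <- pmax(zv, 0) - zv * target + log1p(exp(-abs(zv)))
  y <- sum(w * l)
  if (!is_nd(z)) return(y)
  nd(y, list(z), function(g) {
    gz <- w * (stats::plogis(zv) - target)
    dim(gz) <- dim(zv)
    list(g * gz)
  })
}

## Distribution-focal expectation: logits is (reg_max x n); returns length-n
## expectation over bins 0..reg_max-1 via column softmax.
op_dfl_expect <- function(logits) {
  zv <- vv(logits)
  rm <- nrow(zv)
  m <- zv - matrix(apply(zv, 2, max), rm, ncol(zv), byrow = TRUE)
  e <- exp(m)
  p <- e / matrix(colSums(e), rm, ncol(zv), byrow = TRUE)
  bins <- seq_len(rm) - 1
  y <- as.vector(crossprod(p, bins))
  if (!is_nd(logits)) return(y)
  nd(y, list(logits), function(g) {
    ## d y_j / d z_ij = p_ij * (bin_i - y_j)
    gm <- p * (matrix(bins, rm, length(y)) - matrix(y, rm, length(y), byrow = TRUE))
    list(gm * matrix(g, rm, length(y), byrow = TRUE))
  })
}
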