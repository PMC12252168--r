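## Building blocks of the detector: CBS, SCDown, C2f / S_C2f, C2fCIB, SPPF,
## PSA. All constructors return modules; forward passes preserve spatial size
## except stride-2 blocks, which halve it (ceiling division).

#' Convolution-BN-SiLU block
#'
#' @param c_in,c_out channel counts.
#' @param k square kernel size.
#' @param stride 1 or 2.
#' @return a module; its forward pass maps `(c_in, H, W)` to
#'   `(c_out, H', W')` with same-padding semantics.
#' @export
build_cbs <- function(c_in, c_out, k = 3L, stride = 1L) {
  stopifnot(stride %in% c(1L, 2L))
  layer_conv(c_in, c_out, k, stride = stride, bn = TRUE, act = "silu")
}

#' Spatial-channel decoupled downsampling
#'
#' A 1x1 channel-adjusting convolution followed by a depthwise 3x3 stride-2
#' convolution; halves height and width.
#' @inheritParams build_cbs
#' @export
build_scdown <- function(c_in, c_out) {
  m <- new_module("scdown", cfg = list(c_in = c_in, c_out = c_out))
  add_child(m, "cv1", layer_conv(c_in, c_out, 1, act = "silu"))
  add_child(m, "cv2", layer_conv(c_out, c_out, 3, stride = 2L, groups = c_out, act = "none"))
  m
}

ud_fwd.ud_scdown <- function(mod, x, ...) ud_fwd(mod$children$cv2, ud_fwd(mod$children$cv1, x))

## Standard two-conv bottleneck, optionally with MASM after the second conv.
build_bottleneck <- function(c, shortcut = TRUE, masm_cfg = NULL) {
  m <- new_module("bottleneck", cfg = list(c = c, shortcut = shortcut, masm = !is.null(masm_cfg)))
  add_child(m, "cv1", layer_conv(c, c, 3, act = "silu"))
  add_child(m, "cv2", layer_conv(c, c, 3, act = "silu"))
  if (!is.null(masm_cfg)) {
    add_child(m, "masm", masm_module(c, reduction_ratio = masm_cfg$reduction_ratio %||% 8L,
                                     kernel_set = masm_cfg$kernel_set %||% c(7L, 11L, 21L)))
  }
  m
}

ud_fwd.ud_bottleneck <- function(mod, x, ...) {
  y <- ud_fwd(mod$children$cv2, ud_fwd(mod$children$cv1, x))
  if (mod$cfg$masm) y <- masm_forward(y, mod$children$masm)
  if (mod$cfg$shortcut) op_add(x, y) else y
}

#' Split-transform-concat block (C2f), plain or with MASM bottlenecks (S_C2f)
#'
#' An entry 1x1 convolution to twice the hidden width, a channel split, `n`
#' chained bottlenecks on one half, concatenation of every intermediate map,
#' and an exit 1x1 convolution. When `masm` is supplied each bottleneck embeds
#' a MASM after its second convolution, giving the S_C2f variant.
#'
#' @inheritParams build_cbs
#' @param n number of bottlenecks.
#' @param shortcut residual add inside each bottleneck.
#' @param masm `NULL` for plain C2f, or a list with optional
#'   `reduction_ratio` / `kernel_set` entries for S_C2f.
#' @export
build_c2f <- function(c_in, c_out, n = 1L, shortcut = FALSE, masm = NULL) {
  ch <- c_out %/% 2L
  m <- new_module("c2f", cfg = list(c_in = c_in, c_out = c_out, n = n, hidden = ch,
                                    sc2f = !is.null(masm)))
  add_child(m, "cv1", layer_conv(c_in, 2L * ch, 1, act = "silu"))
  add_child(m, "cv2", layer_conv((2L + n) * ch, c_out, 1, act = "silu"))
  for (i in seq_len(n)) add_child(m, paste0("b", i), build_bottleneck(ch, shortcut, masm))
  m
}

ud_fwd.ud_c2f <- function(mod, x, ...) {
  cf <- mod$cfg
  y <- ud_fwd(mod$children$cv1, x)
  parts <- list(op_slice_c(y, 1L, cf$hidden), op_slice_c(y, cf$hidden + 1L, cf$hidden))
  cur <- parts[[2]]
  for (i in seq_len(cf$n)) {
    cur <- ud_fwd(mod$children[[paste0("b", i)]], cur)
    parts[[length(parts) + 1L]] <- cur
  }
  ud_fwd(mod$children$cv2, op_concat(parts))
}

## Compact inverted block (large-kernel variant) and its C2f wrapper: part of
## the inherited base topology, used at the final neck stage of the base model.
build_cib <- function(c, shortcut = TRUE) {
  m <- new_module("cib", cfg = list(c = c, shortcut = shortcut))
  add_child(m, "cv1", layer_conv(c, c, 3, groups = c, act = "silu"))
  add_child(m, "cv2", layer_conv(c, 2L * c, 1, act = "silu"))
  add_child(m, "rep7", layer_conv(2L * c, 2L * c, 7, groups = 2L * c, act = "none"))
  add_child(m, "rep3", layer_conv(2L * c, 2L * c, 3, groups = 2L * c, act = "none"))
  add_child(m, "cv3", layer_conv(2L * c, c, 1, act = "silu"))
  add_child(m, "cv4", layer_conv(c, c, 3, groups = c, act = "silu"))
  m
}

ud_fwd.ud_cib <- function(mod, x, ...) {
  ch <- mod$children
  y <- ud_fwd(ch$cv2, ud_fwd(ch$cv1, x))
  y <- op_silu(op_add(ud_fwd(ch$rep7, y), ud_fwd(ch$rep3, y)))
  y <- ud_fwd(ch$cv4, ud_fwd(ch$cv3, y))
  if (mod$cfg$shortcut) op_add(x, y) else y
}

build_c2fcib <- function(c_in, c_out, n = 1L, shortcut = TRUE) {
  ch <- c_out %/% 2L
  m <- new_module("c2f", cfg = list(c_in = c_in, c_out = c_out, n = n, hidden = ch, sc2f = FALSE))
  add_child(m, "cv1", layer_conv(c_in, 2L * ch, 1, act = "silu"))
  add_child(m, "cv2", layer_conv((2L + n) * ch, c_out, 1, act = "silu"))
  for (i in seq_len(n)) add_child(m, paste0("b", i), build_cib(ch, shortcut))
  m
}

#' Fast spatial pyramid pooling block
#'
#' Entry 1x1 convolution, three successive 5x5 stride-1 max-pools (effective
#' receptive fields 5/9/13), concatenation of the four maps, exit 1x1
#' convolution. Spatial size is preserved.
#' @inheritParams build_cbs
#' @export
build_sppf <- function(c_in, c_out) {
  ch <- c_in %/% 2L
  m <- new_module("sppf", cfg = list(hidden = ch))
  add_child(m, "cv1", layer_conv(c_in, ch, 1, act = "silu"))
  add_child(m, "cv2", layer_conv(4L * ch, c_out, 1, act = "silu"))
  m
}

ud_fwd.ud_sppf <- function(mod, x, ...) {
  y <- ud_fwd(mod$children$cv1, x)
  p1 <- op_maxpool(y, 5L, 1L, 2L)
  p2 <- op_maxpool(p1, 5L, 1L, 2L)
  p3 <- op_maxpool(p2, 5L, 1L, 2L)
  ud_fwd(mod$children$cv2, op_concat(list(y, p1, p2, p3)))
}

#' Partial self-attention block
#'
#' Splits the map after a 1x1 convolution, applies multi-head self-attention
#' and a feed-forward stack to one partition (with residual connections),
#' concatenates and mixes with a final 1x1 convolution. Shape-preserving.
#'
#' @param channels input = output channels; must be even.
#' @param num_heads heads for the attended partition; defaults to
#'   `max(1, (channels/2) %/% 64)`. The head dimension must be integral.
#' @export
build_psa <- function(channels, num_heads = NULL) {
  if (channels %% 2L != 0L) stop("PSA needs an even channel count", call. = FALSE)
  ch <- channels %/% 2L
  nh <- if (is.null(num_heads)) max(1L, ch %/% 64L) else as.integer(num_heads)
  if (ch %% nh != 0L)
    stop("PSA head dim not integral: ", ch, " channels / ", nh, " heads", call. = FALSE)
  hd <- ch %/% nh
  kd <- max(1L, hd %/% 2L)
  m <- new_module("psa", cfg = list(c = channels, ch = ch, nh = nh, hd = hd, kd = kd))
  add_child(m, "cv1", layer_conv(channels, 2L * ch, 1, act = "silu"))
  add_child(m, "cv2", layer_conv(2L * ch, channels, 1, act = "silu"))
  add_child(m, "qkv", layer_conv(ch, nh * (2L * kd + hd), 1, act = "none"))
  add_child(m, "proj", layer_conv(ch, ch, 1, act = "none"))
  add_child(m, "pe", layer_conv(ch, ch, 3, groups = ch, act = "none"))
  add_child(m, "ffn1", layer_conv(ch, 2L * ch, 1, act = "silu"))
  add_child(m, "ffn2", layer_conv(2L * ch, ch, 1, act = "none"))
  m
}

ud_fwd.ud_psa <- function(mod, x, ...) {
  cf <- mod$cfg
  ch <- mod$children
  if (is_shape(x)) {
    s <- x$shape
    ud_fwd(ch$cv1, x)
    bshape <- new_shape(c(cf$ch, s[2], s[3]))
    ud_fwd(ch$qkv, bshape)
    ud_fwd(ch$pe, bshape)
    ud_fwd(ch$proj, bshape)
    ud_fwd(ch$ffn2, ud_fwd(ch$ffn1, bshape))
    ud_fwd(ch$cv2, new_shape(c(2L * cf$ch, s[2], s[3])))
    return(x)
  }
  y <- ud_fwd(ch$cv1, x)
  a <- op_slice_c(y, 1L, cf$ch)
  b <- op_slice_c(y, cf$ch + 1L, cf$ch)
  d <- shape_of(b)
  N <- d[2] * d[3]
  qkv <- ud_fwd(ch$qkv, b)
  per <- 2L * cf$kd + cf$hd
  outs <- vector("list", cf$nh)
  vparts <- vector("list", cf$nh)
  scale <- cf$kd^(-0.5)
  for (h in seq_len(cf$nh)) {
    base <- (h - 1L) * per
    q <- op_reshape(op_slice_c(qkv, base + 1L, cf$kd), c(cf$kd, N))
    k <- op_reshape(op_slice_c(qkv, base + cf$kd + 1L, cf$kd), c(cf$kd, N))
    v <- op_slice_c(qkv, base + 2L * cf$kd + 1L, cf$hd)
    vparts[[h]] <- v
    vm <- op_reshape(v, c(cf$hd, N))
    attn <- op_softmax_rows(op_scale(op_matmul(op_t(q), k), scale))  # (N, N), rows = queries
    outs[[h]] <- op_reshape(op_matmul(vm, op_t(attn)), c(cf$hd, d[2], d[3]))
  }
  att <- op_concat(outs)
  vfull <- op_concat(vparts)
  att <- op_add(att, ud_fwd(ch$pe, vfull))
  b2 <- op_add(b, ud_fwd(ch$proj, att))
  b3 <- op_add(b2, ud_fwd(ch$ffn2, ud_fwd(ch$ffn1, b2)))
  ud_fwd(ch$cv2, op_concat(list(a, b3)))
}

## 2-D transpose as an op
op_t <- function(x) {
  xv <- vv(x)
  y <- t(xv)
  if (!is_nd(x)) return(y)
  nd(y, list(x), function(g) list(t(g)))
}
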