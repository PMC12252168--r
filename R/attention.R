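## Multi-Scale Attention Synergy Module (MASM) and Efficient Multi-Scale
## Attention (EMA): shape-preserving feature-map operators.
##
## MASM runs sequential channel gating followed by two parallel paths --
## pixel-level gating and multi-kernel strip-convolution spatial attention --
## whose outputs are combined by an elementwise product. EMA groups channels,
## gates each group with 1-D directional pooled descriptors, and builds a
## spatial map through cross-branch softmax interaction.

#' Multi-scale attention synergy module
#'
#' Constructs the MASM operator for feature maps with `channels` channels.
#' The module chains channel attention (average- and max-pooled descriptors
#' through a shared two-layer 1x1 convolution stack, sigmoid-gated), pixel
#' attention (a per-position sigmoid gate from two 1x1 convolutions), and
#' spatial attention built from a 5x5 depthwise convolution plus pairs of
#' 1xK / Kx1 depthwise strip convolutions for each K in `kernel_set`, mixed
#' by a single pointwise convolution.
#'
#' @param channels number of input/output channels.
#' @param reduction_ratio hidden width divisor of the two-convolution stacks;
#'   the hidden width is `max(1, channels %/% reduction_ratio)`.
#' @param kernel_set strip kernel lengths, default `c(7, 11, 21)`.
#' @param shared_mlp if `TRUE` (default) the average- and max-pooled channel
#'   descriptors share one convolution stack.
#' @return a module usable with [masm_forward()] and friends.
#' @export
masm_module <- function(channels, reduction_ratio = 8L, kernel_set = c(7L, 11L, 21L),
                        shared_mlp = TRUE) {
  stopifnot(channels >= 1L, reduction_ratio >= 1L, all(kernel_set >= 1L))
  h <- max(1L, channels %/% reduction_ratio)
  m <- new_module("masm", cfg = list(channels = channels, hidden = h,
                                     kernel_set = as.integer(kernel_set),
                                     shared_mlp = shared_mlp))
  mk_stack <- function(tag) {
    add_child(m, paste0(tag, "1"), layer_conv(channels, h, 1, bias = TRUE, bn = FALSE, act = "relu"))
    add_child(m, paste0(tag, "2"), layer_conv(h, channels, 1, bias = TRUE, bn = FALSE, act = "none"))
  }
  mk_stack("ca")
  if (!shared_mlp) mk_stack("cm")
  mk_stack("pa")
  add_child(m, "dw5", layer_conv(channels, channels, 5, groups = channels,
                                 bias = TRUE, bn = FALSE, act = "none"))
  for (K in kernel_set) {
    add_child(m, paste0("dwh", K), layer_conv(channels, channels, c(1L, K),
                                              groups = channels, bias = TRUE, bn = FALSE, act = "none"))
    add_child(m, paste0("dwv", K), layer_conv(channels, channels, c(K, 1L),
                                              groups = channels, bias = TRUE, bn = FALSE, act = "none"))
  }
  add_child(m, "mix", layer_conv(channels, channels, 1, bias = FALSE, bn = FALSE, act = "none"))
  m
}

check_masm_channels <- function(x, masm) {
  cx <- shape_of(x)[1]
  if (cx != masm$cfg$channels)
    stop("feature map has ", cx, " channels but the attention module expects ",
         masm$cfg$channels, call. = FALSE)
}

#' Channel attention weights
#'
#' Average- and max-pooled channel descriptors are passed through a two-layer
#' 1x1 convolution stack (ReLU between), summed, and squashed by a sigmoid,
#' yielding one weight in (0, 1) per channel.
#'
#' @param x feature map, a numeric array with dim `c(C, H, W)`.
#' @param masm a module from [masm_module()].
#' @return array with dim `c(C, 1, 1)` of per-channel weights.
#' @export
channel_attention <- function(x, masm) {
  check_masm_channels(x, masm)
  ch <- masm$children
  stack_a <- function(z) ud_fwd(ch$ca2, ud_fwd(ch$ca1, z))
  stack_m <- if (masm$cfg$shared_mlp) stack_a else function(z) ud_fwd(ch$cm2, ud_fwd(ch$cm1, z))
  fa <- stack_a(op_gap(x))
  fm <- stack_m(op_gmp(x))
  op_sigmoid(op_add(fa, fm))
}

#' Pixel attention
#'
#' Applies a per-position sigmoid gate, computed by two 1x1 convolutions with
#' a ReLU between, to the channel-weighted feature map.
#'
#' @param x_weighted the channel-weighted feature map.
#' @inheritParams channel_attention
#' @return feature map of the same shape.
#' @export
pixel_attention <- function(x_weighted, masm) {
  check_masm_channels(x_weighted, masm)
  ch <- masm$children
  gate <- op_sigmoid(ud_fwd(ch$pa2, ud_fwd(ch$pa1, x_weighted)))
  op_mul(x_weighted, gate)
}

#' Multi-kernel spatial attention
#'
#' A 5x5 depthwise base convolution followed, for each configured K, by a 1xK
#' and a Kx1 depthwise strip convolution; the strip outputs and the base are
#' summed and mixed by a pointwise convolution.
#'
#' @inheritParams pixel_attention
#' @return spatial attention map of the same shape as the input.
#' @export
spatial_attention <- function(x_weighted, masm) {
  check_masm_channels(x_weighted, masm)
  ch <- masm$children
  base <- ud_fwd(ch$dw5, x_weighted)
  s <- base
  for (K in masm$cfg$kernel_set) {
    strip <- ud_fwd(ch[[paste0("dwv", K)]], ud_fwd(ch[[paste0("dwh", K)]], base))
    s <- op_add(s, strip)
  }
  ud_fwd(ch$mix, s)
}

#' MASM forward pass
#'
#' Full synergy module: channel gating, then the elementwise product of the
#' pixel-attended map and the spatial attention map.
#'
#' @inheritParams channel_attention
#' @return enhanced feature map of the same shape.
#' @export
masm_forward <- function(x, masm) {
  xw <- op_mul(x, channel_attention(x, masm))
  op_mul(pixel_attention(xw, masm), spatial_attention(xw, masm))
}

ud_fwd.ud_masm <- function(mod, x, ...) masm_forward(x, mod)

#' Directional global average pooling
#'
#' Per channel: the mean of each row (pooling over width), the mean of each
#' column (pooling over height), and the global spatial mean.
#'
#' @param x feature map, dim `c(C, H, W)`.
#' @return list with `row_means` (C x H), `col_means` (C x W) and
#'   `global_mean` (length C).
#' @export
directional_means <- function(x) {
  stopifnot(length(dim(x)) == 3L)
  list(row_means = apply(x, c(1, 2), mean),
       col_means = apply(x, c(1, 3), mean),
       global_mean = apply(x, 1, mean))
}

#' Efficient multi-scale attention module
#'
#' Constructs the grouped EMA operator: channels are split into `groups`
#' sub-features; a 1x1 branch re-weights each group from its horizontal and
#' vertical 1-D pooled descriptors, a 3x3 branch extracts local features, and
#' cross-branch interaction (2-D global pooling, channel softmax and per-group
#' matrix products) produces a sigmoid-gated spatial map.
#'
#' @param channels number of channels; must be divisible by `groups` with at
#'   least two channels per group.
#' @param groups number of channel groups (default 8).
#' @export
ema_module <- function(channels, groups = 8L) {
  if (channels %% groups != 0L)
    stop("groups (", groups, ") must divide channels (", channels, ")", call. = FALSE)
  cg <- channels %/% groups
  if (cg < 2L)
    stop("EMA needs at least 2 channels per group; got ", cg, call. = FALSE)
  m <- new_module("ema", cfg = list(channels = channels, groups = groups, cg = cg))
  add_child(m, "conv1", layer_conv(cg, cg, 1, bias = TRUE, bn = FALSE, act = "none"))
  add_child(m, "conv3", layer_conv(cg, cg, 3, bias = TRUE, bn = FALSE, act = "none"))
  gn <- new_module("gn", cfg = list(c = cg))
  gn$params$gamma <- rep(1, cg)
  gn$params$beta <- rep(0, cg)
  add_child(m, "gn", gn)
  m
}

#' EMA forward pass
#'
#' @param x feature map, dim `c(C, H, W)` with C divisible by the module's
#'   group count.
#' @param ema a module from [ema_module()].
#' @return feature map of the same shape.
#' @export
ema_forward <- function(x, ema) {
  cf <- ema$cfg
  sx <- shape_of(x)
  if (sx[1] != cf$channels)
    stop("feature map has ", sx[1], " channels but EMA expects ", cf$channels, call. = FALSE)
  ch <- ema$children
  if (is_shape(x)) {
    for (g in seq_len(cf$groups)) {
      ud_fwd(ch$conv1, new_shape(c(cf$cg, sx[2], 1L)))
      ud_fwd(ch$conv1, new_shape(c(cf$cg, 1L, sx[3])))
      ud_fwd(ch$conv3, new_shape(c(cf$cg, sx[2], sx[3])))
    }
    return(x)
  }
  H <- sx[2]; W <- sx[3]; cg <- cf$cg
  outs <- vector("list", cf$groups)
  for (g in seq_len(cf$groups)) {
    xg <- op_slice_c(x, (g - 1L) * cg + 1L, cg)
    ## 1x1 branch: directional pooled descriptors, pointwise transform, gates
    gh <- ud_fwd(ch$conv1, op_pool_w(xg))          # (cg, H, 1)
    gw <- ud_fwd(ch$conv1, op_pool_h(xg))          # (cg, 1, W)
    x1 <- op_mul(op_mul(xg, op_sigmoid(gh)), op_sigmoid(gw))
    gnm <- ch$gn
    x1 <- op_channelnorm(x1, pnode(gnm, "gamma"), pnode(gnm, "beta"))
    ## 3x3 branch
    x2 <- ud_fwd(ch$conv3, xg)
    ## cross-branch interaction
    t1 <- op_softmax_rows(op_reshape(op_gap(x1), c(1L, cg)))
    t2 <- op_softmax_rows(op_reshape(op_gap(x2), c(1L, cg)))
    m1 <- op_reshape(x1, c(cg, H * W))
    m2 <- op_reshape(x2, c(cg, H * W))
    wmap <- op_sigmoid(op_add(op_matmul(t1, m2), op_matmul(t2, m1)))
    outs[[g]] <- op_mul(xg, op_reshape(wmap, c(1L, H, W)))
  }
  op_concat(outs)
}

ud_fwd.ud_ema <- function(mod, x, ...) ema_forward(x, mod)
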