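## Feature-fusion necks.
##
## The base neck is the inherited FPN+PAN: top-down concatenation then a
## bottom-up path, one block per merge point. The improved neck is a single
## bidirectional weighted-fusion round: learnable non-negative per-edge
## weights (fast normalized fusion), P2 integrated on the bottom-up P3 node,
## single-input nodes removed, and skip connections from the original inputs
## to the output nodes.

#' Learnable-weight feature fusion
#'
#' Computes `O = sum(w_i I_i) / (eps + sum(w_i))` with weights clamped at zero
#' before use. All-zero weights yield a zero map (the epsilon guard), not an
#' error.
#'
#' @param inputs list of equally shaped numeric arrays.
#' @param weights numeric vector, one per input.
#' @param eps stabilizing constant, default 1e-4.
#' @return fused array of the common input shape.
#' @export
weighted_fuse <- function(inputs, weights, eps = 1e-4) {
  stopifnot(length(inputs) >= 1L, length(inputs) == length(weights))
  d <- dim(inputs[[1]])
  for (x in inputs) {
    if (!identical(dim(x), d)) stop("weighted_fuse inputs must share one shape", call. = FALSE)
  }
  op_wfuse(inputs, weights, eps)
}

#' Resample a feature map across pyramid levels
#'
#' `up` doubles height and width by nearest-neighbour; `down` halves them by
#' 2x2 average pooling with ceiling division. An optional 1x1 convolution
#' module (`align`, e.g. from `build_cbs(c_in, c_out, k = 1)`) adjusts the
#' channel count.
#'
#' @param x feature map `(C, H, W)`.
#' @param direction `"up"` or `"down"`.
#' @param align optional channel-aligning convolution module.
#' @export
resample <- function(x, direction = c("up", "down"), align = NULL) {
  direction <- match.arg(direction)
  if (!is.null(align)) x <- ud_fwd(align, x)
  if (direction == "up") return(op_upsample2(x))
  d <- dim(vv(x))
  ho <- ceiling(d[2] / 2); wo <- ceiling(d[3] / 2)
  ## ceil-division average pool via padded 2x2 mean
  y <- vv(x)
  out <- array(0, c(d[1], ho, wo))
  for (i in seq_len(ho)) for (j in seq_len(wo)) {
    hs <- (2 * i - 1):min(2 * i, d[2]); ws <- (2 * j - 1):min(2 * j, d[3])
    out[, i, j] <- apply(y[, hs, ws, drop = FALSE], 1, mean)
  }
  out
}

## Base FPN+PAN neck. ch = c(p2, p3, p4, p5) widths; the p2 entry is unused
## here but kept so both necks share a signature.
build_neck_fpnpan <- function(ch, masm = NULL, ema_sites = character(), ema_groups = 8L) {
  p3 <- ch[2]; p4 <- ch[3]; p5 <- ch[4]
  m <- new_module("neck_fpnpan", cfg = list(ch = ch))
  add_child(m, "td_p4", build_c2f(p4 + p5, p4, 1L, FALSE, masm))
  add_child(m, "td_p3", build_c2f(p3 + p4, p3, 1L, FALSE, masm))
  if ("neck_p3" %in% ema_sites) add_child(m, "ema_p3", ema_module(p3, ema_groups))
  add_child(m, "down_p3", build_cbs(p3, p3, 3L, 2L))
  add_child(m, "bu_p4", build_c2f(p3 + p4, p4, 1L, FALSE, masm))
  if ("neck_p4" %in% ema_sites) add_child(m, "ema_p4", ema_module(p4, ema_groups))
  add_child(m, "down_p4", build_scdown(p4, p4))
  add_child(m, "bu_p5", build_c2fcib(p4 + p5, p5, 1L, TRUE))
  m
}

ud_fwd.ud_neck_fpnpan <- function(mod, x, ...) {
  ch <- mod$children
  p3 <- x$p3; p4 <- x$p4; p5 <- x$p5
  t4 <- ud_fwd(ch$td_p4, op_concat(list(op_upsample2(p5), p4)))
  t3 <- ud_fwd(ch$td_p3, op_concat(list(op_upsample2(t4), p3)))
  if (!is.null(ch$ema_p3)) t3 <- ema_forward(t3, ch$ema_p3)
  b4 <- ud_fwd(ch$bu_p4, op_concat(list(ud_fwd(ch$down_p3, t3), t4)))
  if (!is.null(ch$ema_p4)) b4 <- ema_forward(b4, ch$ema_p4)
  b5 <- ud_fwd(ch$bu_p5, op_concat(list(ud_fwd(ch$down_p4, b4), p5)))
  list(p3 = t3, p4 = b4, p5 = b5)
}

## Improved bidirectional neck (single round).
## Nodes (topological order): P4td, P3td, P3out, P4out, P5out.
build_neck_bifpn <- function(ch, masm = NULL, ema_sites = character(), ema_groups = 8L,
                             eps = 1e-4) {
  p2 <- ch[1]; p3 <- ch[2]; p4 <- ch[3]; p5 <- ch[4]
  m <- new_module("neck_bifpn", cfg = list(ch = ch))
  ## top-down
  add_child(m, "a_p5", build_cbs(p5, p4, 1L, 1L))          # align before upsample
  add_child(m, "f_p4td", layer_wfuse(2L, eps))
  add_child(m, "blk_p4td", build_c2f(p4, p4, 1L, FALSE, masm))
  add_child(m, "a_p4td", build_cbs(p4, p3, 1L, 1L))
  add_child(m, "f_p3td", layer_wfuse(2L, eps))             # fusion-only node
  ## bottom-up
  add_child(m, "d_p2a", layer_conv(p2, p2, 3L, stride = 2L, groups = p2, act = "none"))
  add_child(m, "d_p2b", build_cbs(p2, p3, 1L, 1L))
  add_child(m, "skip_p3", build_cbs(p3, p3, 1L, 1L))
  add_child(m, "f_p3out", layer_wfuse(3L, eps))
  add_child(m, "blk_p3out", build_c2f(p3, p3, 1L, FALSE, masm))
  if ("neck_p3" %in% ema_sites) add_child(m, "ema_p3", ema_module(p3, ema_groups))
  add_child(m, "d_p3a", layer_conv(p3, p3, 3L, stride = 2L, groups = p3, act = "none"))
  add_child(m, "d_p3b", build_cbs(p3, p4, 1L, 1L))
  add_child(m, "skip_p4", build_cbs(p4, p4, 1L, 1L))
  add_child(m, "f_p4out", layer_wfuse(3L, eps))
  add_child(m, "blk_p4out", build_c2f(p4, p4, 1L, FALSE, masm))
  if ("neck_p4" %in% ema_sites) add_child(m, "ema_p4", ema_module(p4, ema_groups))
  add_child(m, "d_p4a", build_cbs(p4, p5, 1L, 1L))
  add_child(m, "d_p4b", layer_conv(p5, p5, 3L, stride = 2L, groups = p5, act = "none"))
  add_child(m, "f_p5out", layer_wfuse(2L, eps))
  m$state$graph <- neck_graph_table()
  m
}

ud_fwd.ud_neck_bifpn <- function(mod, x, ...) {
  ch <- mod$children
  p2 <- x$p2; p3 <- x$p3; p4 <- x$p4; p5 <- x$p5
  t4 <- ud_fwd(ch$f_p4td, list(p4, op_upsample2(ud_fwd(ch$a_p5, p5))))
  t4 <- ud_fwd(ch$blk_p4td, t4)
  t3 <- ud_fwd(ch$f_p3td, list(p3, op_upsample2(ud_fwd(ch$a_p4td, t4))))
  p2d <- ud_fwd(ch$d_p2b, ud_fwd(ch$d_p2a, p2))
  o3 <- ud_fwd(ch$f_p3out, list(ud_fwd(ch$skip_p3, p3), t3, p2d))
  o3 <- ud_fwd(ch$blk_p3out, o3)
  if (!is.null(ch$ema_p3)) o3 <- ema_forward(o3, ch$ema_p3)
  o3d <- ud_fwd(ch$d_p3b, ud_fwd(ch$d_p3a, o3))
  o4 <- ud_fwd(ch$f_p4out, list(ud_fwd(ch$skip_p4, p4), t4, o3d))
  o4 <- ud_fwd(ch$blk_p4out, o4)
  if (!is.null(ch$ema_p4)) o4 <- ema_forward(o4, ch$ema_p4)
  o4d <- ud_fwd(ch$d_p4b, ud_fwd(ch$d_p4a, o4))
  o5 <- ud_fwd(ch$f_p5out, list(p5, o4d))
  list(p3 = o3, p4 = o4, p5 = o5)
}

## Static description of the bidirectional fusion graph, used for validation
## and introspection.
neck_graph_table <- function() {
  tibble::tibble(
    node = c("P4td", "P3td", "P3out", "P4out", "P5out"),
    inputs = list(c("P4", "P5"),
                  c("P3", "P4td"),
                  c("P3", "P3td", "P2"),
                  c("P4", "P4td", "P3out"),
                  c("P5", "P4out")),
    level = c("P4", "P3", "P3", "P4", "P5"))
}

#' Fusion-graph description of the bidirectional neck
#'
#' Returns one row per fusion node with its input edges and pyramid level.
#' The graph is validated to be acyclic (inputs reference only raw pyramid
#' levels or earlier nodes) and free of single-input nodes.
#'
#' @param neck a neck module built with the bidirectional topology (for the
#'   default `NULL`, the static topology is returned).
#' @return a tibble with columns `node`, `inputs`, `level`.
#' @export
neck_graph <- function(neck = NULL) {
  g <- if (is.null(neck)) neck_graph_table() else neck$state$graph
  seen <- c("P2", "P3", "P4", "P5")
  for (i in seq_len(nrow(g))) {
    ins <- g$inputs[[i]]
    if (length(ins) < 2L) stop("single-input fusion node: ", g$node[i], call. = FALSE)
    if (!all(ins %in% seen)) stop("cycle or forward reference at node ", g$node[i], call. = FALSE)
    seen <- c(seen, g$node[i])
  }
  g
}
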