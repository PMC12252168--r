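## Reverse-mode tape engine.
##
## A tensor is one of:
##   * a plain numeric array with dim c(C, H, W) -- evaluation mode,
##   * a `ud_node` environment on the active tape -- training mode,
##   * a `ud_shape` token carrying only dim -- structural profiling mode,
##     during which conv-type ops add their multiply-accumulate counts to a
##     global counter and everything else just propagates shapes.

the <- new.env(parent = emptyenv())
the$tape <- NULL
the$pnodes <- NULL
the$macs <- 0
the$module_id <- 0L

is_nd <- function(x) inherits(x, "ud_node")
is_shape <- function(x) inherits(x, "ud_shape")
vv <- function(x) if (is_nd(x)) x$value else x

shape_of <- function(x) if (is_shape(x)) x$shape else dim(vv(x))

new_shape <- function(shp) structure(list(shape = as.integer(shp)), class = "ud_shape")

tape_active <- function() !is.null(the$tape)

tape_start <- function() {
  the$tape <- vector("list", 512L)
  the$tape_n <- 0L
  the$pnodes <- new.env(parent = emptyenv())
  invisible(NULL)
}

tape_stop <- function() {
  the$tape <- NULL
  the$pnodes <- NULL
  invisible(NULL)
}

tape_push <- function(e) {
  n <- the$tape_n + 1L
  if (n > length(the$tape)) the$tape <- c(the$tape, vector("list", length(the$tape)))
  the$tape[[n]] <- e
  the$tape_n <- n
  e
}

## Create a tape node. `bw` maps the output gradient to a list of gradients,
## one per entry of `parents` (non-node parents receive NULL).
nd <- function(value, parents, bw) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$parents <- parents
  e$bw <- bw
  e$grad <- NULL
  class(e) <- "ud_node"
  tape_push(e)
}

nd_leaf <- function(value) nd(value, list(), NULL)

## Parameter node for `name` in module `mod`, cached for the current tape so
## each parameter appears once per step no matter how often it is read.
pnode <- function(mod, name) {
  if (!tape_active()) return(mod$params[[name]])
  key <- paste0(mod$id, ".", name)
  e <- the$pnodes[[key]]
  if (is.null(e)) {
    e <- nd_leaf(mod$params[[name]])
    e$owner <- mod
    e$pname <- name
    the$pnodes[[key]] <- e
  }
  e
}

acc_grad <- function(node, g) {
  if (!is_nd(node) || is.null(g)) return(invisible(NULL))
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

## Run reverse sweep from a scalar loss node; afterwards leaf parameter
## gradients are available in the$pnodes.
backward <- function(loss) {
  stopifnot(is_nd(loss))
  loss$grad <- 1
  for (i in seq(the$tape_n, 1L)) {
    e <- the$tape[[i]]
    if (is.null(e$grad) || is.null(e$bw)) next
    gs <- e$bw(e$grad)
    for (j in seq_along(e$parents)) acc_grad(e$parents[[j]], gs[[j]])
    e$grad <- NULL  # free
  }
  invisible(NULL)
}

## Collect (module, name, grad) triples accumulated on the current tape.
collected_grads <- function() {
  out <- list()
  for (key in ls(the$pnodes)) {
    e <- the$pnodes[[key]]
    if (!is.null(e$grad)) out[[key]] <- list(mod = e$owner, name = e$pname, grad = e$grad)
  }
  out
}
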