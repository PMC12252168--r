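## Module protocol: a module is an environment with
##   id       unique integer (assigned at construction)
##   kind     character tag, also its S3 class (plus "ud_module")
##   params   named list of learnable arrays owned directly
##   children named list of sub-modules
##   state    mutable non-learnable state
##   cfg      constructor arguments needed by the forward pass
## Forward passes go through ud_fwd(), an S3 generic on the module class.

new_module <- function(kind, cfg = list()) {
  e <- new.env(parent = emptyenv())
  the$module_id <- the$module_id + 1L
  e$id <- the$module_id
  e$kind <- kind
  e$params <- list()
  e$children <- list()
  e$state <- list()
  e$cfg <- cfg
  class(e) <- c(paste0("ud_", kind), "ud_module")
  e
}

add_child <- function(mod, name, child) {
  mod$children[[name]] <- child
  child
}

ud_fwd <- function(mod, x, ...) UseMethod("ud_fwd")

kaiming_mat <- function(nrow, ncol, fan_in) {
  b <- sqrt(1 / fan_in)
  matrix(stats::runif(nrow * ncol, -b, b), nrow, ncol)
}

## Convolution layer, optionally followed by batch norm and an activation.
## k may be a single size or c(kh, kw); padding is always "same" for stride 1
## and the conventional k %/% 2 for stride 2.
layer_conv <- function(c1, c2, k = 1L, stride = 1L, groups = 1L,
                       bias = !bn, bn = TRUE, act = c("silu", "relu", "none")) {
  act <- match.arg(act)
  if (length(k) == 1L) k <- c(k, k)
  stopifnot(c1 %% groups == 0L, c2 %% groups == 0L)
  m <- new_module("conv", cfg = list(
    c1 = c1, c2 = c2, kh = k[1], kw = k[2], stride = stride, groups = groups,
    ph = k[1] %/% 2L, pw = k[2] %/% 2L, bias = bias, bn = bn, act = act))
  fan_in <- (c1 / groups) * k[1] * k[2]
  m$params$w <- kaiming_mat(c2, fan_in, fan_in)
  if (bias) m$params$b <- stats::runif(c2, -sqrt(1 / fan_in), sqrt(1 / fan_in))
  if (bn) {
    m$params$gamma <- rep(1, c2)
    m$params$beta <- rep(0, c2)
  }
  m
}

ud_fwd.ud_conv <- function(mod, x, ...) {
  cf <- mod$cfg
  b <- if (cf$bias) pnode(mod, "b") else NULL
  y <- op_conv(x, pnode(mod, "w"), b, cf$kh, cf$kw, cf$stride, cf$ph, cf$pw, cf$groups)
  ## batch size is always 1 in this engine, so the normalization layers act
  ## as instance norm: per-map statistics both during training and inference
  if (cf$bn) y <- op_bn(y, pnode(mod, "gamma"), pnode(mod, "beta"), NULL, NULL)
  switch(cf$act, silu = op_silu(y), relu = op_relu(y), none = y)
}

## Learnable weighted fusion (fast normalized fusion): weights are clamped at
## zero before use and the sum is stabilized by a small epsilon.
layer_wfuse <- function(n_inputs, eps = 1e-4) {
  m <- new_module("wfuse", cfg = list(n = n_inputs, eps = eps))
  m$params$w <- rep(1, n_inputs)
  m
}

ud_fwd.ud_wfuse <- function(mod, x, ...) {
  op_wfuse(x, pnode(mod, "w"), mod$cfg$eps)
}

## x: list of same-shape maps; w: weight vector (node or numeric).
op_wfuse <- function(xs, w, eps = 1e-4) {
  if (is_shape(xs[[1]])) return(xs[[1]])
  wv <- vv(w)
  ws <- pmax(wv, 0)
  s <- eps + sum(ws)
  num <- 0
  for (i in seq_along(xs)) num <- num + ws[i] * vv(xs[[i]])
  y <- num / s
  if (!any(vapply(xs, is_nd, TRUE)) && !is_nd(w)) return(y)
  nd(y, c(xs, list(w)), function(g) {
    gs <- lapply(seq_along(xs), function(i) g * (ws[i] / s))
    gw <- vapply(seq_along(xs), function(i) {
      if (wv[i] <= 0) return(0)
      sum(g * (vv(xs[[i]]) * s - num)) / s^2
    }, 1)
    c(gs, list(gw))
  })
}

## Tree utilities ------------------------------------------------------------

walk_modules <- function(mod, fn, path = "model") {
  fn(mod, path)
  for (nm in names(mod$children)) walk_modules(mod$children[[nm]], fn, paste(path, nm, sep = "/"))
  invisible(NULL)
}

## Flat list of (module, param name) handles, deterministic order.
param_handles <- function(mod) {
  out <- list()
  walk_modules(mod, function(m, path) {
    for (nm in names(m$params)) out[[length(out) + 1L]] <<- list(mod = m, name = nm, path = path)
  })
  out
}

n_params <- function(mod) {
  tot <- 0
  walk_modules(mod, function(m, path) {
    for (p in m$params) tot <<- tot + length(p)
  })
  tot + (mod$state$extra_params %||% 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a module's forward pass
#'
#' Applies any built module (a block from [build_cbs()] and friends, an
#' attention module, a neck, or a whole model) to a feature map or, for
#' fusion layers, a list of feature maps.
#'
#' @param module a module.
#' @param x numeric array `(C, H, W)` (or list of arrays for fusion nodes).
#' @return the module output.
#' @export
block_forward <- function(module, x) ud_fwd(module, x)
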