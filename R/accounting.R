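## Structural accounting: learnable parameter counts and FLOPs.
##
## Parameters follow the training-time convention: both head branches, unfused
## batch-norm affine pairs, fusion weights, attention internals, and the fixed
## integration kernel of the DFL decode. FLOPs are 2 x multiply-accumulates
## summed over convolution layers at batch 1 (the dialect of the established
## profilers used for this model family: pooling, activations, normalization
## and raw attention matrix products are not counted).

round_half_up <- function(x, digits) floor(x * 10^digits + 0.5) / 10^digits

#' Count learnable parameters
#'
#' Walks the module tree and sums the lengths of every learnable array.
#'
#' @param model a module (typically from [build_model()]).
#' @return an object of class `ud_param_report`: a list with `total`,
#'   `millions` (half-up, 2 decimals) and `per_module`, a tibble breakdown by
#'   top-level component.
#' @export
count_parameters <- function(model) {
  rows <- list()
  walk_modules(model, function(m, path) {
    n <- sum(vapply(m$params, length, 1L))
    if (n > 0L) rows[[length(rows) + 1L]] <<- tibble::tibble(path = path, n = n)
  })
  per <- dplyr::bind_rows(rows)
  extra <- model$state$extra_params %||% 0
  if (extra > 0) per <- dplyr::bind_rows(per, tibble::tibble(path = "model/dfl", n = as.integer(extra)))
  total <- sum(per$n)
  structure(list(total = total,
                 millions = round_half_up(total / 1e6, 2),
                 per_module = per),
            class = "ud_param_report")
}

#' @export
print.ud_param_report <- function(x, ...) {
  cat(sprintf("parameters: %d (%.2f M) across %d parameterized modules\n",
              x$total, x$millions, nrow(x$per_module)))
  invisible(x)
}

#' Compute forward-pass FLOPs
#'
#' Propagates shape tokens through the full training-time graph (both head
#' branches) and accumulates convolution multiply-accumulates; FLOPs are
#' 2 x MACs.
#'
#' @param model a built model, or any module when `input_shape` is given.
#' @param input_size square input side, divisible by 32; defaults to the
#'   model's configured size.
#' @param input_shape alternatively, an explicit `c(C, H, W)` input shape;
#'   allows profiling a single block instead of a whole model.
#' @return object of class `ud_flops_report` with `total_flops`, `gflops`
#'   (half-up, 1 decimal) and `input_size`.
#' @export
compute_flops <- function(model, input_size = NULL, input_shape = NULL) {
  if (is.null(input_shape)) {
    input_size <- as.integer(input_size %||% model$cfg$input_size)
    if (input_size %% 32L != 0L) stop("input_size must be divisible by 32", call. = FALSE)
    input_shape <- c(3L, input_size, input_size)
  } else {
    input_size <- as.integer(input_shape[2])
  }
  the$macs <- 0
  invisible(ud_fwd(model, new_shape(as.integer(input_shape))))
  fl <- 2 * the$macs
  structure(list(input_size = input_size, total_flops = fl,
                 gflops = round_half_up(fl / 1e9, 1)),
            class = "ud_flops_report")
}

#' @export
print.ud_flops_report <- function(x, ...) {
  cat(sprintf("FLOPs at %dx%d: %.0f (%.1f G)\n", x$input_size, x$input_size,
              x$total_flops, x$gflops))
  invisible(x)
}

#' Structural accounting table across variants
#'
#' Builds each requested variant and reports parameters and GFLOPs, the
#' ablation-table view of the architecture family.
#'
#' @param variants character vector of variant names.
#' @param input_size square input side for the FLOPs column.
#' @param seed weight-initialization seed (counts do not depend on it).
#' @param cfg_fn optional function(variant) returning a [model_config()];
#'   defaults to the calibrated default configuration.
#' @return tibble with `variant`, `params`, `params_m`, `gflops`.
#' @export
variant_table <- function(variants = VARIANTS, input_size = 640L, seed = 0L,
                          cfg_fn = NULL) {
  cfg_fn <- cfg_fn %||% function(v) model_config(variant = v, input_size = input_size)
  purrr::map_dfr(variants, function(v) {
    m <- build_model(cfg_fn(v), seed = seed)
    p <- count_parameters(m)
    f <- compute_flops(m, input_size)
    tibble::tibble(variant = v, params = p$total, params_m = p$millions,
                   gflops = f$gflops)
  })
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.ud_param_report <- function(x, ...) x$per_module

#' @export
glance.ud_param_report <- function(x, ...) {
  tibble::tibble(total = x$total, millions = x$millions)
}

#' @export
tidy.ud_flops_report <- function(x, ...) {
  tibble::tibble(input_size = x$input_size, total_flops = x$total_flops,
                 gflops = x$gflops)
}

#' @export
glance.ud_flops_report <- function(x, ...) tidy.ud_flops_report(x, ...)
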