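## Assembly of the eight architecture variants: backbone (with optional EMA
## insertions), base or bidirectional neck (optionally with MASM-augmented
## C2f blocks), and the dual detection head (one-to-many branch used during
## training, one-to-one branch decoded NMS-free at inference).

VARIANTS <- c("baseline", "B", "S", "E", "BS", "BE", "SE", "BSE")

#' Parse an architecture variant name
#'
#' The eight named configurations map bijectively onto the three feature
#' flags: `B` = bidirectional weighted neck, `S` = MASM-augmented neck C2f
#' blocks (S_C2f), `E` = efficient multi-scale attention insertions.
#'
#' @param name one of `"baseline"`, `"B"`, `"S"`, `"E"`, `"BS"`, `"BE"`,
#'   `"SE"`, `"BSE"`.
#' @return list with `name`, `use_bifpn`, `use_sc2f`, `use_ema`.
#' @export
parse_variant <- function(name) {
  name <- match.arg(name, VARIANTS)
  list(name = name,
       use_bifpn = grepl("B", name),
       use_sc2f = grepl("S", name),
       use_ema = grepl("E", name))
}

#' Model configuration
#'
#' @param variant variant name, see [parse_variant()].
#' @param num_classes number of object classes (default 4: holothurian,
#'   echinus, scallop, starfish).
#' @param input_size square input side in pixels, divisible by 32.
#' @param channels channel plan at strides 2/4/8/16/32 (P1..P5).
#' @param depths bottleneck counts of the four backbone C2f stages.
#' @param reg_max number of distribution bins of the box regression head.
#' @param ema_groups channel groups of each EMA module.
#' @param ema_sites where EMA modules are inserted when the `E` flag is on.
#' @param masm_reduction hidden-width divisor of the MASM gating stacks.
#' @param masm_kernels strip kernel set of the MASM spatial branch.
#' @return a config list consumed by [build_model()].
#' @export
model_config <- function(variant = "BSE", num_classes = 4L, input_size = 640L,
                         channels = c(16L, 32L, 64L, 128L, 256L),
                         depths = c(1L, 2L, 2L, 1L), reg_max = 16L,
                         ema_groups = 8L,
                         ema_sites = c("backbone_p2", "backbone_p3", "neck_p3", "neck_p4"),
                         masm_reduction = 8L, masm_kernels = c(7L, 11L, 21L)) {
  if (input_size %% 32L != 0L) stop("input_size must be divisible by 32", call. = FALSE)
  stopifnot(length(channels) == 5L, length(depths) == 4L, num_classes >= 1L)
  list(variant = parse_variant(variant), num_classes = as.integer(num_classes),
       input_size = as.integer(input_size), channels = as.integer(channels),
       depths = as.integer(depths), reg_max = as.integer(reg_max),
       ema_groups = as.integer(ema_groups), ema_sites = ema_sites,
       masm = list(reduction_ratio = as.integer(masm_reduction),
                   kernel_set = as.integer(masm_kernels)))
}

build_backbone <- function(cfg) {
  ch <- cfg$channels; d <- cfg$depths
  ema <- cfg$variant$use_ema
  m <- new_module("backbone", cfg = list(ch = ch))
  add_child(m, "stem1", build_cbs(3L, ch[1], 3L, 2L))
  add_child(m, "stem2", build_cbs(ch[1], ch[2], 3L, 2L))
  add_child(m, "c2f_p2", build_c2f(ch[2], ch[2], d[1], TRUE))
  if (ema && "backbone_p2" %in% cfg$ema_sites) add_child(m, "ema_p2", ema_module(ch[2], cfg$ema_groups))
  add_child(m, "cbs_p3", build_cbs(ch[2], ch[3], 3L, 2L))
  add_child(m, "c2f_p3", build_c2f(ch[3], ch[3], d[2], TRUE))
  if (ema && "backbone_p3" %in% cfg$ema_sites) add_child(m, "ema_p3", ema_module(ch[3], cfg$ema_groups))
  add_child(m, "sc_p4", build_scdown(ch[3], ch[4]))
  add_child(m, "c2f_p4", build_c2f(ch[4], ch[4], d[3], TRUE))
  add_child(m, "sc_p5", build_scdown(ch[4], ch[5]))
  add_child(m, "c2f_p5", build_c2f(ch[5], ch[5], d[4], TRUE))
  add_child(m, "sppf", build_sppf(ch[5], ch[5]))
  add_child(m, "psa", build_psa(ch[5]))
  m
}

ud_fwd.ud_backbone <- function(mod, x, ...) {
  ch <- mod$children
  y <- ud_fwd(ch$stem2, ud_fwd(ch$stem1, x))
  p2 <- ud_fwd(ch$c2f_p2, y)
  if (!is.null(ch$ema_p2)) p2 <- ema_forward(p2, ch$ema_p2)
  p3 <- ud_fwd(ch$c2f_p3, ud_fwd(ch$cbs_p3, p2))
  if (!is.null(ch$ema_p3)) p3 <- ema_forward(p3, ch$ema_p3)
  p4 <- ud_fwd(ch$c2f_p4, ud_fwd(ch$sc_p4, p3))
  p5 <- ud_fwd(ch$c2f_p5, ud_fwd(ch$sc_p5, p4))
  p5 <- ud_fwd(ch$psa, ud_fwd(ch$sppf, p5))
  list(p2 = p2, p3 = p3, p4 = p4, p5 = p5)
}

build_head <- function(cfg) {
  ch <- cfg$channels[3:5]
  nc <- cfg$num_classes
  rm <- cfg$reg_max
  cbox <- max(16L, ch[1] %/% 4L, 4L * rm)
  ccls <- max(ch[1], min(nc, 100L))
  m <- new_module("head", cfg = list(ch = ch, nc = nc, reg_max = rm,
                                     cbox = cbox, ccls = ccls, strides = c(8L, 16L, 32L)))
  for (br in c("o2m", "o2o")) for (i in 1:3) {
    x <- ch[i]; p <- paste0(br, "_p", i + 2L, "_")
    add_child(m, paste0(p, "box1"), build_cbs(x, cbox, 3L))
    add_child(m, paste0(p, "box2"), build_cbs(cbox, cbox, 3L))
    add_child(m, paste0(p, "box3"), layer_conv(cbox, 4L * rm, 1, bias = TRUE, bn = FALSE, act = "none"))
    add_child(m, paste0(p, "cls1"), layer_conv(x, x, 3, groups = x, act = "silu"))
    add_child(m, paste0(p, "cls2"), build_cbs(x, ccls, 1L))
    add_child(m, paste0(p, "cls3"), layer_conv(ccls, ccls, 3, groups = ccls, act = "silu"))
    add_child(m, paste0(p, "cls4"), build_cbs(ccls, ccls, 1L))
    add_child(m, paste0(p, "cls5"), layer_conv(ccls, nc, 1, bias = TRUE, bn = FALSE, act = "none"))
  }
  m
}

head_branch_fwd <- function(mod, feats, branch) {
  ch <- mod$children
  lapply(1:3, function(i) {
    x <- feats[[i]]
    p <- paste0(branch, "_p", i + 2L, "_")
    box <- ud_fwd(ch[[paste0(p, "box3")]],
                  ud_fwd(ch[[paste0(p, "box2")]], ud_fwd(ch[[paste0(p, "box1")]], x)))
    z <- ud_fwd(ch[[paste0(p, "cls2")]], ud_fwd(ch[[paste0(p, "cls1")]], x))
    z <- ud_fwd(ch[[paste0(p, "cls4")]], ud_fwd(ch[[paste0(p, "cls3")]], z))
    cls <- ud_fwd(ch[[paste0(p, "cls5")]], z)
    list(box = box, cls = cls)
  })
}

ud_fwd.ud_head <- function(mod, x, ...) {
  both <- tape_active() || is_shape(x[[1]])
  out <- list(o2o = head_branch_fwd(mod, x, "o2o"))
  if (both) out$o2m <- head_branch_fwd(mod, x, "o2m")
  out
}

#' Build a detection model
#'
#' Assembles backbone, neck and dual head according to the configuration's
#' variant flags. Weight initialization is deterministic given `seed`.
#'
#' @param cfg configuration from [model_config()]; a variant name is also
#'   accepted.
#' @param seed integer seed for weight initialization.
#' @return a model module.
#' @export
build_model <- function(cfg = model_config(), seed = 0L) {
  if (is.character(cfg)) cfg <- model_config(variant = cfg)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  v <- cfg$variant
  masm <- if (v$use_sc2f) cfg$masm else NULL
  ema_sites <- if (v$use_ema) cfg$ema_sites else character()
  m <- new_module("model", cfg = cfg)
  add_child(m, "backbone", build_backbone(cfg))
  ch4 <- cfg$channels[2:5]
  neck <- if (v$use_bifpn) {
    build_neck_bifpn(ch4, masm, ema_sites, cfg$ema_groups)
  } else {
    build_neck_fpnpan(ch4, masm, ema_sites, cfg$ema_groups)
  }
  add_child(m, "neck", neck)
  add_child(m, "head", build_head(cfg))
  m$state$extra_params <- cfg$reg_max  # fixed integration kernel of the DFL decode
  m
}

ud_fwd.ud_model <- function(mod, x, ...) {
  feats <- ud_fwd(mod$children$backbone, x)
  fused <- ud_fwd(mod$children$neck, feats)
  ud_fwd(mod$children$head, list(fused$p3, fused$p4, fused$p5))
}

#' Census of structural components
#'
#' Counts instances of the characteristic modules in a built model; useful
#' for structural diffs between variants.
#'
#' @param model a model module.
#' @return tibble with one row per module kind and its instance count.
#' @export
module_census <- function(model) {
  counts <- c(masm = 0L, ema = 0L, wfuse = 0L, c2f = 0L, sc2f = 0L, cib = 0L, conv = 0L)
  walk_modules(model, function(m, path) {
    k <- m$kind
    if (k == "c2f" && isTRUE(m$cfg$sc2f)) k <- "sc2f"
    if (k %in% names(counts)) counts[k] <<- counts[k] + 1L
  })
  tibble::tibble(kind = names(counts), n = as.integer(counts))
}

## Image plumbing ------------------------------------------------------------

## Bilinear resize of a (C,H,W) array.
resize_bilinear <- function(img, ho, wo) {
  d <- dim(img)
  sy <- d[2] / ho; sx <- d[3] / wo
  ys <- pmin(pmax((seq_len(ho) - 0.5) * sy + 0.5, 1), d[2])
  xs <- pmin(pmax((seq_len(wo) - 0.5) * sx + 0.5, 1), d[3])
  y0 <- pmin(floor(ys), d[2] - 1); x0 <- pmin(floor(xs), d[3] - 1)
  wy <- ys - y0; wx <- xs - x0
  a <- img[, y0, x0, drop = FALSE]; b <- img[, y0 + 1, x0, drop = FALSE]
  cc <- img[, y0, x0 + 1, drop = FALSE]; dd <- img[, y0 + 1, x0 + 1, drop = FALSE]
  wyA <- array(rep(rep(1 - wy, each = d[1]), length(xs)), c(d[1], ho, wo))
  wxA <- array(rep(1 - wx, each = d[1] * ho), c(d[1], ho, wo))
  a * wyA * wxA + b * (1 - wyA) * wxA + cc * wyA * (1 - wxA) + dd * (1 - wyA) * (1 - wxA)
}

#' Letterbox an image to the model input size
#'
#' Aspect-preserving bilinear resize onto a square canvas padded with the
#' conventional grey value 114/255.
#'
#' @param img numeric array `(3, H, W)` with values in `[0, 1]`.
#' @param size target square side.
#' @return list with the padded `image`, the `scale` applied and the `pad`
#'   offsets `c(top, left)` needed to invert the mapping.
#' @export
letterbox <- function(img, size) {
  d <- dim(img)
  r <- min(size / d[2], size / d[3])
  ho <- max(1L, round(d[2] * r)); wo <- max(1L, round(d[3] * r))
  resized <- if (ho == d[2] && wo == d[3]) img else resize_bilinear(img, ho, wo)
  out <- array(114 / 255, c(d[1], size, size))
  top <- (size - ho) %/% 2L; left <- (size - wo) %/% 2L
  out[, top + seq_len(ho), left + seq_len(wo)] <- resized
  list(image = out, scale = r, pad = c(top, left))
}

## Decode raw one-to-one head outputs into a detection tibble.
decode_o2o <- function(head_out, cfg, conf_threshold, max_det) {
  strides <- c(8L, 16L, 32L)
  rm <- cfg$reg_max; nc <- cfg$num_classes
  rows <- list()
  for (i in 1:3) {
    box <- vv(head_out[[i]]$box); cls <- vv(head_out[[i]]$cls)
    d <- dim(box); H <- d[2]; W <- d[3]; N <- H * W
    st <- strides[i]
    bm <- matrix(box, 4L * rm, N)
    ltrb <- vapply(0:3, function(k) op_dfl_expect(bm[k * rm + seq_len(rm), , drop = FALSE]), numeric(N))
    hh <- rep(seq_len(H) - 0.5, times = W); ww <- rep(seq_len(W) - 0.5, each = H)
    cxs <- ww * st; cys <- hh * st
    scores <- stats::plogis(matrix(cls, nc, N))
    best <- max.col(t(scores), ties.method = "first")
    sbest <- scores[cbind(best, seq_len(N))]
    rows[[i]] <- tibble::tibble(
      class_id = best - 1L, score = sbest,
      x1 = cxs - ltrb[, 1] * st, y1 = cys - ltrb[, 2] * st,
      x2 = cxs + ltrb[, 3] * st, y2 = cys + ltrb[, 4] * st)
  }
  det <- dplyr::bind_rows(rows)
  det <- det[det$score >= conf_threshold & det$x2 > det$x1 & det$y2 > det$y1, , drop = FALSE]
  det <- det[order(-det$score), , drop = FALSE]
  if (nrow(det) > max_det) det <- det[seq_len(max_det), , drop = FALSE]
  det
}

#' Run detection on one image
#'
#' Letterboxes the image, runs the network, and decodes the one-to-one head
#' without non-maximum suppression: per anchor the best class is kept, then
#' detections are thresholded and truncated to `max_det` by score.
#'
#' @param model a built model.
#' @param image numeric array `(3, H, W)` in `[0, 1]`, or a PNG file path.
#' @param conf_threshold minimum score.
#' @param max_det maximum number of returned detections.
#' @return tibble with `class_id`, `score`, `x1`, `y1`, `x2`, `y2` in original
#'   image pixel coordinates, clipped to the image bounds.
#' @export
forward_detect <- function(model, image, conf_threshold = 0.25, max_det = 300L) {
  if (is.character(image)) image <- read_image(image)
  cfg <- model$cfg
  d0 <- dim(image)
  lb <- letterbox(image, cfg$input_size)
  out <- ud_fwd(model, lb$image)
  det <- decode_o2o(out$o2o, cfg, conf_threshold, max_det)
  if (nrow(det) == 0L) return(det)
  det$x1 <- (det$x1 - lb$pad[2]) / lb$scale
  det$x2 <- (det$x2 - lb$pad[2]) / lb$scale
  det$y1 <- (det$y1 - lb$pad[1]) / lb$scale
  det$y2 <- (det$y2 - lb$pad[1]) / lb$scale
  det$x1 <- pmin(pmax(det$x1, 0), d0[3]); det$x2 <- pmin(pmax(det$x2, 0), d0[3])
  det$y1 <- pmin(pmax(det$y1, 0), d0[2]); det$y2 <- pmin(pmax(det$y2, 0), d0[2])
  det[det$x2 > det$x1 & det$y2 > det$y1, , drop = FALSE]
}

read_image <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), c(dim(a), 3L))
  aperm(a[, , 1:3, drop = FALSE], c(3, 1, 2))
}
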