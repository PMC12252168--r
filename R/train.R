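## Desk-scale training loop. This is deliberately simple plumbing: a
## center-in-box positive assigner with a small center-sampling radius,
## binary cross-entropy on class logits and an IoU loss on the
## distribution-expectation box decode, optimized with Adam. It is sufficient
## to overfit a handful of synthetic scenes; it is not a full large-scale
## training recipe (no mosaic augmentation, no dual-assignment schedule).

## IoU loss between predicted and target (l,t,r,b) distances sharing anchor
## points. pred is a 4 x n value (or node); target a 4 x n constant. Returns
## sum over columns of (1 - IoU).
op_iou_loss <- function(pred, target) {
  pv <- vv(pred)
  n <- ncol(pv)
  iou_parts <- function(p) {
    wo <- pmin(p[1, ], target[1, ]) + pmin(p[3, ], target[3, ])
    ho <- pmin(p[2, ], target[2, ]) + pmin(p[4, ], target[4, ])
    inter <- wo * ho
    a <- (p[1, ] + p[3, ]) * (p[2, ] + p[4, ])
    at <- (target[1, ] + target[3, ]) * (target[2, ] + target[4, ])
    u <- a + at - inter
    list(wo = wo, ho = ho, inter = inter, a = a, u = u, iou = inter / pmax(u, 1e-9))
  }
  pt <- iou_parts(pv)
  y <- sum(1 - pt$iou)
  if (!is_nd(pred)) return(y)
  nd(y, list(pred), function(g) {
    gp <- matrix(0, 4, n)
    for (k in 1:4) {
      horiz <- k %in% c(1, 3)
      dov <- as.numeric(pv[k, ] < target[k, ])       # d overlap_k / d p_k
      dI <- dov * (if (horiz) pt$ho else pt$wo)
      dA <- if (horiz) pv[2, ] + pv[4, ] else pv[1, ] + pv[3, ]
      dU <- dA - dI
      dIoU <- (dI * pt$u - pt$inter * dU) / pmax(pt$u, 1e-9)^2
      gp[k, ] <- -dIoU
    }
    list(g * gp)
  })
}

## Assign ground-truth boxes (pixel corner coords) to anchors of one level.
## Positive anchors have their center inside a gt box and within
## `radius * stride` of the gt center; ties go to the smallest gt box.
assign_level <- function(gt, H, W, stride, reg_max, radius = 2.5) {
  if (nrow(gt) == 0L)
    return(list(pos = integer(), cls = integer(), ltrb = matrix(0, 4, 0)))
  hh <- rep(seq_len(H) - 0.5, times = W) * stride   # anchor y
  ww <- rep(seq_len(W) - 0.5, each = H) * stride    # anchor x
  n <- H * W
  best_gt <- rep(NA_integer_, n)
  best_area <- rep(Inf, n)
  for (j in seq_len(nrow(gt))) {
    cx <- (gt$x1[j] + gt$x2[j]) / 2; cy <- (gt$y1[j] + gt$y2[j]) / 2
    inside <- ww > gt$x1[j] & ww < gt$x2[j] & hh > gt$y1[j] & hh < gt$y2[j]
    near <- abs(ww - cx) <= radius * stride & abs(hh - cy) <= radius * stride
    cand <- which(inside & near)
    if (!length(cand)) next
    l <- ww[cand] - gt$x1[j]; t <- hh[cand] - gt$y1[j]
    r <- gt$x2[j] - ww[cand]; b <- gt$y2[j] - hh[cand]
    fits <- pmax(l, t, r, b) / stride < reg_max - 0.5
    cand <- cand[fits]
    if (!length(cand)) next
    area <- (gt$x2[j] - gt$x1[j]) * (gt$y2[j] - gt$y1[j])
    upd <- cand[area < best_area[cand]]
    best_gt[upd] <- j
    best_area[upd] <- area
  }
  pos <- which(!is.na(best_gt))
  j <- best_gt[pos]
  ltrb <- rbind(ww[pos] - gt$x1[j], hh[pos] - gt$y1[j],
                gt$x2[j] - ww[pos], gt$y2[j] - hh[pos]) / stride
  list(pos = pos, cls = gt$class_id[j], ltrb = ltrb)
}

## One-to-one assignment: exactly one positive anchor per ground-truth box,
## at the level whose stride best matches the box size (among levels whose
## regression range can represent it), at the anchor nearest the box center.
assign_top1 <- function(gt, dims, strides, reg_max) {
  out <- lapply(seq_along(strides), function(i)
    list(pos = integer(), cls = integer(), ltrb = matrix(0, 4, 0)))
  for (j in seq_len(nrow(gt))) {
    cx <- (gt$x1[j] + gt$x2[j]) / 2; cy <- (gt$y1[j] + gt$y2[j]) / 2
    size <- max(gt$x2[j] - gt$x1[j], gt$y2[j] - gt$y1[j])
    best_i <- 0L; best_fit <- Inf
    for (i in seq_along(strides)) {
      st <- strides[i]
      H <- dims[[i]][1]; W <- dims[[i]][2]
      hy <- min(max(ceiling(cy / st), 1L), H); wx <- min(max(ceiling(cx / st), 1L), W)
      ax <- (wx - 0.5) * st; ay <- (hy - 0.5) * st
      ltrb <- c(ax - gt$x1[j], ay - gt$y1[j], gt$x2[j] - ax, gt$y2[j] - ay) / st
      if (any(ltrb <= 0) || max(ltrb) >= reg_max - 0.5) next
      fit <- abs(log2(size / (4 * st)))
      if (fit < best_fit) { best_fit <- fit; best_i <- i }
    }
    if (best_i == 0L) next
    st <- strides[best_i]
    H <- dims[[best_i]][1]; W <- dims[[best_i]][2]
    hy <- min(max(ceiling(cy / st), 1L), H); wx <- min(max(ceiling(cx / st), 1L), W)
    ax <- (wx - 0.5) * st; ay <- (hy - 0.5) * st
    pos <- hy + H * (wx - 1L)
    o <- out[[best_i]]
    o$pos <- c(o$pos, pos)
    o$cls <- c(o$cls, gt$class_id[j])
    o$ltrb <- cbind(o$ltrb, c(ax - gt$x1[j], ay - gt$y1[j],
                              gt$x2[j] - ax, gt$y2[j] - ay) / st)
    out[[best_i]] <- o
  }
  out
}

## Loss of one head branch for one image.
branch_loss <- function(branch_out, gt, cfg, box_weight = 5, top1 = FALSE) {
  strides <- c(8L, 16L, 32L)
  rm <- cfg$reg_max; nc <- cfg$num_classes
  dims <- lapply(branch_out, function(l) shape_of(l$cls)[2:3])
  pre <- if (top1) assign_top1(gt, dims, strides, rm) else NULL
  terms <- list()
  npos_total <- 0L
  for (i in 1:3) {
    d <- shape_of(branch_out[[i]]$cls)
    asg <- if (top1) pre[[i]] else assign_level(gt, d[2], d[3], strides[i], rm)
    N <- d[2] * d[3]
    tgt <- matrix(0, nc, N)
    if (length(asg$pos)) tgt[cbind(asg$cls + 1L, asg$pos)] <- 1
    cls_flat <- op_reshape(branch_out[[i]]$cls, c(nc, N))
    terms[[length(terms) + 1L]] <- op_bce_logits_sum(cls_flat, tgt)
    npos_total <- npos_total + length(asg$pos)
    if (length(asg$pos)) {
      box_flat <- op_reshape(branch_out[[i]]$box, c(4L * rm, N))
      sel <- op_cols(box_flat, asg$pos)             # (4*rm, npos)
      ltrb <- op_rbind4(lapply(0:3, function(k)
        op_dfl_expect(op_rows(sel, k * rm + seq_len(rm)))))
      terms[[length(terms) + 1L]] <- op_scale(op_iou_loss(ltrb, asg$ltrb), box_weight)
    }
  }
  list(loss = op_add_scalar_chain(terms), npos = npos_total)
}

## Column / row selection and row-binding of 4 vectors as tape ops.
op_cols <- function(x, idx) {
  xv <- vv(x)
  y <- xv[, idx, drop = FALSE]
  if (!is_nd(x)) return(y)
  nd(y, list(x), function(g) {
    gx <- matrix(0, nrow(xv), ncol(xv))
    gx[, idx] <- gx[, idx] + g
    list(gx)
  })
}

op_rows <- function(x, idx) {
  xv <- vv(x)
  y <- xv[idx, , drop = FALSE]
  if (!is_nd(x)) return(y)
  nd(y, list(x), function(g) {
    gx <- matrix(0, nrow(xv), ncol(xv))
    gx[idx, ] <- gx[idx, ] + g
    list(gx)
  })
}

op_rbind4 <- function(xs) {
  vs <- lapply(xs, vv)
  y <- do.call(rbind, vs)
  if (!any(vapply(xs, is_nd, TRUE))) return(y)
  nd(y, xs, function(g) lapply(seq_along(xs), function(i) g[i, , drop = FALSE]))
}

## Adam update over collected gradients.
adam_step <- function(grads, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- (state$t %||% 0L) + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (key in names(grads)) {
    h <- grads[[key]]
    g <- h$grad
    m <- state$m[[key]] %||% (g * 0)
    v <- state$v[[key]] %||% (g * 0)
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    state$m[[key]] <- m
    state$v[[key]] <- v
    h$mod$params[[h$name]] <- h$mod$params[[h$name]] -
      lr * (m / bc1) / (sqrt(v / bc2) + eps)
  }
  invisible(state)
}

#' Desk-scale supervised training loop
#'
#' Trains a model on a small labeled dataset with a simple center-in-box
#' assigner, binary cross-entropy class loss and IoU box loss on both head
#' branches, optimized with Adam at batch size 1. Designed to overfit a few
#' dozen synthetic scenes on a CPU; it is not a large-scale training recipe.
#'
#' @param model a built model (see [build_model()]); modified in place.
#' @param data_dir dataset directory in YOLO layout ([make_dataset()]).
#' @param epochs training epochs.
#' @param seed seed controlling image order shuffling.
#' @param lr peak Adam learning rate; a 3-epoch linear warmup precedes a
#'   cosine decay to `lr / 10` over the remaining epochs.
#' @param eval_conf confidence threshold of the final train-set evaluation.
#' @return object of class `ud_train_report`: per-epoch losses, the final
#'   train-set evaluation summary and its mAP@0.5.
#' @export
train_demo <- function(model, data_dir, epochs = 40L, seed = 0L, lr = 3e-3,
                       eval_conf = 0.05) {
  stems <- sort(sub("\\.png$", "", list.files(file.path(data_dir, "images"), "\\.png$")))
  if (length(stems) == 0L) stop("empty dataset: ", data_dir, call. = FALSE)
  size <- model$cfg$input_size
  imgs <- lapply(stems, function(s) {
    im <- read_image(file.path(data_dir, "images", paste0(s, ".png")))
    letterbox(im, size)$image
  })
  gts <- lapply(stems, function(s) {
    lb <- read_yolo_labels(file.path(data_dir, "labels", paste0(s, ".txt")))
    labels_to_boxes(lb, size)  # letterbox of square scenes is identity up to scale
  })
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  state <- new.env(parent = emptyenv())
  losses <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    lr_ep <- if (ep <= 3L) lr * ep / 3 else {
      frac <- (ep - 3) / max(1L, epochs - 3L)
      lr * (0.1 + 0.45 * (1 + cos(pi * frac)))
    }
    tot <- 0
    for (i in sample(seq_along(imgs))) {
      tape_start()
      out <- ud_fwd(model, imgs[[i]])
      lo2o <- branch_loss(out$o2o, gts[[i]], model$cfg, top1 = TRUE)
      lo2m <- branch_loss(out$o2m, gts[[i]], model$cfg)
      loss <- op_add_scalar_chain(list(
        op_scale(lo2o$loss, 1 / max(1L, lo2o$npos)),
        op_scale(lo2m$loss, 1 / max(1L, lo2m$npos))))
      backward(loss)
      gr <- collected_grads()
      tape_stop()
      adam_step(gr, state, lr_ep)
      tot <- tot + vv(loss)
    }
    losses[ep] <- tot / length(imgs)
    if (!is.finite(losses[ep])) stop("non-finite loss at epoch ", ep, call. = FALSE)
  }
  ## train-set evaluation
  dets <- purrr::map_dfr(seq_along(stems), function(i) {
    d <- forward_detect(model, read_image(file.path(data_dir, "images", paste0(stems[i], ".png"))),
                        conf_threshold = eval_conf, max_det = 100L)
    if (nrow(d)) d$image <- stems[i]
    d
  })
  gtall <- read_ground_truth(data_dir, size)
  ev <- map_summary(dets, gtall)
  structure(list(losses = tibble::tibble(epoch = seq_len(epochs), loss = losses),
                 eval = ev, map50 = ev$map50, epochs = epochs, seed = seed, lr = lr),
            class = "ud_train_report")
}

#' @export
print.ud_train_report <- function(x, ...) {
  cat(sprintf("trained %d epochs; final loss %.4f; train-set mAP@0.5 %.4f\n",
              x$epochs, utils::tail(x$losses$loss, 1), x$map50))
  invisible(x)
}

#' @export
tidy.ud_train_report <- function(x, ...) x$losses

#' @export
glance.ud_train_report <- function(x, ...) {
  tibble::tibble(epochs = x$epochs, final_loss = utils::tail(x$losses$loss, 1),
                 map50 = x$map50)
}

#' Save or load model weights
#'
#' Parameters are stored by module path in an RDS container.
#'
#' @param model a built model.
#' @param path file path.
#' @export
save_weights <- function(model, path) {
  st <- list()
  walk_modules(model, function(m, p) {
    st[[p]] <<- list(params = m$params)
  })
  saveRDS(st, path)
  invisible(path)
}

#' @rdname save_weights
#' @export
load_weights <- function(model, path) {
  st <- readRDS(path)
  walk_modules(model, function(m, p) {
    s <- st[[p]]
    if (is.null(s)) stop("weights missing for module ", p, call. = FALSE)
    m$params <- s$params
  })
  invisible(model)
}
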