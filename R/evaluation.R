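## Detection metrics: IoU, greedy matching, precision/recall, average
## precision (101-point COCO-style interpolation by default, continuous
## envelope behind a flag) and the mAP summary at IoU 0.5 and 0.5:0.95.

#' Intersection over union of two axis-aligned boxes
#'
#' Continuous-coordinate convention (no +1). Degenerate boxes
#' (`x1 >= x2` or `y1 >= y2`) are an error.
#'
#' @param box_a,box_b numeric length-4 vectors `c(x1, y1, x2, y2)`.
#' @return overlap ratio in `[0, 1]`.
#' @export
iou <- function(box_a, box_b) {
  ok <- function(b) length(b) == 4L && b[1] < b[3] && b[2] < b[4]
  if (!ok(box_a) || !ok(box_b)) stop("degenerate box", call. = FALSE)
  iw <- max(0, min(box_a[3], box_b[3]) - max(box_a[1], box_b[1]))
  ih <- max(0, min(box_a[4], box_b[4]) - max(box_a[2], box_b[2]))
  inter <- iw * ih
  ua <- (box_a[3] - box_a[1]) * (box_a[4] - box_a[2]) +
    (box_b[3] - box_b[1]) * (box_b[4] - box_b[2]) - inter
  inter / ua
}

## Vectorized IoU matrix between det rows and gt rows (x1,y1,x2,y2 columns).
iou_matrix <- function(d, g) {
  nd <- nrow(d); ng <- nrow(g)
  if (nd == 0L || ng == 0L) return(matrix(0, nd, ng))
  iw <- pmax(0, outer(d$x2, g$x2, pmin) - outer(d$x1, g$x1, pmax))
  ih <- pmax(0, outer(d$y2, g$y2, pmin) - outer(d$y1, g$y1, pmax))
  inter <- iw * ih
  area_d <- (d$x2 - d$x1) * (d$y2 - d$y1)
  area_g <- (g$x2 - g$x1) * (g$y2 - g$y1)
  inter / (outer(area_d, area_g, `+`) - inter)
}

#' Greedy matching of detections to ground truth
#'
#' Detections are visited in decreasing score order; each is a true positive
#' iff its best-IoU still-unmatched ground-truth box reaches the threshold.
#' Each ground-truth box is matched at most once; unmatched boxes are false
#' negatives. Call per image and per class.
#'
#' @param dets tibble with `score`, `x1`, `y1`, `x2`, `y2`.
#' @param gts tibble with `x1`, `y1`, `x2`, `y2`.
#' @param iou_threshold matching threshold.
#' @return list with `dets` (input rows in decreasing score order plus
#'   `is_tp` and `matched_gt`), `tp`, `fp`, `fn`.
#' @export
match_detections <- function(dets, gts, iou_threshold = 0.5) {
  ord <- order(-dets$score)
  dets <- dets[ord, , drop = FALSE]
  nd <- nrow(dets); ng <- nrow(gts)
  is_tp <- logical(nd)
  matched_gt <- rep(NA_integer_, nd)
  if (nd > 0L && ng > 0L) {
    iom <- iou_matrix(dets, gts)
    taken <- logical(ng)
    for (i in seq_len(nd)) {
      free <- which(!taken)
      if (length(free) == 0L) break
      j <- free[which.max(iom[i, free])]
      if (iom[i, j] >= iou_threshold) {
        is_tp[i] <- TRUE
        matched_gt[i] <- j
        taken[j] <- TRUE
      }
    }
  }
  dets$is_tp <- is_tp
  dets$matched_gt <- matched_gt
  list(dets = dets, tp = sum(is_tp), fp = nd - sum(is_tp), fn = ng - sum(is_tp))
}

#' Precision and recall from a match result
#'
#' `P = TP / (TP + FP)` and `R = TP / (TP + FN)`; both are defined as 1 when
#' their denominator is zero (nothing to get wrong).
#'
#' @param m a match result from [match_detections()], or any list with `tp`,
#'   `fp`, `fn` counts.
#' @return named numeric vector `c(precision, recall)`.
#' @export
precision_recall <- function(m) {
  p <- if (m$tp + m$fp == 0L) 1 else m$tp / (m$tp + m$fp)
  r <- if (m$tp + m$fn == 0L) 1 else m$tp / (m$tp + m$fn)
  c(precision = p, recall = r)
}

#' Precision-recall curve from pooled scored detections
#'
#' @param scores detection scores pooled over images (one class).
#' @param is_tp logical true-positive flags aligned with `scores`.
#' @param n_gt number of ground-truth boxes of the class.
#' @return tibble in decreasing score order with cumulative `precision`,
#'   `recall` and the non-increasing interpolated `envelope`.
#' @export
pr_curve <- function(scores, is_tp, n_gt) {
  ord <- order(-scores)
  tp <- cumsum(is_tp[ord])
  fp <- cumsum(!is_tp[ord])
  prec <- tp / (tp + fp)
  rec <- if (n_gt > 0L) tp / n_gt else rep(0, length(tp))
  env <- rev(cummax(rev(prec)))
  tibble::tibble(score = scores[ord], precision = prec, recall = rec, envelope = env)
}

#' Average precision from a precision-recall curve
#'
#' `"101pt"` (default) averages the interpolated precision envelope over the
#' 101 recall points 0, 0.01, ..., 1. `"continuous"` integrates the envelope
#' exactly over recall.
#'
#' @param curve a tibble from [pr_curve()].
#' @param method `"101pt"` or `"continuous"`.
#' @return average precision in `[0, 1]`.
#' @export
average_precision <- function(curve, method = c("101pt", "continuous")) {
  method <- match.arg(method)
  if (nrow(curve) == 0L) return(0)
  if (method == "101pt") {
    grid <- seq(0, 1, by = 0.01)
    idx <- findInterval(grid, curve$recall, left.open = TRUE) + 1L
    p <- ifelse(idx <= nrow(curve), curve$envelope[idx], 0)
    return(mean(p))
  }
  r <- c(0, curve$recall)
  e <- c(curve$envelope, 0)
  sum(diff(r) * e[-length(e)])
}

## Pooled per-class TP flags at one IoU threshold across images.
flags_at_threshold <- function(dets, gts, cls, thr) {
  d <- dets[dets$class_id == cls, , drop = FALSE]
  g <- gts[gts$class_id == cls, , drop = FALSE]
  scores <- numeric(0); flags <- logical(0)
  for (im in unique(c(d$image, g$image))) {
    di <- d[d$image == im, , drop = FALSE]
    gi <- g[g$image == im, , drop = FALSE]
    m <- match_detections(di, gi, thr)
    scores <- c(scores, m$dets$score)
    flags <- c(flags, m$dets$is_tp)
  }
  list(scores = scores, flags = flags, n_gt = nrow(g))
}

#' Detection evaluation summary (mAP)
#'
#' Pools detections per class over images, matches greedily at each IoU
#' threshold, and reports per-class AP at 0.5, AP averaged over
#' 0.50:0.05:0.95, their class means (mAP), and overall precision/recall at
#' IoU 0.5. Classes without ground truth are excluded from the means with a
#' warning.
#'
#' @param dets tibble with `image`, `class_id`, `score`, `x1`, `y1`, `x2`,
#'   `y2`.
#' @param gts tibble with `image`, `class_id`, `x1`, `y1`, `x2`, `y2`.
#' @param method interpolation dialect passed to [average_precision()].
#' @return object of class `ud_eval_summary`.
#' @export
map_summary <- function(dets, gts, method = "101pt") {
  if (nrow(gts) == 0L) stop("no ground-truth boxes", call. = FALSE)
  thrs <- seq(0.5, 0.95, by = 0.05)
  classes <- sort(unique(gts$class_id))
  missing <- setdiff(sort(unique(dets$class_id)), classes)
  if (length(missing))
    warning("classes without ground truth excluded from mAP: ",
            paste(missing, collapse = ", "), call. = FALSE)
  per <- purrr::map_dfr(classes, function(cls) {
    aps <- vapply(thrs, function(thr) {
      fl <- flags_at_threshold(dets, gts, cls, thr)
      average_precision(pr_curve(fl$scores, fl$flags, fl$n_gt), method)
    }, 1)
    tibble::tibble(class_id = cls,
                   class_name = CLASS_NAMES[cls + 1L],
                   n_gt = sum(gts$class_id == cls),
                   ap50 = aps[1], ap5095 = mean(aps))
  })
  ## overall P/R at IoU 0.5 pooled over classes and images
  tp <- 0L; fp <- 0L; fn <- 0L
  for (cls in classes) {
    fl <- flags_at_threshold(dets, gts, cls, 0.5)
    tp <- tp + sum(fl$flags); fp <- fp + sum(!fl$flags); fn <- fn + fl$n_gt - sum(fl$flags)
  }
  pr <- precision_recall(list(tp = tp, fp = fp, fn = fn))
  curves <- lapply(classes, function(cls) {
    fl <- flags_at_threshold(dets, gts, cls, 0.5)
    dplyr::mutate(pr_curve(fl$scores, fl$flags, fl$n_gt),
                  class_id = cls, class_name = CLASS_NAMES[cls + 1L])
  })
  structure(list(per_class = per,
                 map50 = mean(per$ap50), map5095 = mean(per$ap5095),
                 precision = pr[["precision"]], recall = pr[["recall"]],
                 curves = dplyr::bind_rows(curves)),
            class = "ud_eval_summary")
}

#' @export
print.ud_eval_summary <- function(x, ...) {
  cat(sprintf("mAP@0.5 %.4f  mAP@0.5:0.95 %.4f  P %.4f  R %.4f\n",
              x$map50, x$map5095, x$precision, x$recall))
  print(x$per_class)
  invisible(x)
}

#' @export
tidy.ud_eval_summary <- function(x, ...) x$per_class

#' @export
glance.ud_eval_summary <- function(x, ...) {
  tibble::tibble(map50 = x$map50, map5095 = x$map5095,
                 precision = x$precision, recall = x$recall)
}

#' Read predictions written one file per image
#'
#' Each line is `class score cx cy w h` with normalized coordinates.
#'
#' @param pred_dir directory of `.txt` prediction files.
#' @param image_size pixel side used to scale boxes.
#' @return tibble with `image`, `class_id`, `score` and pixel corner boxes.
#' @export
read_predictions <- function(pred_dir, image_size) {
  fs <- sort(list.files(pred_dir, "\\.txt$", full.names = TRUE))
  purrr::map_dfr(fs, function(f) {
    lines <- readLines(f)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) return(NULL)
    m <- do.call(rbind, lapply(strsplit(lines, "\\s+"), as.numeric))
    tibble::tibble(image = sub("\\.txt$", "", basename(f)),
                   class_id = as.integer(m[, 1]), score = m[, 2],
                   x1 = (m[, 3] - m[, 5] / 2) * image_size,
                   y1 = (m[, 4] - m[, 6] / 2) * image_size,
                   x2 = (m[, 3] + m[, 5] / 2) * image_size,
                   y2 = (m[, 4] + m[, 6] / 2) * image_size)
  })
}

#' Evaluate a directory of ground-truth labels
#'
#' @param data_dir dataset directory in YOLO layout (see [make_dataset()]).
#' @param image_size pixel side used to scale boxes.
#' @return tibble with `image`, `class_id` and pixel corner boxes.
#' @export
read_ground_truth <- function(data_dir, image_size) {
  fs <- sort(list.files(file.path(data_dir, "labels"), "\\.txt$", full.names = TRUE))
  purrr::map_dfr(fs, function(f) {
    lb <- read_yolo_labels(f)
    if (!nrow(lb)) return(NULL)
    dplyr::mutate(labels_to_boxes(lb, image_size),
                  image = sub("\\.txt$", "", basename(f)), .before = 1)
  })
}
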