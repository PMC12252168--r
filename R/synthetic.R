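## Synthetic underwater scenes with YOLO-format ground truth.
##
## The generator emulates the pathologies reported for real underwater
## benchmark imagery: low foreground/background contrast, blur, additive
## sensor noise, a green-blue colour cast, small objects, tight clustering
## and per-class shape variation. Four parametric silhouettes stand in for
## the four organism classes: an elongated wavy blob (holothurian), a spiked
## disc (echinus), a ridged fan (scallop) and a five-armed star (starfish).
## Boxes are computed from the exact silhouette mask before any degradation.

CLASS_NAMES <- c("holothurian", "echinus", "scallop", "starfish")

#' Scene generator configuration
#'
#' @param image_size square image side in pixels.
#' @param n_objects number of objects to attempt per scene.
#' @param class_mix probabilities over the four classes, summing to 1.
#' @param object_scale_range object diameter range as a fraction of the image
#'   side, within (0, 0.5].
#' @param cluster_factor in `[0, 1]`: 0 places objects uniformly, 1 packs
#'   them tightly around a few cluster centres.
#' @param contrast in `[0, 1]`: foreground/background separation; 0 makes
#'   objects indistinguishable from the background.
#' @param blur_sigma Gaussian blur in pixels.
#' @param noise_sigma additive Gaussian noise amplitude (intensity units of
#'   the `[0, 1]` scale).
#' @param seed integer; together with the image index it fully determines
#'   every generated byte.
#' @return a config list for [generate_scene()] / [make_dataset()].
#' @export
scene_config <- function(image_size = 640L, n_objects = 6L,
                         class_mix = rep(0.25, 4),
                         object_scale_range = c(0.05, 0.18),
                         cluster_factor = 0.7, contrast = 0.35,
                         blur_sigma = 2, noise_sigma = 0.03, seed = 0L) {
  if (abs(sum(class_mix) - 1) > 1e-9) stop("class_mix must sum to 1", call. = FALSE)
  if (any(object_scale_range <= 0) || any(object_scale_range > 0.5))
    stop("object_scale_range must lie in (0, 0.5]", call. = FALSE)
  stopifnot(length(class_mix) == 4L, cluster_factor >= 0, cluster_factor <= 1,
            contrast >= 0, contrast <= 1, blur_sigma >= 0, noise_sigma >= 0)
  list(image_size = as.integer(image_size), n_objects = as.integer(n_objects),
       class_mix = class_mix, object_scale_range = object_scale_range,
       cluster_factor = cluster_factor, contrast = contrast,
       blur_sigma = blur_sigma, noise_sigma = noise_sigma, seed = as.integer(seed))
}

## Silhouette mask on a local grid. cls in 0..3, r0 = nominal radius (px),
## rot = rotation angle. Returns a logical matrix (rows = y, cols = x).
silhouette_mask <- function(cls, r0, rot, wobble) {
  half <- ceiling(r0 * 1.6) + 2L
  n <- 2L * half + 1L
  gx <- matrix(rep(seq(-half, half), each = n), n, n)
  gy <- matrix(rep(seq(-half, half), times = n), n, n)
  xr <- cos(rot) * gx + sin(rot) * gy
  yr <- -sin(rot) * gx + cos(rot) * gy
  th <- atan2(yr, xr)
  rr <- sqrt(xr^2 + yr^2)
  if (cls == 0L) {            # holothurian: elongated blob with wavy edge
    a <- r0 * 1.32; b <- r0 * 0.74
    edge <- 1 + 0.06 * sin(5 * th + wobble)
    m <- (xr / a)^2 + (yr / b)^2 <= edge
  } else if (cls == 1L) {     # echinus: disc with short radial spikes
    spikes <- 1 + 0.12 * abs(sin(9 * th + wobble))^6
    m <- rr <= 0.87 * r0 * spikes
  } else if (cls == 2L) {     # scallop: ridged fan
    ridge <- 1 + 0.05 * cos(9 * (th - wobble))
    sector <- cos(th - wobble) > -0.55        # open fan side
    m <- (rr <= r0 * ridge) & (sector | rr <= 0.74 * r0)  # rounded hinge
  } else {                    # starfish: five fat arms
    arms <- 0.62 + 0.38 * abs(cos(2.5 * (th + wobble)))^0.6
    m <- rr <= r0 * arms
  }
  m
}

## Low-frequency textured background with green-blue cast, (3, S, S).
scene_background <- function(S) {
  f <- function() {
    z <- matrix(0, S, S)
    u <- seq(0, 2 * pi, length.out = S)
    for (k in 1:4) {
      fx <- stats::runif(1, 0.5, 3); fy <- stats::runif(1, 0.5, 3)
      ph <- stats::runif(2, 0, 2 * pi); amp <- stats::runif(1, 0.2, 0.6)
      z <- z + amp * outer(sin(fx * u + ph[1]), sin(fy * u + ph[2]))
    }
    (z - min(z)) / max(1e-9, diff(range(z)))
  }
  tex <- f()
  base <- c(stats::runif(1, 0.05, 0.18),   # red: heavily attenuated
            stats::runif(1, 0.32, 0.5),    # green
            stats::runif(1, 0.28, 0.45))   # blue
  img <- array(0, c(3, S, S))
  for (ch in 1:3) img[ch, , ] <- base[ch] + 0.12 * (tex - 0.5)
  img
}

## Per-class foreground colours (before contrast compression / cast).
class_colour <- function(cls) {
  base <- switch(cls + 1L,
                 c(0.45, 0.35, 0.22),   # holothurian: brownish
                 c(0.12, 0.10, 0.14),   # echinus: dark
                 c(0.62, 0.55, 0.42),   # scallop: pale
                 c(0.55, 0.30, 0.25))   # starfish: reddish
  pmin(pmax(base + stats::rnorm(3, 0, 0.04), 0), 1)
}

gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  C <- dim(img)[1]
  wrow <- matrix(rep(k, C), nrow = C, byrow = TRUE)        # (C) x (1*(2r+1))
  ones <- array(1, dim(img))
  blur1 <- function(a, horiz) {
    kh <- if (horiz) 1L else (2L * r + 1L)
    kw <- if (horiz) (2L * r + 1L) else 1L
    cpp_conv2d_fw(a, dim(a), wrow, NULL, kh, kw, 1L, (kh - 1L) %/% 2L, (kw - 1L) %/% 2L, C)
  }
  num <- blur1(blur1(img, TRUE), FALSE)
  den <- blur1(blur1(ones, TRUE), FALSE)   # normalize away zero padding
  num / den
}

#' Generate one synthetic underwater scene
#'
#' @param cfg configuration from [scene_config()].
#' @return list with `image` (numeric array `(3, S, S)` in `[0, 1]`),
#'   `annotations` (tibble with `class_id`, `cx`, `cy`, `w`, `h`, normalized
#'   center-size coordinates in `[0, 1]`), and `n_dropped` (objects discarded
#'   after bounded placement retries).
#' @export
generate_scene <- function(cfg = scene_config()) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(cfg$seed)
  S <- cfg$image_size
  img <- scene_background(S)
  bg <- img
  ## cluster centres
  ncl <- max(1L, round(1 + (1 - cfg$cluster_factor) * 3))
  centres <- cbind(stats::runif(ncl, 0.2 * S, 0.8 * S), stats::runif(ncl, 0.2 * S, 0.8 * S))
  cluster_sd <- S * (0.25 - 0.2 * cfg$cluster_factor)
  ann <- list()
  n_dropped <- 0L
  classes <- if (cfg$n_objects > 0L) {
    sample.int(4L, cfg$n_objects, replace = TRUE, prob = cfg$class_mix) - 1L
  } else integer()
  for (cls in classes) {
    placed <- FALSE
    for (try in 1:20) {
      r0 <- stats::runif(1, cfg$object_scale_range[1], cfg$object_scale_range[2]) * S / 2
      rot <- stats::runif(1, 0, 2 * pi)
      wob <- stats::runif(1, 0, 2 * pi)
      if (stats::runif(1) < cfg$cluster_factor) {
        ci <- sample.int(ncl, 1L)
        cx <- stats::rnorm(1, centres[ci, 1], cluster_sd)
        cy <- stats::rnorm(1, centres[ci, 2], cluster_sd)
      } else {
        cx <- stats::runif(1, 0, S); cy <- stats::runif(1, 0, S)
      }
      mask <- silhouette_mask(cls, r0, rot, wob)
      half <- (nrow(mask) - 1L) %/% 2L
      x0 <- round(cx) - half; y0 <- round(cy) - half
      ys <- which(rowSums(mask) > 0); xs <- which(colSums(mask) > 0)
      ## tight box in image coordinates (pixel extent of the mask)
      bx1 <- x0 + min(xs) - 1L; bx2 <- x0 + max(xs)
      by1 <- y0 + min(ys) - 1L; by2 <- y0 + max(ys)
      if (bx1 < 0 || by1 < 0 || bx2 > S || by2 > S) next
      col <- class_colour(cls)
      shade <- 1 + 0.15 * sin(seq_len(nrow(mask)) / max(3, r0))
      idx <- which(mask, arr.ind = TRUE)   # (row = y, col = x) on local grid
      px <- x0 + idx[, 2] - 1L; py <- y0 + idx[, 1] - 1L
      keep <- px >= 1 & px <= S & py >= 1 & py <= S
      px <- px[keep]; py <- py[keep]; sh <- shade[idx[keep, 1]]
      for (chn in 1:3) {
        lin <- (chn - 1L) + 3L * (py - 1L) + 3L * S * (px - 1L) + 1L
        img[lin] <- col[chn] * sh
      }
      ann[[length(ann) + 1L]] <- tibble::tibble(
        class_id = cls,
        cx = (bx1 + bx2) / 2 / S, cy = (by1 + by2) / 2 / S,
        w = (bx2 - bx1) / S, h = (by2 - by1) / S)
      placed <- TRUE
      break
    }
    if (!placed) n_dropped <- n_dropped + 1L
  }
  ## degradations (never move the boxes: labels were computed above)
  img <- bg + (img - bg) * cfg$contrast
  img <- gaussian_blur(img, cfg$blur_sigma)
  if (cfg$noise_sigma > 0) img <- img + array(stats::rnorm(length(img), 0, cfg$noise_sigma), dim(img))
  img <- pmin(pmax(img, 0), 1)
  anns <- if (length(ann)) dplyr::bind_rows(ann) else
    tibble::tibble(class_id = integer(), cx = numeric(), cy = numeric(),
                   w = numeric(), h = numeric())
  structure(list(image = img, annotations = anns, n_dropped = n_dropped,
                 config = cfg), class = "ud_scene")
}

#' Write a dataset of synthetic scenes in YOLO layout
#'
#' Produces `images/*.png` and `labels/*.txt` (one line per object:
#' `class cx cy w h`, normalized) plus a JSON manifest recording files,
#' per-class counts and the generating configuration. Each scene's RNG stream
#' is derived from `(cfg$seed, image index)`, so the dataset is independent
#' of generation order.
#'
#' @param n_images number of scenes.
#' @param cfg configuration from [scene_config()].
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly also written to `manifest.json`.
#' @export
make_dataset <- function(n_images, cfg = scene_config(), out_dir) {
  dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "labels"), recursive = TRUE, showWarnings = FALSE)
  files <- character(n_images)
  counts <- stats::setNames(integer(4), CLASS_NAMES)
  dropped <- 0L
  for (i in seq_len(n_images)) {
    ci <- cfg
    ci$seed <- scene_seed(cfg$seed, i)
    sc <- generate_scene(ci)
    stem <- sprintf("img%04d", i)
    png::writePNG(aperm(sc$image, c(2, 3, 1)), file.path(out_dir, "images", paste0(stem, ".png")))
    write_yolo_labels(sc$annotations, file.path(out_dir, "labels", paste0(stem, ".txt")))
    files[i] <- stem
    tb <- table(factor(sc$annotations$class_id, levels = 0:3))
    counts <- counts + as.integer(tb)
    dropped <- dropped + sc$n_dropped
  }
  manifest <- list(files = files, class_counts = as.list(counts),
                   n_dropped = dropped, config = cfg)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

scene_seed <- function(seed, index) (as.integer(seed) %% 100003L) * 10007L + as.integer(index)

#' Read and write YOLO-format label files
#'
#' One line per object, `class cx cy w h`, space separated, coordinates
#' normalized to `[0, 1]`.
#'
#' @param labels tibble with `class_id`, `cx`, `cy`, `w`, `h`.
#' @param path file path.
#' @return `read_yolo_labels()` returns the tibble; boxes are validated to
#'   lie inside the unit square with positive extent.
#' @export
write_yolo_labels <- function(labels, path) {
  lines <- sprintf("%d %.6f %.6f %.6f %.6f",
                   labels$class_id, labels$cx, labels$cy, labels$w, labels$h)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_yolo_labels
#' @export
read_yolo_labels <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(tibble::tibble(class_id = integer(), cx = numeric(), cy = numeric(),
                          w = numeric(), h = numeric()))
  m <- do.call(rbind, lapply(strsplit(lines, "\\s+"), as.numeric))
  out <- tibble::tibble(class_id = as.integer(m[, 1]), cx = m[, 2], cy = m[, 3],
                        w = m[, 4], h = m[, 5])
  bad <- out$w <= 0 | out$h <= 0 | out$cx - out$w / 2 < -1e-6 |
    out$cy - out$h / 2 < -1e-6 | out$cx + out$w / 2 > 1 + 1e-6 |
    out$cy + out$h / 2 > 1 + 1e-6
  if (any(bad)) stop("invalid YOLO boxes in ", path, call. = FALSE)
  out
}

#' Export a YOLO-layout dataset as COCO-style JSON
#'
#' @param data_dir directory produced by [make_dataset()].
#' @param path output JSON path (default `annotations.json` inside the
#'   dataset directory).
#' @export
coco_export <- function(data_dir, path = file.path(data_dir, "annotations.json")) {
  stems <- sort(sub("\\.png$", "", list.files(file.path(data_dir, "images"), "\\.png$")))
  images <- list(); annotations <- list(); aid <- 0L
  for (i in seq_along(stems)) {
    img <- png::readPNG(file.path(data_dir, "images", paste0(stems[i], ".png")))
    H <- dim(img)[1]; W <- dim(img)[2]
    images[[i]] <- list(id = i, file_name = paste0(stems[i], ".png"),
                        width = W, height = H)
    lb <- read_yolo_labels(file.path(data_dir, "labels", paste0(stems[i], ".txt")))
    for (j in seq_len(nrow(lb))) {
      aid <- aid + 1L
      bw <- lb$w[j] * W; bh <- lb$h[j] * H
      annotations[[aid]] <- list(
        id = aid, image_id = i, category_id = lb$class_id[j] + 1L,
        bbox = c(lb$cx[j] * W - bw / 2, lb$cy[j] * H - bh / 2, bw, bh),
        area = bw * bh, iscrowd = 0L)
    }
  }
  categories <- lapply(1:4, function(k) list(id = k, name = CLASS_NAMES[k]))
  jsonlite::write_json(list(images = images, annotations = annotations,
                            categories = categories),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

## Convert normalized center-size labels to pixel corner boxes.
labels_to_boxes <- function(labels, size) {
  tibble::tibble(class_id = labels$class_id,
                 x1 = (labels$cx - labels$w / 2) * size,
                 y1 = (labels$cy - labels$h / 2) * size,
                 x2 = (labels$cx + labels$w / 2) * size,
                 y2 = (labels$cy + labels$h / 2) * size)
}
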