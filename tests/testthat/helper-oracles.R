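# Independent loop-based oracles. These deliberately avoid the package's
# compute engine: plain nested loops and scalar arithmetic only.

# Naive 2-D convolution on a (C,H,W) array; w is the packed (Co x Cg*kh*kw)
# weight matrix used by the package layers, unpacked here element by element.
oracle_conv2d <- function(x, w, b = NULL, kh, kw, stride = 1, ph, pw, groups = 1) {
  d <- dim(x); C <- d[1]; H <- d[2]; W <- d[3]
  Co <- nrow(w); Cg <- C / groups; Cog <- Co / groups
  Ho <- (H + 2 * ph - kh) %/% stride + 1
  Wo <- (W + 2 * pw - kw) %/% stride + 1
  out <- array(0, c(Co, Ho, Wo))
  for (co in seq_len(Co)) {
    g <- (co - 1) %/% Cog
    for (ho in seq_len(Ho)) for (wo in seq_len(Wo)) {
      acc <- if (is.null(b)) 0 else b[co]
      for (ci in seq_len(Cg)) for (dh in seq_len(kh)) for (dw in seq_len(kw)) {
        hi <- (ho - 1) * stride - ph + dh
        wi <- (wo - 1) * stride - pw + dw
        if (hi >= 1 && hi <= H && wi >= 1 && wi <= W) {
          widx <- ci + Cg * (dh - 1) + Cg * kh * (dw - 1)
          acc <- acc + w[co, widx] * x[g * Cg + ci, hi, wi]
        }
      }
      out[co, ho, wo] <- acc
    }
  }
  out
}

sigmoid_s <- function(z) 1 / (1 + exp(-z))

# Apply a bias 1x1-conv two-layer stack (ReLU between) to a length-C vector.
oracle_mlp_stack <- function(v, m1, m2) {
  h <- as.vector(m1$params$w %*% v) + m1$params$b
  h <- pmax(h, 0)
  as.vector(m2$params$w %*% h) + m2$params$b
}

# Channel attention of a MASM module, scalar arithmetic.
oracle_channel_attention <- function(x, masm) {
  C <- dim(x)[1]
  avg <- vapply(seq_len(C), function(c) mean(x[c, , ]), 1)
  mx <- vapply(seq_len(C), function(c) max(x[c, , ]), 1)
  fa <- oracle_mlp_stack(avg, masm$children$ca1, masm$children$ca2)
  fm <- oracle_mlp_stack(mx, masm$children$ca1, masm$children$ca2)
  sigmoid_s(fa + fm)
}

oracle_pixel_attention <- function(xw, masm) {
  d <- dim(xw)
  out <- array(0, d)
  for (hh in seq_len(d[2])) for (ww in seq_len(d[3])) {
    v <- xw[, hh, ww]
    gate <- sigmoid_s(oracle_mlp_stack(v, masm$children$pa1, masm$children$pa2))
    out[, hh, ww] <- v * gate
  }
  out
}

oracle_dwconv <- function(x, mod) {
  cf <- mod$cfg
  oracle_conv2d(x, mod$params$w, mod$params$b, cf$kh, cf$kw, cf$stride,
                cf$ph, cf$pw, cf$groups)
}

oracle_spatial_attention <- function(xw, masm) {
  base <- oracle_dwconv(xw, masm$children$dw5)
  s <- base
  for (K in masm$cfg$kernel_set) {
    s <- s + oracle_dwconv(oracle_dwconv(base, masm$children[[paste0("dwh", K)]]),
                           masm$children[[paste0("dwv", K)]])
  }
  oracle_conv2d(s, masm$children$mix$params$w, NULL, 1, 1, 1, 0, 0, 1)
}

oracle_masm <- function(x, masm) {
  ca <- oracle_channel_attention(x, masm)
  xw <- x * array(rep(ca, prod(dim(x)[2:3])), dim(x))
  oracle_pixel_attention(xw, masm) * oracle_spatial_attention(xw, masm)
}

# Greedy matcher re-implemented with explicit loops over score order.
oracle_greedy_match <- function(dets, gts, thr) {
  ord <- order(-dets$score)
  taken <- rep(FALSE, nrow(gts))
  tp <- 0
  for (i in ord) {
    best <- -1; bj <- 0
    for (j in seq_len(nrow(gts))) {
      if (taken[j]) next
      v <- iou(c(dets$x1[i], dets$y1[i], dets$x2[i], dets$y2[i]),
               c(gts$x1[j], gts$y1[j], gts$x2[j], gts$y2[j]))
      if (v > best) { best <- v; bj <- j }
    }
    if (bj > 0 && best >= thr) { taken[bj] <- TRUE; tp <- tp + 1 }
  }
  list(tp = tp, fp = nrow(dets) - tp, fn = nrow(gts) - tp)
}

# Brute-force 101-point AP from ordered TP flags: precision envelope computed
# by an explicit max over suffixes at every grid point.
oracle_ap_101 <- function(flags_in_score_order, n_gt) {
  n <- length(flags_in_score_order)
  tp <- cumsum(flags_in_score_order)
  fp <- cumsum(!flags_in_score_order)
  prec <- tp / (tp + fp)
  rec <- tp / n_gt
  total <- 0
  for (r in seq(0, 1, by = 0.01)) {
    best <- 0
    for (i in seq_len(n)) if (rec[i] >= r && prec[i] > best) best <- prec[i]
    total <- total + best
  }
  total / 101
}

# Closed-form parameter counts for the calibrated default configuration,
# independent of the module tree (mirrors the layer inventory analytically).
oracle_param_count <- function(variant) {
  conv <- function(c1, c2, k, bn = TRUE, bias = FALSE, g = 1) {
    c1 / g * c2 * k * k + (if (bias) c2 else 0) + (if (bn) 2 * c2 else 0)
  }
  cbs <- function(c1, c2, k) conv(c1, c2, k)
  bneck <- function(c) 2 * cbs(c, c, 3)
  masm <- function(c) {
    h <- max(1, c %/% 8)
    2 * (c * h + h + h * c + c) +            # shared channel stack + pixel stack
      (25 * c + c) + 2 * sum(c(7, 11, 21) * c + c) + c * c
  }
  c2f <- function(c1, c2, n, with_masm = FALSE) {
    ch <- c2 %/% 2
    cbs(c1, 2 * ch, 1) + cbs((2 + n) * ch, c2, 1) + n * bneck(ch) +
      (if (with_masm) n * masm(ch) else 0)
  }
  cib <- function(c) {
    conv(c, c, 3, g = c) + cbs(c, 2 * c, 1) +
      conv(2 * c, 2 * c, 7, g = 2 * c) + conv(2 * c, 2 * c, 3, g = 2 * c) +
      cbs(2 * c, c, 1) + conv(c, c, 3, g = c)
  }
  c2fcib <- function(c1, c2, n) {
    ch <- c2 %/% 2
    cbs(c1, 2 * ch, 1) + cbs((2 + n) * ch, c2, 1) + n * cib(ch)
  }
  scdown <- function(c1, c2) cbs(c1, c2, 1) + conv(c2, c2, 3, g = c2)
  sppf <- function(c) { ch <- c %/% 2; cbs(c, ch, 1) + cbs(4 * ch, c, 1) }
  psa <- function(c) {
    ch <- c %/% 2
    cbs(c, 2 * ch, 1) + cbs(2 * ch, c, 1) + cbs(ch, 2 * ch, 1) +
      cbs(ch, ch, 1) + conv(ch, ch, 3, g = ch) + cbs(ch, 2 * ch, 1) + cbs(2 * ch, ch, 1)
  }
  ema <- function(c, g = 8) { cg <- c %/% g; 10 * cg * cg + 4 * cg }
  head <- function() {
    per_branch <- 0
    for (x in c(64, 128, 256)) {
      per_branch <- per_branch + cbs(x, 64, 3) + cbs(64, 64, 3) + conv(64, 64, 1, bn = FALSE, bias = TRUE)
      per_branch <- per_branch + conv(x, x, 3, g = x) + cbs(x, 64, 1) +
        conv(64, 64, 3, g = 64) + cbs(64, 64, 1) + conv(64, 4, 1, bn = FALSE, bias = TRUE)
    }
    2 * per_branch + 16
  }
  B <- grepl("B", variant); S <- grepl("S", variant); E <- grepl("E", variant)
  backbone <- cbs(3, 16, 3) + cbs(16, 32, 3) + c2f(32, 32, 1) + cbs(32, 64, 3) +
    c2f(64, 64, 2) + scdown(64, 128) + c2f(128, 128, 2) + scdown(128, 256) +
    c2f(256, 256, 1) + sppf(256) + psa(256) +
    (if (E) ema(32) + ema(64) else 0)
  neck <- if (!B) {
    c2f(384, 128, 1, S) + c2f(192, 64, 1, S) + cbs(64, 64, 3) +
      c2f(192, 128, 1, S) + scdown(128, 128) + c2fcib(384, 256, 1) +
      (if (E) ema(64) + ema(128) else 0)
  } else {
    cbs(256, 128, 1) + c2f(128, 128, 1, S) + cbs(128, 64, 1) +
      conv(32, 32, 3, g = 32) + cbs(32, 64, 1) + cbs(64, 64, 1) +
      c2f(64, 64, 1, S) + conv(64, 64, 3, g = 64) + cbs(64, 128, 1) +
      cbs(128, 128, 1) + c2f(128, 128, 1, S) + cbs(128, 256, 1) +
      conv(256, 256, 3, g = 256) + 12 +
      (if (E) ema(64) + ema(128) else 0)
  }
  backbone + neck + head()
}

# Deterministic tiny dataset shared across tests.
make_demo_dataset <- function(n = 4, px = 64, seed = 11) {
  dir <- file.path(tempdir(), sprintf("udet-ds-%d-%d-%d", n, px, seed))
  if (!dir.exists(dir)) {
    cfg <- scene_config(image_size = px, n_objects = 3,
                        object_scale_range = c(0.25, 0.45), cluster_factor = 0.3,
                        contrast = 0.8, blur_sigma = 1, noise_sigma = 0.02, seed = seed)
    make_dataset(n, cfg, dir)
  }
  dir
}

expect_rel_equal <- function(actual, expected, tol = 1e-6) {
  denom <- pmax(abs(expected), 1e-12)
  expect_lt(max(abs(actual - expected) / denom), tol)
}
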