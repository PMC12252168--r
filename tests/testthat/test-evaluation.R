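test_that("IoU: worked examples and degenerate boxes", {
  expect_equal(iou(c(0, 0, 2, 2), c(0, 0, 2, 2)), 1)
  expect_equal(iou(c(0, 0, 1, 1), c(5, 5, 6, 6)), 0)
  expect_equal(iou(c(0, 0, 2, 2), c(1, 0, 3, 2)), 1 / 3)
  expect_error(iou(c(0, 0, 0, 2), c(0, 0, 1, 1)), "degenerate")
})

test_that("greedy matching: worked examples", {
  gts <- tibble::tibble(x1 = c(0, 10, 20), y1 = 0, x2 = c(5, 15, 25), y2 = 5)
  m0 <- match_detections(tibble::tibble(score = numeric(), x1 = numeric(),
                                        y1 = numeric(), x2 = numeric(), y2 = numeric()),
                         gts)
  expect_equal(c(m0$tp, m0$fp, m0$fn), c(0, 0, 3))
  ## two detections on one gt: the higher score wins, the other is FP
  dets <- tibble::tibble(score = c(0.9, 0.8),
                         x1 = c(0, 0.2), y1 = c(0, 0), x2 = c(5, 5.2), y2 = c(5, 5))
  m <- match_detections(dets, gts[1, ], 0.5)
  expect_equal(m$dets$is_tp, c(TRUE, FALSE))
  expect_equal(c(m$tp, m$fp, m$fn), c(1, 1, 0))
})

test_that("greedy matching equals the brute-force oracle on random instances", {
  set.seed(14)
  for (rep in 1:10) {
    gts <- tibble::tibble(x1 = runif(4, 0, 50), y1 = runif(4, 0, 50))
    gts$x2 <- gts$x1 + runif(4, 5, 20); gts$y2 <- gts$y1 + runif(4, 5, 20)
    dets <- tibble::tibble(score = runif(6),
                           x1 = runif(6, 0, 50), y1 = runif(6, 0, 50))
    dets$x2 <- dets$x1 + runif(6, 5, 20); dets$y2 <- dets$y1 + runif(6, 5, 20)
    for (thr in c(0.3, 0.5)) {
      got <- match_detections(dets, gts, thr)
      want <- oracle_greedy_match(dets, gts, thr)
      expect_equal(c(got$tp, got$fp, got$fn), c(want$tp, want$fp, want$fn))
    }
  }
})

test_that("precision and recall including the degenerate conventions", {
  expect_equal(precision_recall(list(tp = 8, fp = 2, fn = 0))[["precision"]], 0.8)
  expect_equal(precision_recall(list(tp = 8, fp = 0, fn = 8))[["recall"]], 0.5)
  pr0 <- precision_recall(list(tp = 0, fp = 0, fn = 0))
  expect_equal(unname(pr0), c(1, 1))
})

test_that("average precision: extremes, toy case, and the envelope oracle", {
  cv_all <- pr_curve(c(0.9, 0.8, 0.7), c(TRUE, TRUE, TRUE), 3)
  expect_equal(average_precision(cv_all), 1)
  expect_equal(average_precision(cv_all, "continuous"), 1)
  cv_none <- pr_curve(c(0.9, 0.8), c(FALSE, FALSE), 2)
  expect_equal(average_precision(cv_none), 0)
  flags <- c(TRUE, FALSE, TRUE, TRUE, FALSE)
  cv <- pr_curve(c(0.9, 0.8, 0.7, 0.6, 0.5), flags, 4)
  expect_equal(average_precision(cv), oracle_ap_101(flags, 4), tolerance = 1e-12)
  set.seed(3)
  for (rep in 1:8) {
    n <- sample(5:12, 1)
    flags <- runif(n) < 0.5
    ngt <- sum(flags) + sample(0:3, 1)
    if (ngt == 0) next
    cv <- pr_curve(seq(0.99, 0.5, length.out = n), flags, ngt)
    expect_equal(average_precision(cv), oracle_ap_101(flags, ngt), tolerance = 1e-12)
    ## 101-point and continuous interpolation agree closely
    expect_lt(abs(average_precision(cv) - average_precision(cv, "continuous")), 0.01 + 1 / ngt / 10)
  }
})

test_that("AP is invariant to monotone score transforms and image order", {
  set.seed(19)
  mk <- function(im, n) {
    d <- tibble::tibble(image = im, class_id = 0L, score = runif(n),
                        x1 = runif(n, 0, 40), y1 = runif(n, 0, 40))
    d$x2 <- d$x1 + 10; d$y2 <- d$y1 + 10
    d
  }
  gt <- dplyr::bind_rows(mk("a", 4), mk("b", 3))[, -3]
  dets <- dplyr::bind_rows(mk("a", 5), mk("b", 4))
  s1 <- map_summary(dets, gt)
  dets2 <- dplyr::mutate(dets, score = plogis(3 * score - 1))  # monotone
  s2 <- map_summary(dets2, gt)
  expect_equal(s1$map50, s2$map50)
  dets3 <- dets[rev(seq_len(nrow(dets))), ]
  expect_equal(map_summary(dets3, gt)$map50, s1$map50)
})

test_that("mAP is the class mean and the perfect predictor scores 1", {
  gts <- tibble::tibble(image = rep("a", 4), class_id = c(0L, 0L, 1L, 1L),
                        x1 = c(0, 20, 40, 60), y1 = 0,
                        x2 = c(10, 30, 50, 70), y2 = 10)
  half <- dplyr::mutate(gts[c(1, 3), ], score = 1)  # half of each class found
  s <- map_summary(dplyr::bind_rows(half), gts)
  expect_equal(s$per_class$ap50, c(0.5, 0.5), tolerance = 0.01)
  expect_equal(s$map50, mean(s$per_class$ap50))
  ## perfect predictor on a generated dataset
  dir <- make_demo_dataset(n = 8, px = 64, seed = 12)
  gt <- read_ground_truth(dir, 64)
  dets <- dplyr::mutate(gt, score = 1)
  sp <- map_summary(dets, gt)
  expect_equal(sp$map50, 1)
  expect_equal(sp$map5095, 1)
  expect_equal(sp$precision, 1)
  expect_equal(sp$recall, 1)
})

test_that("prediction files round-trip through the text dialect", {
  dir <- file.path(tempdir(), "udet-preds")
  unlink(dir, recursive = TRUE); dir.create(dir)
  writeLines(c("0 0.9 0.5 0.5 0.2 0.2", "2 0.4 0.25 0.25 0.1 0.1"),
             file.path(dir, "img0001.txt"))
  p <- read_predictions(dir, 100)
  expect_equal(nrow(p), 2L)
  expect_equal(p$class_id, c(0L, 2L))
  expect_equal(p$x1, c(40, 20))
  expect_equal(p$x2 - p$x1, c(20, 10))
})
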