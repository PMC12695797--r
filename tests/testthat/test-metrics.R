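truth_df <- function(rows, cols, radii) {
  data.frame(apple = seq_along(rows), row = rows, col = cols, radius = radii,
             a_row = radii, a_col = radii, theta_deg = 0)
}

test_that("greedy matching accounts for every truth apple exactly once", {
  tr <- truth_df(c(20, 60, 90), c(20, 50, 80), c(10, 10, 10))
  det <- data.frame(row = c(20.5, 60.2, 89), col = c(20.1, 50, 80.5))
  m <- match_detections(det, tr)
  expect_equal(c(m$tp, m$fp, m$fn), c(3, 0, 0))

  m0 <- match_detections(det[0, ], tr)
  expect_equal(c(m0$tp, m0$fn), c(0, 3))

  # two detections equally close to one truth apple: lower index wins
  det2 <- data.frame(row = c(22, 18), col = c(20, 20))
  m2 <- match_detections(det2, tr[1, ])
  expect_equal(m2$pairs$detection, 1)
  expect_equal(c(m2$tp, m2$fp), c(1, 1))

  # TP + FN always equals the number of truth apples; reordering
  # detections does not change the matched set size
  set.seed(44)
  for (i in 1:10) {
    nt <- sample(1:6, 1); nd <- sample(0:6, 1)
    tr_i <- truth_df(runif(nt, 10, 90), runif(nt, 10, 90), rep(8, nt))
    det_i <- data.frame(row = runif(nd, 10, 90), col = runif(nd, 10, 90))
    m_i <- match_detections(det_i, tr_i)
    expect_equal(m_i$tp + m_i$fn, nt)
    perm <- sample(seq_len(nd))
    m_p <- match_detections(det_i[perm, , drop = FALSE], tr_i)
    expect_equal(m_p$tp, m_i$tp)
  }
})

test_that("recognition accuracy is the detected fraction of truth", {
  tr <- truth_df(seq(10, 90, length.out = 5), seq(10, 90, length.out = 5),
                 rep(8, 5))
  det <- data.frame(row = tr$row, col = tr$col)
  expect_equal(recognition_accuracy(match_detections(det, tr)), 100)
  expect_equal(recognition_accuracy(match_detections(det[0, ], tr)), 0)

  m <- list(tp = 39, fn = 3)
  expect_equal(recognition_accuracy(m), 100 * 39 / 42, tolerance = 1e-10)
  expect_equal(round(recognition_accuracy(m), 2), 92.86)
})

test_that("MCD normalizes centroid deviation by the image diagonal", {
  tr <- truth_df(50, 50, 20)
  det <- data.frame(row = 50, col = 61)  # 11 px off
  m <- match_detections(det, tr)
  diag1080 <- sqrt(1920^2 + 1080^2)
  expect_equal(mean_coordinate_deviation(m, diag1080), 100 * 11 / diag1080)
  expect_equal(round(mean_coordinate_deviation(m, diag1080), 3), 0.499)

  det0 <- data.frame(row = 50, col = 50)
  expect_equal(mean_coordinate_deviation(match_detections(det0, tr), 100), 0)

  m_none <- match_detections(data.frame(row = numeric(0), col = numeric(0)), tr)
  expect_warning(v <- mean_coordinate_deviation(m_none, 100), "undefined")
  expect_true(is.na(v))
})

test_that("CRR counts truth apples reaching the IoU threshold", {
  lab <- matrix(0L, 60, 60)
  d <- disc_mask(60, 60, 30, 30, 12)
  lab[d == 1L] <- 1L
  tr <- truth_df(30, 30, 12)
  expect_equal(correct_recognition_rate(lab, tr), 100)
  expect_equal(correct_recognition_rate(matrix(0L, 60, 60), tr), 0)

  # region = disc plus an equal-area appendix: IoU is exactly 0.5, and the
  # threshold is inclusive
  lab2 <- lab
  idx0 <- which(lab == 0L & row(lab) < 15)
  lab2[idx0[seq_len(sum(d))]] <- 1L
  iou <- orchardvision:::.truth_region_iou(tr[1, ], lab2)
  expect_equal(iou, 0.5)
  expect_equal(correct_recognition_rate(lab2, tr, iou_threshold = 0.5), 100)
})

test_that("precision, recall, F1 and AP follow their definitions", {
  tr <- truth_df(c(30, 70), c(30, 70), c(10, 10))
  det <- data.frame(row = c(30, 70), col = c(30, 70))
  m <- match_detections(det, tr)
  pr <- precision_recall_f1_map(m, scores = c(0.9, 0.8))
  expect_equal(pr$precision, 1)
  expect_equal(pr$recall, 1)
  expect_equal(pr$f1, 1)
  expect_equal(pr$ap, 1)

  det_fp <- data.frame(row = c(10, 90), col = c(90, 10))
  m_fp <- match_detections(det_fp, tr[1, ])
  pr_fp <- precision_recall_f1_map(m_fp, scores = c(0.7, 0.6))
  expect_equal(pr_fp$precision, 0)
  expect_equal(pr_fp$f1, 0)
  expect_equal(pr_fp$ap, 0)

  # TP ranked above FP over a single truth apple: AP = 1
  det2 <- data.frame(row = c(30, 55), col = c(30, 55))
  m2 <- match_detections(det2, tr[1, ])
  expect_equal(m2$tp, 1)
  pr2 <- precision_recall_f1_map(m2, scores = c(0.9, 0.8))
  expect_equal(pr2$ap, 1)
  # FP ranked first halves the precision at full recall
  pr3 <- precision_recall_f1_map(m2, scores = c(0.8, 0.9))
  expect_equal(pr3$ap, 0.5)

  expect_equal(pr2$f1, 2 * 0.5 * 1 / 1.5)
})

test_that("angle stability is the per-angle dispersion of RA", {
  rep_same <- data.frame(angle = rep(c(0, 15), each = 3), ra = rep(95, 6))
  tab <- angle_stability(rep_same)
  expect_equal(tab$sd_ra, c(0, 0))

  two <- data.frame(angle = rep(30, 2), ra = c(90, 94))
  expect_equal(angle_stability(two)$sd_ra, sqrt(8), tolerance = 1e-9)
  expect_equal(round(angle_stability(two)$sd_ra, 3), 2.828)

  set.seed(5)
  many <- data.frame(angle = sample(c(0, 15, 30, 45), 40, TRUE),
                     ra = runif(40, 80, 100))
  expect_true(all(angle_stability(many)$sd_ra >= 0))
})
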