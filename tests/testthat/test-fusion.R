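test_that("GLCM statistics hit their closed-form extremes", {
  const <- matrix(100, 15, 15)
  expect_equal(glcm_score(const, glcm_spec(statistic = "energy")), 1)
  expect_equal(glcm_score(const, glcm_spec(statistic = "contrast")), 0)
  expect_equal(glcm_score(const, glcm_spec(statistic = "homogeneity")), 1)

  # 2-level checkerboard at distance 1, angle 0: every horizontal pair
  # differs, so contrast reaches its maximum (levels-1)^2 and normalizes to 1
  chk <- matrix(0, 10, 10)
  chk[(row(chk) + col(chk)) %% 2 == 0] <- 255
  sp <- glcm_spec(angles = 0, levels = 2, statistic = "contrast")
  expect_equal(glcm_score(chk, sp), 1)

  set.seed(2)
  rnd <- matrix(sample(0:255, 400, replace = TRUE), 20, 20)
  e <- glcm_score(rnd, glcm_spec(statistic = "energy"))
  expect_gte(e, 1 / 16^2)
  expect_lte(e, 1)

  expect_error(glcm_score(matrix(1, 1, 1), glcm_spec(distance = 2)),
               "distance")
})

test_that("circularity separates discs, squares and lines", {
  d <- connected_regions(disc_mask(60, 60, 30, 30, 20))
  expect_gte(shape_score(d[1, ]), 0.9)

  sq <- matrix(0L, 50, 50); sq[6:45, 6:45] <- 1L  # side 40
  s <- connected_regions(sq)
  expect_lt(abs(shape_score(s[1, ]) - pi / 4), 0.08)

  ln <- matrix(0L, 10, 30); ln[5, 5:24] <- 1L     # 1-px line, length 20
  l <- connected_regions(ln)
  expect_lt(shape_score(l[1, ]), 0.3)

  expect_error(shape_score(list(area = 0, perimeter = 4)), "degenerate")
})

test_that("composite score is a convex combination", {
  w <- fusion_weights(0.5, 0.3, 0.2)
  expect_equal(composite_score(1, 1, 1, w), 1)
  expect_equal(composite_score(0, 0, 0, w), 0)
  expect_equal(composite_score(0.8, 0.5, 1.0, w), 0.75)
  expect_error(composite_score(1.2, 0, 0, w), "\\[0, 1\\]")

  set.seed(8)
  for (i in 1:20) {
    comp <- runif(3)
    a <- runif(3); w2 <- fusion_weights(a[1], a[2], a[3])
    t <- composite_score(comp[1], comp[2], comp[3], w2)
    expect_gte(t, min(comp) - 1e-12)
    expect_lte(t, max(comp) + 1e-12)
    expect_lte(composite_score(comp[1] * 0.5, comp[2], comp[3], w2), t)
  }
  expect_equal(sum(unclass(fusion_weights(2, 1, 1))), 1)
})

test_that("weighted centroid follows the lever rule", {
  d <- disc_mask(31, 31, 16, 16, 10)
  expect_equal(unname(weighted_centroid(d)), c(16, 16))

  m <- matrix(0L, 1, 3); m[1, 1] <- 1L; m[1, 3] <- 1L
  w <- matrix(0, 1, 3); w[1, 1] <- 1; w[1, 3] <- 3
  expect_equal(unname(weighted_centroid(m, w)), c(1, 2.5))

  wu <- matrix(1, 31, 31)
  expect_equal(weighted_centroid(d, wu), weighted_centroid(d))
  expect_error(weighted_centroid(d, matrix(0, 31, 31)), "zero")
  expect_error(weighted_centroid(matrix(0L, 3, 3)), "empty")
})

test_that("circle fit recovers exact and rasterized circles", {
  tt <- seq(0, 2 * pi, length.out = 40)[-40]
  pts <- cbind(12 + 7.5 * sin(tt), 30 + 7.5 * cos(tt))
  fit <- fit_circle(pts)
  expect_equal(unname(fit$center), c(12, 30), tolerance = 1e-8)
  expect_equal(fit$radius, 7.5, tolerance = 1e-8)

  # circumcircle of three points: right triangle on a circle of radius 5
  p3 <- rbind(c(0, 5), c(5, 0), c(0, -5))
  f3 <- fit_circle(p3)
  expect_equal(unname(f3$center), c(0, 0), tolerance = 1e-9)
  expect_equal(f3$radius, 5, tolerance = 1e-9)

  d <- disc_mask(60, 60, 30, 30, 20)
  fr <- region_circle(d)
  expect_lt(abs(fr$radius - 20), 0.5)
  expect_lt(max(abs(unname(fr$center) - c(30, 30))), 0.5)

  expect_error(fit_circle(cbind(1:5, 1:5)), "collinear")
  expect_error(fit_circle(rbind(c(0, 0), c(1, 1))), "3 points")
})

test_that("detection finds clean apples and rejects foliage and streaks", {
  sc <- small_scene(seed = 31, n_apples = 1, noise_sigma = 0)
  cfg <- pipeline_config()
  res <- detect_scene(sc$left, config = cfg)
  expect_equal(nrow(res$detections), 1)
  expect_lt(sqrt((res$detections$row - sc$truth$row)^2 +
                   (res$detections$col - sc$truth$col)^2), 1)

  # foliage only: nothing to detect
  sc0 <- small_scene(seed = 32, n_apples = 0)
  res0 <- detect_scene(sc0$left, config = cfg)
  expect_equal(nrow(res0$detections), 0)

  # a branch-coloured elongated streak: its partial hue support cannot
  # carry the fusion score once the tiny circularity is weighed in
  img <- sc0$left
  img[88:91, 30:150, 1] <- 139; img[88:91, 30:150, 2] <- 90
  img[88:91, 30:150, 3] <- 43
  hsi <- rgb_to_hsi(img); gray <- to_gray(img)
  mask <- (hsi$h < 40 | hsi$h > 330) * 1L
  det <- detect_apples(mask, hsi, gray, threshold = 0.6, hue_ref = 0,
                       min_area = 10, split = FALSE)
  expect_equal(nrow(det), 0)
})
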