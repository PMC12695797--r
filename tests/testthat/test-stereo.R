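test_that("block matching recovers a pure integer shift", {
  set.seed(6)
  base <- orchardvision:::.gauss_smooth(matrix(runif(48 * 90, 0, 255), 48, 90), 1)
  s <- 7L
  right <- cbind(base[, (s + 1):90], base[, rep(90, s)])
  # right(i, j) = base(i, j + s) -> left pixel j matches right j - s
  dm <- block_match(base, right, block = 7, max_disparity = 15)
  interior <- dm$disparity[10:38, 20:80]
  vals <- interior[!is.na(interior)]
  expect_gt(length(vals), 500)
  expect_lt(stats::median(abs(vals - s)), 0.1)
})

test_that("textureless images yield no valid disparities", {
  flat <- matrix(100, 30, 40)
  dm <- block_match(flat, flat, block = 5, max_disparity = 8)
  expect_false(any(dm$valid))
  expect_true(all(is.na(dm$disparity)))
})

test_that("integer stage equals the exhaustive SAD oracle", {
  set.seed(13)
  for (rep in 1:3) {
    left <- matrix(sample(0:255, 40 * 60, replace = TRUE), 40, 60)
    s <- sample(2:6, 1)
    right <- cbind(left[, (s + 1):60], matrix(sample(0:255, 40 * s, replace = TRUE), 40, s))
    dm <- block_match(left, right, block = 5, max_disparity = 10,
                      subpixel = FALSE, lr_check = FALSE)
    oracle <- sad_oracle(left, right, block = 5, max_d = 10)
    inner <- cbind(rep(3:38, times = 48), rep(11:58, each = 36))
    keep <- dm$valid[inner]
    expect_gt(sum(keep), 100)
    expect_equal(dm$disparity[inner][keep], oracle[inner][keep])
  }
})

test_that("triangulation closed forms and round trip are exact", {
  rig <- stereo_rig(focal_px = 700, baseline_mm = 60,
                    principal_point = c(540, 960), image_size = c(1080, 1920))
  expect_equal(disparity_to_depth(52.5, rig), 800)
  expect_equal(disparity_to_depth(26.25, rig), 1600)
  expect_equal(disparity_to_depth(38.18, rig), 42000 / 38.18)
  expect_true(is.na(disparity_to_depth(0, rig)))
  expect_true(is.na(disparity_to_depth(-3, rig)))

  for (z in c(123.4, 800, 1100, 5000)) {
    d <- rig$focal_px * rig$baseline_mm / z
    expect_equal(disparity_to_depth(d, rig), z, tolerance = 1e-12)
  }

  expect_equal(unname(pixel_to_3d(c(540, 960), 900, rig)), c(0, 0, 900))
  expect_equal(pixel_to_3d(c(540, 960 + 700), 650, rig)[["X"]], 650)
  expect_equal(pixel_to_3d(c(540, 1100), 800, rig)[["X"]], 140 * 800 / 700)
})

test_that("localization error is the 3D Euclidean distance", {
  expect_equal(localization_error(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(localization_error(c(0, 0, 0), c(3, 4, 12)), 13)
  expect_equal(localization_error(c(1, 1, 1), c(2, 2, 2)), sqrt(3))
})

test_that("occlusion holes are filled from their surroundings", {
  depth <- matrix(900, 20, 20)
  valid <- matrix(TRUE, 20, 20); valid[10, 10] <- FALSE
  depth[10, 10] <- 0
  out <- fill_occluded_depth(depth, valid)
  expect_equal(out[10, 10], 900)
  expect_equal(out[valid], depth[valid])

  full <- matrix(1:100 + 0, 10, 10)
  expect_equal(fill_occluded_depth(full, matrix(TRUE, 10, 10)), full)

  ramp <- matrix(rep(seq(800, 1200, length.out = 30), each = 10), 10, 30)
  v <- matrix(TRUE, 10, 30); v[, 14:16] <- FALSE
  out2 <- fill_occluded_depth(ramp, v)
  expect_lt(max(abs(out2[, 14:16] - ramp[, 14:16])), 1)

  expect_error(fill_occluded_depth(ramp, matrix(FALSE, 10, 30)), "valid")
})

test_that("the depth validation protocol meets its precision regime", {
  rig <- stereo_rig()
  tab0 <- depth_validation_run(rig, noise_sigma_px = 0, seed = 5)
  expect_equal(nrow(tab0), 24)
  expect_equal(unique(tab0$distance_mm), c(800, 900, 1000, 1100))
  expect_lt(max(tab0$rel_err_pct), 0.1)

  # error scale grows with distance at fixed disparity noise: dZ/Z = dd/d,
  # d ~ 1/Z
  tab <- depth_validation_run(rig, noise_sigma_px = 0.2, seed = 11)
  agg <- tapply(tab$rel_err_pct, tab$distance_mm, mean)
  expect_gt(mean(agg[3:4]), mean(agg[1:2]) * 0.8)
})

test_that("detected apples triangulate to their true depth on clean scenes", {
  sp <- scene_spec(image_size = c(200, 320), n_apples = 3,
                   radius_range = c(14, 18), depth_range = c(800, 1300),
                   max_overlap = 0, noise_sigma = 0, brightness_jitter = 0,
                   seed = 17)
  rig <- stereo_rig(image_size = c(200, 320))
  sc <- render_scene(sp, rig)
  res <- detect_scene(sc$left, sc$right, pipeline_config(), rig)
  m <- match_detections(res$detections, sc$truth)
  expect_equal(m$tp, 3)
  for (k in seq_len(nrow(m$pairs))) {
    i <- m$pairs$detection[k]; j <- m$pairs$truth[k]
    expect_lt(abs(res$detections$disparity_px[i] - sc$truth$disparity_px[j]),
              0.5)
  }
})
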