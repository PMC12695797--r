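test_that("identical spec and seed render bit-identical stereo pairs", {
  sp <- scene_spec(image_size = c(120, 200), n_apples = 4, seed = 5,
                   radius_range = c(10, 15))
  a <- render_scene(sp, stereo_rig(image_size = c(120, 200)))
  b <- render_scene(sp, stereo_rig(image_size = c(120, 200)))
  expect_identical(a$left, b$left)
  expect_identical(a$right, b$right)
  expect_identical(a$truth, b$truth)
})

test_that("an empty scene is foliage only", {
  sp <- scene_spec(image_size = c(80, 100), n_apples = 0, seed = 1)
  sc <- render_scene(sp, stereo_rig(image_size = c(80, 100)))
  expect_equal(nrow(sc$truth), 0)
  expect_equal(dim(sc$left), c(80, 100, 3))
})

test_that("stereo geometry is exact: d = f B / Z", {
  rig <- stereo_rig(image_size = c(160, 300))
  sp <- scene_spec(image_size = c(160, 300), n_apples = 1,
                   depth_range = c(800, 800), radius_range = c(12, 12),
                   seed = 3)
  sc <- render_scene(sp, rig)
  expect_equal(sc$truth$disparity_px, 700 * 60 / 800)  # 52.5 px

  sp2 <- scene_spec(image_size = c(160, 300), n_apples = 5, seed = 9,
                    radius_range = c(8, 12))
  sc2 <- render_scene(sp2, rig)
  z_back <- rig$focal_px * rig$baseline_mm / sc2$truth$disparity_px
  expect_lt(max(abs(z_back / sc2$truth$depth_mm - 1)), 1e-6)
})

test_that("overlap_fraction matches geometry and a rasterized oracle", {
  expect_equal(overlap_fraction(c(0, 0), 5, c(0, 0), 5), 1)
  expect_equal(overlap_fraction(c(0, 0), 5, c(0, 20), 5), 0)
  expect_equal(overlap_fraction(c(0, 0), 10, c(1, 1), 3), 1)  # containment

  # Monte-Carlo / raster oracle: r1 = r2 = 10, centers 10 px apart
  analytic <- overlap_fraction(c(50, 50), 10, c(50, 60), 10)
  g <- expand.grid(r = seq(30.5, 80.5, by = 0.25),
                   c = seq(30.5, 80.5, by = 0.25))
  in1 <- (g$r - 50)^2 + (g$c - 50)^2 <= 100
  in2 <- (g$r - 50)^2 + (g$c - 60)^2 <= 100
  raster <- sum(in1 & in2) / sum(in1)
  expect_lt(abs(analytic - raster) / raster, 0.01)
})

test_that("placement honours the per-apple overlap budget", {
  sp <- scene_spec(image_size = c(250, 400), n_apples = 10, seed = 21,
                   radius_range = c(12, 20), max_overlap = 0.35)
  sc <- render_scene(sp, stereo_rig(image_size = c(250, 400)))
  expect_true(all(sc$truth$occlusion <= 0.35 + 1e-6))
  n <- nrow(sc$truth)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ov <- overlap_fraction(c(sc$truth$row[i], sc$truth$col[i]),
                           sc$truth$radius[i],
                           c(sc$truth$row[j], sc$truth$col[j]),
                           sc$truth$radius[j])
    expect_lte(ov, 0.35 + 0.05)  # ellipse radius is the geometric mean
  }
  expect_true(all(sc$truth$row >= 1 & sc$truth$row <= 250))
  expect_true(all(sc$truth$col >= 1 & sc$truth$col <= 400))
  expect_true(all(sc$truth$depth_mm >= 800 & sc$truth$depth_mm <= 1700))
})

test_that("an infeasible spec is rejected rather than silently violated", {
  sp <- scene_spec(image_size = c(64, 64), n_apples = 30, seed = 2,
                   radius_range = c(20, 25), max_overlap = 0)
  expect_error(render_scene(sp, stereo_rig(image_size = c(64, 64))),
               "infeasible")
})

test_that("scenes serialize to PNG pairs plus JSON truth", {
  sc <- small_scene(seed = 12, n_apples = 2)
  d <- withr::local_tempdir()
  write_scene(sc, d)
  expect_true(all(file.exists(file.path(d, c("left.png", "right.png",
                                             "truth.json")))))
  tr <- jsonlite::read_json(file.path(d, "truth.json"))
  expect_length(tr$apples, 2)
  expect_equal(tr$rig$focal_px, 700)
})
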