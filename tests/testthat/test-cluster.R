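test_that("weighted distance follows the closed forms", {
  expect_equal(weighted_distance(c(1, 2), c(1, 2)), 0)
  expect_equal(weighted_distance(c(0, 3), c(4, 0), c(1, 1)), 5)
  expect_equal(weighted_distance(1, 3, 4), 4)
  expect_equal(weighted_distance(c(0, 3), c(4, 0)),
               weighted_distance(c(4, 0), c(0, 3)))
  expect_error(weighted_distance(c(1, 2), c(1, 2, 3)), "dimension")
  expect_error(weighted_distance(1, 2, -1), "nonnegative")
})

test_that("adaptive centers land in the dominant feature modes", {
  # two-tone image: brute-force scoring oracle picks one pixel per tone
  f <- matrix(0, 12, 20)
  f[, 11:20] <- 120
  ctr <- select_initial_centers(f, k = 2)
  expect_setequal(sort(ctr[, 1]), c(0, 120))

  # brute-force oracle: density score of every pixel, max must be selected
  score_oracle <- function(f, eps = 1e-3, r = 2) {
    h <- nrow(f); w <- ncol(f)
    s <- matrix(0, h, w)
    for (i in 1:h) for (j in 1:w)
      for (di in -r:r) for (dj in -r:r) {
        if (di == 0 && dj == 0) next
        ii <- min(max(i + di, 1), h); jj <- min(max(j + dj, 1), w)
        s[i, j] <- s[i, j] + 1 / (abs(f[i, j] - f[ii, jj]) + eps)
      }
    s
  }
  set.seed(3)
  f2 <- matrix(sample(c(10, 80), 15 * 15, replace = TRUE, prob = c(0.7, 0.3)),
               15, 15)
  c1 <- select_initial_centers(f2, k = 1)
  s <- score_oracle(f2)
  expect_equal(c1[1, 1], f2[which.max(s)])

  expect_error(select_initial_centers(matrix(5, 10, 10), k = 2), "degenerate")
})

test_that("k-means segmentation matches the optimal 1-D split oracle", {
  # exhaustive oracle: best threshold over sorted unique values for k = 2
  split_oracle <- function(v) {
    sv <- sort(unique(v))
    best <- Inf; lab <- NULL
    for (t in sv[-length(sv)]) {
      g <- v > t
      ss <- sum((v[!g] - mean(v[!g]))^2) + sum((v[g] - mean(v[g]))^2)
      if (ss < best) { best <- ss; lab <- g }
    }
    lab
  }
  set.seed(9)
  for (rep in 1:5) {
    v <- c(rnorm(130, 10, 3), rnorm(120, 100, 5))
    v <- pmax(0, sample(v))
    f <- matrix(v[1:240], 12, 20)
    seg <- kmeans_segment(f, k = 2)
    oracle <- split_oracle(as.vector(f))
    agree <- mean((seg$labels == seg$labels[1, 1]) ==
                    (matrix(oracle, 12, 20) == oracle[1]))
    expect_true(agree == 1 || agree == 0)  # same partition up to label swap
  }
})

test_that("k-means objective is monotone and converges at a fixed point", {
  set.seed(15)
  f <- matrix(c(rnorm(100, 0, 0.5), rnorm(100, 50, 0.5)), 10, 20)
  seg <- kmeans_segment(f, k = 2, centers = matrix(c(0, 50), 2, 1))
  expect_lte(seg$iterations, 3)
  expect_true(all(diff(seg$wss) <= 1e-9))

  for (rep in 1:5) {
    f <- matrix(runif(300, 0, 360), 15, 20)
    seg <- kmeans_segment(f, k = 3)
    expect_true(all(diff(seg$wss) <= 1e-9))
  }
})

test_that("segmentation is invariant to pixel arrangement", {
  set.seed(5)
  v <- c(rnorm(150, 20, 4), rnorm(150, 200, 4))
  f1 <- matrix(v, 15, 20)
  perm <- sample(300)
  f2 <- matrix(v[perm], 15, 20)
  s1 <- kmeans_segment(f1, k = 2, centers = matrix(c(20, 200), 2, 1))
  s2 <- kmeans_segment(f2, k = 2, centers = matrix(c(20, 200), 2, 1))
  expect_equal(as.vector(s1$labels)[perm], as.vector(s2$labels))
})

test_that("foreground selection picks the cluster nearest the fruit hue", {
  f <- matrix(c(rep(5, 100), rep(115, 200)), 15, 20)
  seg <- kmeans_segment(f, k = 2, centers = matrix(c(5, 115), 2, 1))
  fg <- foreground_mask(seg, hue_ref = 0)
  expect_equal(sum(fg), 100)
  fg2 <- foreground_mask(seg, hue_ref = 120)
  expect_equal(sum(fg2), 200)
})

test_that("morphological cleanup removes specks and keeps large discs", {
  m <- matrix(0L, 40, 40)
  m[20, 20] <- 1L                       # speck
  expect_equal(sum(morph_clean(m, selem_radius = 1, min_area = 5)), 0)

  d <- disc_mask(41, 41, 21, 21, 12)
  cleaned <- morph_clean(d, selem_radius = 1)
  expect_lt(abs(sum(cleaned) - sum(d)) / sum(d), 0.15)

  empty <- matrix(0L, 10, 10)
  expect_equal(morph_clean(empty, 1, 5), empty + 0)
})

test_that("boundary extraction is erosion-and-subtract", {
  sq <- matrix(0L, 9, 9); sq[3:7, 3:7] <- 1L
  b <- extract_boundary(sq, 1)
  expect_equal(sum(b), 16)              # 5x5 square keeps a 16-px frame
  expect_true(all(b[sq == 0] == 0))     # boundary within mask

  expect_equal(sum(extract_boundary(matrix(0L, 5, 5), 1)), 0)
  single <- matrix(0L, 5, 5); single[3, 3] <- 1L
  expect_equal(extract_boundary(single, 1), single)

  # re-extracting from the boundary stays within the boundary
  b2 <- extract_boundary(b, 1)
  expect_true(all(b2[b == 0] == 0))
})

test_that("connected regions are 8-connected and area-filtered", {
  m <- matrix(0L, 12, 12)
  m[2:4, 2:4] <- 1L
  m[8:10, 8:10] <- 1L
  regs <- connected_regions(m)
  expect_equal(nrow(regs), 2)
  expect_equal(regs$area, c(9, 9))
  expect_equal(regs$centroid_row, c(3, 9))

  diagm <- matrix(0L, 6, 6)
  diagm[2, 2] <- 1L; diagm[3, 3] <- 1L; diagm[4, 4] <- 1L
  expect_equal(nrow(connected_regions(diagm)), 1)

  m3 <- matrix(0L, 8, 8); m3[2, 2:4] <- 1L
  expect_equal(nrow(connected_regions(m3, min_area = 4)), 0)
  expect_equal(nrow(connected_regions(m3, min_area = 3)), 1)
})

test_that("watershed splitting separates touching discs", {
  m <- disc_mask(60, 110, 30, 35, 18) | disc_mask(60, 110, 30, 64, 18)
  lab <- split_touching(m * 1L, min_area = 10)
  expect_equal(max(lab), 2)
  regs <- connected_regions((lab == 1) * 1L)
  expect_equal(nrow(regs), 1)
  cents <- sort(vapply(1:2, function(k) mean(which(lab == k, arr.ind = TRUE)[, 2]),
                       numeric(1)))
  expect_lt(abs(cents[1] - 35), 3)
  expect_lt(abs(cents[2] - 64), 3)

  expect_equal(max(split_touching(matrix(0L, 5, 5))), 0)
})
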