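#' Adaptive selection of initial cluster centers
#'
#' Scores every pixel `i` by `P(i) * sum_{j in N(i)} 1 / (||H(i) - H(j)|| +
#' density_epsilon)` where `N(i)` is the square spatial neighborhood of
#' half-width `neighborhood_radius` and `P(i)` is a uniform candidate
#' indicator, then returns the `k` highest-scoring pixels' feature vectors
#' subject to a minimum pairwise separation in feature space. High scores
#' mark pixels inside large homogeneous regions, so the selected centers land
#' in the dominant feature modes (fruit, foliage, shadow) instead of on noise
#' or region boundaries, which is what makes the subsequent K-Means stable.
#'
#' @param features matrix `[height, width]` (single feature plane, e.g. hue)
#'   or array `[height, width, n]` of per-pixel feature vectors.
#' @param k number of centers, `>= 1`.
#' @param neighborhood_radius spatial half-width of `N(i)` in pixels
#'   (default 2, a 5x5 window).
#' @param density_epsilon small positive guard added to feature distances
#'   before taking reciprocals.
#' @param min_separation minimum pairwise distance between selected centers
#'   in feature units; default `range/(3k)` of the observed feature span.
#' @return matrix `k x n` of center feature vectors, with attribute
#'   `"pixel"` giving the linear index of each selected pixel.
#' @export
select_initial_centers <- function(features, k, neighborhood_radius = 2,
                                   density_epsilon = 1e-3,
                                   min_separation = NULL) {
  stopifnot(k >= 1, neighborhood_radius >= 1, density_epsilon > 0)
  if (is.matrix(features)) features <- array(features, c(dim(features), 1L))
  h <- dim(features)[1]; w <- dim(features)[2]; nf <- dim(features)[3]
  score <- matrix(0, h, w)
  r <- as.integer(neighborhood_radius)
  for (dr in -r:r) for (dc in -r:r) {
    if (dr == 0 && dc == 0) next
    if (nf == 1L) {
      fm <- features[, , 1]
      dist1 <- abs(fm - .shift_mat(fm, dr, dc))
    } else {
      d2 <- matrix(0, h, w)
      for (m in seq_len(nf)) {
        fm <- features[, , m]
        d2 <- d2 + (fm - .shift_mat(fm, dr, dc))^2
      }
      dist1 <- sqrt(d2)
    }
    score <- score + 1 / (dist1 + density_epsilon)
  }
  fmat <- matrix(features, h * w, nf)
  if (is.null(min_separation)) {
    span <- max(apply(fmat, 2, function(x) diff(range(x))))
    min_separation <- span / (3 * k)
  }
  if (k > 1 && min_separation <= 0)
    stop("degenerate image: no feature separation available for k >= 2",
         call. = FALSE)
  ord <- order(score, decreasing = TRUE)
  chosen <- integer(0)
  for (idx in ord) {
    if (length(chosen) == 0) {
      chosen <- idx
    } else {
      dmin <- min(sqrt(colSums((t(fmat[chosen, , drop = FALSE]) -
                                  fmat[idx, ])^2)))
      if (dmin >= min_separation) chosen <- c(chosen, idx)
    }
    if (length(chosen) == k) break
  }
  if (length(chosen) < k)
    stop("degenerate image: fewer than k separable cluster-center candidates",
         call. = FALSE)
  centers <- fmat[chosen, , drop = FALSE]
  attr(centers, "pixel") <- chosen
  centers
}

#' Weighted Euclidean distance between feature vectors
#'
#' `sqrt(sum_m w_m * (x_m - y_m)^2)`: the distance that drives cluster
#' assignment, letting individual feature planes (hue, intensity, ...) be
#' emphasised or switched off.
#'
#' @param x,y numeric feature vectors of equal length.
#' @param weights nonnegative per-dimension weights, recycled if scalar.
#' @return nonnegative scalar distance.
#' @export
weighted_distance <- function(x, y, weights = 1) {
  if (length(x) != length(y))
    stop("feature dimension mismatch", call. = FALSE)
  weights <- rep_len(weights, length(x))
  if (any(weights < 0)) stop("weights must be nonnegative", call. = FALSE)
  sqrt(sum(weights * (x - y)^2))
}

# Lloyd iterations on an n x nf feature matrix with per-dimension weights and
# optional per-point multiplicities (used by the binned 1-D fast path).
# Ties in assignment break to the lowest cluster index; an emptied cluster is
# re-seeded at the point farthest from its assigned center.
.lloyd <- function(fmat, centers, weights, max_iter, tol, counts = NULL) {
  n <- nrow(fmat); nf <- ncol(fmat); k <- nrow(centers)
  if (is.null(counts)) counts <- rep(1, n)
  wss_trace <- numeric(0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    d2 <- matrix(0, n, k)
    for (j in seq_len(k)) {
      acc <- 0
      for (m in seq_len(nf))
        acc <- acc + weights[m] * (fmat[, m] - centers[j, m])^2
      d2[, j] <- acc
    }
    labels <- max.col(-d2, ties.method = "first")
    best <- d2[cbind(seq_len(n), labels)]
    wss_trace <- c(wss_trace, sum(counts * best))
    new_centers <- centers
    for (j in seq_len(k)) {
      sel <- labels == j
      if (!any(sel)) {
        far <- which.max(best)
        new_centers[j, ] <- fmat[far, ]
        next
      }
      cw <- counts[sel]
      new_centers[j, ] <- colSums(fmat[sel, , drop = FALSE] * cw) / sum(cw)
    }
    move <- max(abs(new_centers - centers))
    centers <- new_centers
    if (move < tol || iter >= max_iter) break
  }
  list(labels = labels, centers = centers, iterations = iter,
       wss = wss_trace)
}

#' Segment an image by weighted K-Means in feature space
#'
#' Runs batch Lloyd iterations under the weighted Euclidean distance until
#' the largest center movement falls below `tol` or `max_iter` is reached.
#' Centers default to the adaptive density-based initialization of
#' [select_initial_centers()]. The weighted within-cluster sum of squares is
#' non-increasing across iterations; assignment ties break deterministically
#' to the lowest cluster index.
#'
#' For a single feature plane on large images the iteration runs on a binned
#' histogram of the feature (bin width `bin_width`, default 0.05 feature
#' units), which is numerically indistinguishable for hue data and removes
#' the dependence of runtime on image size.
#'
#' @param features matrix `[h, w]` or array `[h, w, n]` of features.
#' @param k number of clusters (`>= 2` for segmentation; default 3: fruit,
#'   foliage, background/shadow).
#' @param weights nonnegative per-dimension feature weights.
#' @param max_iter,tol convergence controls (center movement, feature units).
#' @param centers optional `k x n` matrix of initial centers (must be
#'   pairwise distinct); default adaptive initialization.
#' @param bin_width histogram resolution of the 1-D fast path; set to 0 to
#'   force exact per-pixel iteration.
#' @return object of class `apple_segmentation`: list with `labels`
#'   (`[h, w]` integer matrix in `1..k`), `centers`, `weights`,
#'   `iterations`, `wss` (per-iteration objective trace).
#' @export
kmeans_segment <- function(features, k = 3, weights = 1, max_iter = 100,
                           tol = 1e-4, centers = NULL, bin_width = 0.05) {
  stopifnot(k >= 1, max_iter >= 1, tol > 0)
  if (is.matrix(features)) features <- array(features, c(dim(features), 1L))
  h <- dim(features)[1]; w <- dim(features)[2]; nf <- dim(features)[3]
  weights <- rep_len(weights, nf)
  if (all(weights == 0)) stop("at least one feature weight must be positive",
                              call. = FALSE)
  if (is.null(centers))
    centers <- select_initial_centers(features, k)
  centers <- matrix(centers, k, nf)
  if (k > 1 && min(stats::dist(centers)) == 0)
    stop("initial centers must be pairwise distinct", call. = FALSE)
  fmat <- matrix(features, h * w, nf)
  use_bins <- nf == 1L && bin_width > 0 && h * w > 30000L
  if (use_bins) {
    lo <- min(fmat)
    bin <- as.integer(floor((fmat[, 1] - lo) / bin_width))
    tab <- tabulate(bin + 1L, nbins = max(bin) + 1L)
    nz <- which(tab > 0L)
    vals <- lo + (nz - 1 + 0.5) * bin_width
    fit <- .lloyd(matrix(vals, ncol = 1), centers, weights, max_iter, tol,
                  counts = tab[nz])
    bin_label <- integer(max(bin) + 1L)
    bin_label[nz] <- fit$labels
    labels <- matrix(bin_label[bin + 1L], h, w)
  } else {
    fit <- .lloyd(fmat, centers, weights, max_iter, tol)
    labels <- matrix(fit$labels, h, w)
  }
  structure(list(labels = labels, centers = fit$centers, weights = weights,
                 iterations = fit$iterations, wss = fit$wss, k = k),
            class = "apple_segmentation")
}

#' @export
print.apple_segmentation <- function(x, ...) {
  cat(sprintf("<apple_segmentation> k = %d, %d iterations, final WSS %.4g\n",
              x$k, x$iterations, utils::tail(x$wss, 1)))
  cat("centers:\n"); print(round(x$centers, 3))
  invisible(x)
}

#' Pick the foreground (fruit) cluster of a segmentation
#'
#' The fruit cluster is the one whose center hue lies closest (circularly)
#' to the variety's reference hue.
#'
#' @param seg an `apple_segmentation` whose first feature dimension is hue
#'   in degrees.
#' @param hue_ref apple reference hue in degrees (0 red, ~100 green fruit).
#' @return binary `[h, w]` matrix: 1 where the fruit cluster was assigned.
#' @export
foreground_mask <- function(seg, hue_ref = 0) {
  stopifnot(inherits(seg, "apple_segmentation"))
  fg <- which.min(.circ_dist(seg$centers[, 1], hue_ref))
  (seg$labels == fg) * 1L
}

#' Morphological cleanup of a binary mask
#'
#' Opening followed by closing with a disc structuring element, then removal
#' of connected components smaller than `min_area`: speckle noise disappears
#' and fruit contours are restored without eroding large regions.
#'
#' @param mask binary matrix (nonzero = foreground).
#' @param selem_radius radius of the disc structuring element in pixels.
#' @param min_area minimum surviving component area in px^2.
#' @return cleaned binary matrix.
#' @export
morph_clean <- function(mask, selem_radius = 2, min_area = 0) {
  m <- (mask != 0) * 1
  if (selem_radius >= 1) {
    kern <- EBImage::makeBrush(2 * as.integer(selem_radius) + 1L, shape = "disc")
    m <- EBImage::closing(EBImage::opening(m, kern), kern)
  }
  if (min_area > 0) {
    lab <- .label8(m)
    areas <- tabulate(lab[lab > 0L])
    keep <- which(areas >= min_area)
    m <- matrix(as.integer(lab %in% keep), nrow(m), ncol(m))
  }
  m
}

#' Extract region boundaries by erosion and subtraction
#'
#' `boundary = mask AND NOT erode(mask)` with a disc structuring element of
#' the given radius: a thin contour fully contained in the mask.
#'
#' @param mask binary matrix.
#' @param selem_radius erosion disc radius in pixels.
#' @return binary boundary matrix (subset of `mask`).
#' @export
extract_boundary <- function(mask, selem_radius = 1) {
  m <- (mask != 0) * 1
  kern <- EBImage::makeBrush(2 * as.integer(selem_radius) + 1L, shape = "disc")
  er <- EBImage::erode(m, kern)
  (m == 1 & er == 0) * 1L
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so labels touching
# diagonally are merged afterwards with a union-find pass.
.label8 <- function(mask) {
  m <- (mask != 0) * 1
  lab <- EBImage::bwlabel(m)
  nl <- max(lab)
  if (nl <= 1L) return(matrix(as.integer(lab), nrow(m), ncol(m)))
  parent <- seq_len(nl)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  unite <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  for (off in list(c(1L, 1L), c(1L, -1L))) {
    a <- lab[1:(nrow(lab) - 1L), , drop = FALSE]
    if (off[2] == 1L) {
      a <- a[, 1:(ncol(lab) - 1L), drop = FALSE]
      b <- lab[2:nrow(lab), 2:ncol(lab), drop = FALSE]
    } else {
      a <- a[, 2:ncol(lab), drop = FALSE]
      b <- lab[2:nrow(lab), 1:(ncol(lab) - 1L), drop = FALSE]
    }
    sel <- a > 0L & b > 0L & a != b
    if (any(sel)) {
      pairs <- unique(cbind(a[sel], b[sel]))
      for (p in seq_len(nrow(pairs))) unite(pairs[p, 1], pairs[p, 2])
    }
  }
  root <- vapply(seq_len(nl), find, integer(1))
  compact <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0L] <- compact[lab[lab > 0L]]
  matrix(as.integer(out), nrow(m), ncol(m))
}

# Region table from an integer label matrix.
.regions_from_labels <- function(labels, min_area = 0) {
  nl <- max(labels)
  empty <- data.frame(label = integer(0), area = numeric(0),
                      perimeter = numeric(0), centroid_row = numeric(0),
                      centroid_col = numeric(0), bbox_r1 = integer(0),
                      bbox_r2 = integer(0), bbox_c1 = integer(0),
                      bbox_c2 = integer(0))
  if (nl == 0L) {
    attr(empty, "labels") <- labels
    return(empty)
  }
  idx <- which(labels > 0L)
  lab <- labels[idx]
  rr <- ((idx - 1L) %% nrow(labels)) + 1L
  cc <- ((idx - 1L) %/% nrow(labels)) + 1L
  area <- tabulate(lab, nbins = nl)
  sum_r <- rowsum(as.numeric(rr), lab)[, 1]
  sum_c <- rowsum(as.numeric(cc), lab)[, 1]
  present <- which(area > 0)
  r1 <- tapply(rr, lab, min); r2 <- tapply(rr, lab, max)
  c1 <- tapply(cc, lab, min); c2 <- tapply(cc, lab, max)
  out <- data.frame(label = present, area = area[present],
                    perimeter = NA_real_,
                    centroid_row = sum_r[as.character(present)] / area[present],
                    centroid_col = sum_c[as.character(present)] / area[present],
                    bbox_r1 = as.integer(r1[as.character(present)]),
                    bbox_r2 = as.integer(r2[as.character(present)]),
                    bbox_c1 = as.integer(c1[as.character(present)]),
                    bbox_c2 = as.integer(c2[as.character(present)]))
  keep <- out$area >= min_area
  if (!all(keep)) {
    dropped <- out$label[!keep]
    labels[labels %in% dropped] <- 0L
  }
  out <- out[keep, , drop = FALSE]
  for (i in seq_len(nrow(out))) {
    crop <- labels[out$bbox_r1[i]:out$bbox_r2[i],
                   out$bbox_c1[i]:out$bbox_c2[i], drop = FALSE]
    out$perimeter[i] <- .ms_perimeter(crop == out$label[i])
  }
  rownames(out) <- NULL
  attr(out, "labels") <- labels
  out
}

#' Connected-region extraction
#'
#' 8-connected component labeling of a binary mask; components below
#' `min_area` are dropped. Each region carries area, marching-squares
#' perimeter, centroid and bounding box; the full label matrix is attached
#' as attribute `"labels"`.
#'
#' @param mask binary matrix.
#' @param min_area minimum region area in px^2.
#' @return data frame of regions (see above).
#' @export
connected_regions <- function(mask, min_area = 0) {
  .regions_from_labels(.label8(mask), min_area = min_area)
}

#' Split touching fruit regions with a distance-transform watershed
#'
#' Overlapping apples segment into one merged blob; the watershed of the
#' mask's Euclidean distance transform recovers one region per fruit because
#' each fruit contributes its own distance peak. `tolerance` is the minimum
#' peak height difference (in pixels of distance) for two peaks to found
#' separate regions, guarding against over-segmentation from boundary noise.
#'
#' @param mask binary matrix.
#' @param tolerance watershed merging tolerance in distance-map units.
#' @param min_area minimum region area in px^2 after splitting.
#' @param smooth_sigma Gaussian smoothing of the distance map before the
#'   watershed, suppressing spurious peaks from ragged region boundaries.
#' @return integer label matrix (0 = background).
#' @export
split_touching <- function(mask, tolerance = 1, min_area = 0,
                           smooth_sigma = 1, refine_circ = 0.88,
                           refine_tolerance = 0.3, max_depth = 3) {
  m <- (mask != 0) * 1
  if (!any(m == 1)) return(matrix(0L, nrow(m), ncol(m)))
  ws_pass <- function(bin, tol) {
    dm <- EBImage::distmap(bin)
    ksize <- 2 * ceiling(3 * smooth_sigma) + 1
    if (smooth_sigma > 0 && min(dim(bin)) > ksize) {
      dm <- EBImage::gblur(dm, smooth_sigma)
      dm[bin == 0] <- 0
    }
    matrix(as.integer(EBImage::watershed(dm, tolerance = tol, ext = 1)),
           nrow(bin), ncol(bin))
  }
  lab <- ws_pass(m, tolerance)
  # adaptive refinement: a clean single fruit is near-circular, so regions
  # with low circularity are still merged chains; re-run the watershed on
  # their own distance map with a finer tolerance, recursively
  queue <- data.frame(label = seq_len(max(lab)), depth = 0L)
  next_label <- max(lab) + 1L
  while (nrow(queue)) {
    lb <- queue$label[1]; depth <- queue$depth[1]
    queue <- queue[-1, , drop = FALSE]
    if (depth >= max_depth) next
    idx <- which(lab == lb)
    if (length(idx) < max(2 * min_area, 4)) next
    rr <- range(((idx - 1L) %% nrow(lab)) + 1L)
    cr <- range(((idx - 1L) %/% nrow(lab)) + 1L)
    sub <- lab[rr[1]:rr[2], cr[1]:cr[2], drop = FALSE] == lb
    circ <- min(1, 4 * pi * sum(sub) / .ms_perimeter(sub)^2)
    if (circ >= refine_circ) next
    ws2 <- ws_pass(sub * 1, refine_tolerance)
    child_areas <- tabulate(ws2[ws2 > 0L])
    min_child <- max(min_area, 0.12 * length(idx))
    kids <- which(child_areas >= min_child)
    if (length(kids) < 2) next
    crop <- lab[rr[1]:rr[2], cr[1]:cr[2], drop = FALSE]
    for (kd in kids) {
      crop[sub & ws2 == kd] <- next_label
      queue <- rbind(queue, data.frame(label = next_label,
                                       depth = depth + 1L))
      next_label <- next_label + 1L
    }
    # fragments below min_child join the nearest (first) kept child
    leftover <- sub & !(ws2 %in% kids)
    if (any(leftover)) crop[leftover] <- next_label - length(kids)
    lab[rr[1]:rr[2], cr[1]:cr[2]] <- crop
  }
  # compact labels
  if (max(lab) > 0L) {
    present <- sort(unique(lab[lab > 0L]))
    lab[lab > 0L] <- match(lab[lab > 0L], present)
  }
  if (min_area > 0) {
    areas <- tabulate(lab[lab > 0L])
    drop <- which(areas < min_area)
    if (length(drop)) lab[lab %in% drop] <- 0L
  }
  lab
}

# Default min_area scaling: 50 px^2 at 1920x1080, proportional to image area.
.default_min_area <- function(h, w) 50 * (h * w) / (1920 * 1080)
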