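#' Dense stereo block matching
#'
#' For every left-image pixel, finds the horizontal disparity in
#' `[0, max_disparity]` minimizing the sum of absolute differences over a
#' square block along the same (rectified) row, refines the minimum to
#' sub-pixel precision with an equiangular three-point fit, and invalidates pixels
#' that fail a left-right consistency check (1 px), have a flat cost curve
#' (textureless) or match at zero disparity (background at infinity).
#'
#' @param left,right grayscale matrices of equal size, row-rectified.
#' @param block odd block side length in pixels.
#' @param max_disparity maximum disparity searched, `< image width`.
#' @param lr_check apply the left-right consistency test.
#' @param subpixel apply sub-pixel refinement.
#' @return object of class `disparity_map`: list with `disparity` (matrix,
#'   `NA` where invalid) and `valid` (logical matrix).
#' @export
block_match <- function(left, right, block = 9, max_disparity = 64,
                        lr_check = TRUE, subpixel = TRUE) {
  .validate_gray(left); .validate_gray(right)
  stopifnot(all(dim(left) == dim(right)))
  .stopifnot_odd(block, "block")
  h <- nrow(left); w <- ncol(left)
  if (block > min(h, w)) stop("block larger than image", call. = FALSE)
  if (max_disparity >= w) stop("max_disparity must be < image width", call. = FALSE)
  r <- (block - 1L) / 2L
  big <- 1e12  # sentinel cost; large vs any SAD yet safe under cumsum

  best <- matrix(Inf, h, w); bestd <- matrix(-1L, h, w)
  cminus <- matrix(NA_real_, h, w); cplus <- matrix(NA_real_, h, w)
  cmax <- matrix(-Inf, h, w)
  bestR <- matrix(Inf, h, w); bestdR <- matrix(-1L, h, w)
  prev_sad <- NULL
  for (d in 0:max_disparity) {
    shifted <- .shift_mat(right, 0L, d)
    diffm <- abs(left - shifted)
    if (d > 0) diffm[, 1:d] <- big   # no right-image support
    sad <- .box_sum(diffm, r)
    # fill c(d+1) for pixels whose best was found at d-1
    pend <- bestd == d - 1L & is.na(cplus)
    if (any(pend)) cplus[pend] <- sad[pend]
    upd <- sad < best
    if (any(upd)) {
      bestd[upd] <- d
      best[upd] <- sad[upd]
      cminus[upd] <- if (is.null(prev_sad)) NA_real_ else prev_sad[upd]
      cplus[upd] <- NA_real_
    }
    cmax <- pmax(cmax, sad)
    if (lr_check) {
      # cost for right pixel (i, j) at disparity d equals left cost at j + d
      sadR <- .shift_mat(sad, 0L, -d)
      if (d > 0) sadR[, (w - d + 1L):w] <- big
      updR <- sadR < bestR
      bestdR[updR] <- d
      bestR[updR] <- sadR[updR]
    }
    prev_sad <- sad
  }
  disp <- bestd + 0
  if (subpixel) {
    # equiangular (two-line) refinement: exact for the V-shaped cost curve
    # of an L1 block cost under linear resampling
    den <- pmax(cminus, cplus) - best
    ok <- !is.na(cminus) & !is.na(cplus) & is.finite(cminus) &
      is.finite(cplus) & den > 0
    delta <- matrix(0, h, w)
    delta[ok] <- .clamp(0.5 * (cminus[ok] - cplus[ok]) / den[ok], -0.5, 0.5)
    disp <- disp + delta
  }
  valid <- bestd > 0L & is.finite(best) & (cmax - best) > 1e-9 * block^2
  if (lr_check) {
    jj <- matrix(seq_len(w), h, w, byrow = TRUE)
    jr <- jj - bestd
    ok_idx <- valid & jr >= 1L
    lin <- cbind(which(ok_idx, arr.ind = TRUE)[, 1],
                 jr[ok_idx])
    dr <- bestdR[lin]
    consistent <- abs(bestd[ok_idx] - dr) <= 1
    v2 <- valid
    v2[ok_idx] <- consistent
    v2[valid & jr < 1L] <- FALSE
    valid <- v2
  }
  disp[!valid] <- NA_real_
  structure(list(disparity = disp, valid = valid, block = block,
                 max_disparity = max_disparity),
            class = "disparity_map")
}

#' @export
print.disparity_map <- function(x, ...) {
  cat(sprintf("<disparity_map> %d x %d px, %.1f%% valid, median %.2f px\n",
              nrow(x$disparity), ncol(x$disparity), 100 * mean(x$valid),
              stats::median(x$disparity[x$valid])))
  invisible(x)
}

#' Disparity to depth by triangulation
#'
#' `Z = f * B / d` for a rectified rig; nonpositive or missing disparities
#' give `NA` depth.
#'
#' @param d disparity in pixels (vectorized).
#' @param rig a [stereo_rig()].
#' @return depth in millimetres.
#' @export
disparity_to_depth <- function(d, rig) {
  stopifnot(inherits(rig, "stereo_rig"))
  out <- rig$focal_px * rig$baseline_mm / d
  out[!is.finite(out) | d <= 0] <- NA_real_
  out
}

#' Back-project a pixel with known depth to camera coordinates
#'
#' `X = (col - c_col) * Z / f`, `Y = (row - c_row) * Z / f`, left-camera
#' frame, X right, Y down, Z forward.
#'
#' @param pixel `(row, col)` or an `n x 2` matrix of pixel coordinates.
#' @param Z depth(s) in millimetres, `> 0`.
#' @param rig a [stereo_rig()].
#' @return numeric `(X, Y, Z)` or an `n x 3` matrix, in millimetres.
#' @export
pixel_to_3d <- function(pixel, Z, rig) {
  stopifnot(inherits(rig, "stereo_rig"), all(Z > 0, na.rm = TRUE))
  p <- if (is.matrix(pixel)) pixel else matrix(pixel, ncol = 2)
  X <- (p[, 2] - rig$principal_point[2]) * Z / rig$focal_px
  Y <- (p[, 1] - rig$principal_point[1]) * Z / rig$focal_px
  out <- cbind(X = X, Y = Y, Z = Z)
  if (nrow(out) == 1L) out[1, ] else out
}

#' Fill occluded or unmatched depth pixels
#'
#' Invalid pixels are filled by linear interpolation along rows, then along
#' columns for anything left, then by nearest-valid propagation; valid
#' pixels are never modified. This mirrors the morphological-closing plus
#' interpolation treatment of occlusion holes.
#'
#' @param depth depth matrix in mm (values at invalid pixels ignored).
#' @param valid logical matrix of trustworthy pixels.
#' @return depth matrix with every pixel filled.
#' @export
fill_occluded_depth <- function(depth, valid) {
  stopifnot(all(dim(depth) == dim(valid)))
  if (!any(valid)) stop("no valid depth pixels to interpolate from", call. = FALSE)
  out <- depth
  out[!valid] <- NA_real_
  interp_vec <- function(v) {
    ok <- !is.na(v)
    if (sum(ok) == 0) return(v)
    if (sum(ok) == 1) { v[!ok] <- v[ok]; return(v) }
    filled <- stats::approx(which(ok), v[ok], xout = seq_along(v),
                            rule = 2)$y
    v[!ok] <- filled[!ok]
    v
  }
  out <- t(apply(out, 1, interp_vec))
  if (anyNA(out)) out <- apply(out, 2, interp_vec)
  while (anyNA(out)) {  # isolated corners: nearest-valid propagation
    na_idx <- is.na(out)
    nb <- list(.shift_mat(out, 1, 0), .shift_mat(out, -1, 0),
               .shift_mat(out, 0, 1), .shift_mat(out, 0, -1))
    acc <- matrix(0, nrow(out), ncol(out)); cnt <- matrix(0, nrow(out), ncol(out))
    for (m in nb) {
      good <- !is.na(m)
      acc[good] <- acc[good] + m[good]
      cnt <- cnt + good
    }
    fill <- na_idx & cnt > 0
    out[fill] <- acc[fill] / cnt[fill]
  }
  out
}

#' Euclidean 3D localization error
#'
#' `E = sqrt((dX)^2 + (dY)^2 + (dZ)^2)` between a real and a computed 3D
#' position.
#'
#' @param real,calc numeric `(X, Y, Z)` in millimetres.
#' @return error in millimetres.
#' @export
localization_error <- function(real, calc) {
  sqrt(sum((as.numeric(real) - as.numeric(calc))^2))
}

# Sub-pixel horizontal image shift, R(i,j) = L(i, j+d), using Catmull-Rom
# cubic interpolation (closer to band-limited resampling than linear).
.shift_subpixel <- function(img, d) {
  w <- ncol(img)
  j <- seq_len(w) + d
  j1 <- .clamp(floor(j), 1, w)
  t <- j - floor(j)
  jm <- .clamp(j1 - 1, 1, w); j2 <- .clamp(j1 + 1, 1, w)
  j3 <- .clamp(j1 + 2, 1, w)
  tm <- t[col(img)]
  p0 <- img[, jm, drop = FALSE]; p1 <- img[, j1, drop = FALSE]
  p2 <- img[, j2, drop = FALSE]; p3 <- img[, j3, drop = FALSE]
  0.5 * ((2 * p1) + (-p0 + p2) * tm + (2 * p0 - 5 * p1 + 4 * p2 - p3) * tm^2 +
           (-p0 + 3 * p1 - 3 * p2 + p3) * tm^3)
}

#' Stereo depth validation protocol
#'
#' Renders a textured planar calibration target at each requested distance,
#' shifts it by the exact sub-pixel disparity `f * B / Z` to form the right
#' view, recovers disparity by block matching with sub-pixel refinement at
#' `n_points` sample points, perturbs the measured disparities with Gaussian
#' noise of `noise_sigma_px`, and reports the per-point relative depth
#' error.
#'
#' @param rig a [stereo_rig()].
#' @param distances target distances in mm.
#' @param n_points sample points per distance.
#' @param noise_sigma_px disparity measurement noise, px.
#' @param seed optional RNG seed for texture and noise.
#' @param target_size `(height, width)` of the rendered target in px.
#' @param block block-matching window.
#' @return data frame `(distance_mm, point_id, z_true, z_calc, rel_err_pct)`.
#' @export
depth_validation_run <- function(rig = stereo_rig(),
                                 distances = c(800, 900, 1000, 1100),
                                 n_points = 6, noise_sigma_px = 0.2,
                                 seed = NULL, target_size = c(96, 160),
                                 block = 9) {
  stopifnot(all(distances > 0), n_points >= 1)
  if (!is.null(seed)) set.seed(seed)
  h <- target_size[1]; w <- target_size[2]
  r <- (block - 1L) / 2L
  # SAD of the block around (i, j) against the right image resampled at a
  # fractional disparity (cubic interpolation along the row)
  frac_cost <- function(left, right, i, j, d) {
    lw <- left[(i - r):(i + r), (j - r):(j + r)]
    p <- (j - r):(j + r) - d
    j1 <- floor(p); t <- p - j1
    wx <- ncol(right)
    cl <- function(x) .clamp(x, 1, wx)
    rw <- right[(i - r):(i + r), , drop = FALSE]
    p0 <- rw[, cl(j1 - 1)]; p1 <- rw[, cl(j1)]
    p2 <- rw[, cl(j1 + 1)]; p3 <- rw[, cl(j1 + 2)]
    tm <- matrix(t, block, block, byrow = TRUE)
    rwin <- 0.5 * ((2 * p1) + (-p0 + p2) * tm +
                     (2 * p0 - 5 * p1 + 4 * p2 - p3) * tm^2 +
                     (-p0 + 3 * p1 - 3 * p2 + p3) * tm^3)
    sum(abs(lw - rwin))
  }
  out <- NULL
  for (z in distances) {
    d_true <- rig$focal_px * rig$baseline_mm / z
    tex <- .gauss_smooth(matrix(stats::runif(h * w, 0, 255), h, w), 1)
    right <- .shift_subpixel(tex, d_true)
    dm <- block_match(tex, right, block = block,
                      max_disparity = as.integer(ceiling(d_true)) + 4L,
                      lr_check = FALSE)
    margin <- block + 2
    ok_cols <- seq(ceiling(d_true) + margin, w - margin)
    ok_rows <- seq(margin, h - margin)
    cand <- expand.grid(row = ok_rows, col = ok_cols)
    cand <- cand[dm$valid[as.matrix(cand)], , drop = FALSE]
    pick <- cand[round(seq(1, nrow(cand), length.out = n_points)), ]
    # refine each corner point on a fine fractional-disparity grid around
    # the integer minimum, avoiding the pixel-locking of 3-point fits
    d_pt <- vapply(seq_len(n_points), function(k) {
      d0 <- round(dm$disparity[pick$row[k], pick$col[k]])
      grid <- seq(d0 - 1, d0 + 1, by = 0.005)
      costs <- vapply(grid, function(d)
        frac_cost(tex, right, pick$row[k], pick$col[k], d), numeric(1))
      grid[which.min(costs)]
    }, numeric(1))
    d_meas <- d_pt + stats::rnorm(n_points, 0, noise_sigma_px)
    z_calc <- disparity_to_depth(d_meas, rig)
    out <- rbind(out, data.frame(distance_mm = z, point_id = seq_len(n_points),
                                 z_true = z, z_calc = z_calc,
                                 rel_err_pct = 100 * abs(z_calc - z) / z))
  }
  rownames(out) <- NULL
  out
}

#' Triangulate detected apples to 3D camera coordinates
#'
#' For each detection, block-matches a horizontal strip around the fruit,
#' takes the median sub-pixel disparity over the fruit's interior disc
#' (robust to occluded or unmatched pixels), triangulates depth and
#' back-projects the detection centroid. Detections with no valid disparity
#' get `NA` coordinates.
#'
#' @param detections an `apple_detections` data frame.
#' @param gray_left,gray_right rectified grayscale stereo pair.
#' @param rig a [stereo_rig()].
#' @param block block-matching window, px.
#' @param max_disparity search range; defaults to `f * B / 600` (anything
#'   nearer than 600 mm).
#' @param interior fraction of the fitted radius used as the interior disc.
#' @param labels optional segmentation label matrix; when given, the median
#'   disparity is taken over the detection's own segmented pixels (via
#'   `region_id`), which excludes background and occluding fruit from the
#'   depth estimate.
#' @param min_support minimum number of consistency-checked pixels required
#'   to report a depth; below it the fruit is treated as stereo-occluded
#'   and its 3D position stays `NA`.
#' @return `detections` with added columns `disparity_px`, `X_mm`, `Y_mm`,
#'   `Z_mm`.
#' @export
locate_apples_3d <- function(detections, gray_left, gray_right,
                             rig = stereo_rig(), block = 9,
                             max_disparity = NULL, interior = 0.7,
                             labels = NULL, min_support = 20) {
  stopifnot(nrow(gray_left) == nrow(gray_right))
  h <- nrow(gray_left); w <- ncol(gray_left)
  if (is.null(max_disparity))
    max_disparity <- ceiling(rig$focal_px * rig$baseline_mm / 600)
  detections$disparity_px <- NA_real_
  detections$X_mm <- NA_real_; detections$Y_mm <- NA_real_
  detections$Z_mm <- NA_real_
  r2 <- (block - 1) / 2
  big <- 1e12
  for (i in seq_len(nrow(detections))) {
    r0 <- detections$row[i]; c0 <- detections$col[i]
    rad <- detections$radius[i]
    own_global <- NULL
    if (!is.null(labels) && "region_id" %in% names(detections)) {
      own_global <- labels == detections$region_id[i]
      idx <- which(own_global)
      rrg <- range(((idx - 1L) %% h) + 1L)
      crg <- range(((idx - 1L) %/% h) + 1L)
    } else {
      rrg <- c(floor(r0 - rad), ceiling(r0 + rad))
      crg <- c(floor(c0 - rad), ceiling(c0 + rad))
    }
    pad <- r2 + 2L
    rows <- max(1, rrg[1] - pad):min(h, rrg[2] + pad)
    # the crop extends right by the search range so that the left-right
    # consistency test sees every left column competing for a right pixel
    cols <- max(1, crg[1] - pad):min(w, crg[2] + pad + max_disparity)
    dmax <- min(max_disparity, max(cols) - 1L)
    if (dmax < 1) next
    nr <- length(rows); nc <- length(cols)
    rc_lo <- max(1L, min(cols) - dmax)
    rcols <- rc_lo:max(cols)
    Lc <- gray_left[rows, cols, drop = FALSE]
    best <- matrix(Inf, nr, nc); bestd <- matrix(-1, nr, nc)
    cminus <- matrix(NA_real_, nr, nc); cplus <- matrix(NA_real_, nr, nc)
    bestR <- matrix(Inf, nr, length(rcols))
    bestdR <- matrix(-1, nr, length(rcols))
    prev <- NULL
    for (d in 0:dmax) {
      cshift <- .clamp(cols - d, 1L, w)
      Rc <- gray_right[rows, cshift, drop = FALSE]
      diffm <- abs(Lc - Rc)
      bad <- cols - d < 1L
      if (any(bad)) diffm[, bad] <- big
      sad <- .box_sum(diffm, r2)
      pend <- bestd == d - 1 & is.na(cplus)
      cplus[pend] <- sad[pend]
      upd <- sad < best
      bestd[upd] <- d
      best[upd] <- sad[upd]
      cminus[upd] <- if (is.null(prev)) NA_real_ else prev[upd]
      cplus[upd] <- NA_real_
      prev <- sad
      # right-view winner bookkeeping: cost of right col (cols - d) at
      # disparity d equals this sad
      tr <- cols - d - rc_lo + 1L
      okc <- !bad & tr >= 1L
      if (any(okc)) {
        sub <- sad[, okc, drop = FALSE]
        cur <- bestR[, tr[okc], drop = FALSE]
        updR <- sub < cur
        if (any(updR)) {
          tmp <- bestR[, tr[okc], drop = FALSE]; tmp[updR] <- sub[updR]
          bestR[, tr[okc]] <- tmp
          tmpd <- bestdR[, tr[okc], drop = FALSE]; tmpd[updR] <- d
          bestdR[, tr[okc]] <- tmpd
        }
      }
    }
    den <- pmax(cminus, cplus) - best
    ok <- !is.na(den) & is.finite(den) & den > 0
    delta <- matrix(0, nr, nc)
    delta[ok] <- .clamp(0.5 * (cminus[ok] - cplus[ok]) / den[ok], -0.5, 0.5)
    dsub <- bestd + delta
    # left-right consistency: the right-view winner at the matched right
    # column must agree within 1 px
    tr_all <- matrix(cols, nr, nc, byrow = TRUE) - bestd - rc_lo + 1L
    lin_ok <- bestd > 0 & tr_all >= 1L & tr_all <= length(rcols)
    consistent <- matrix(FALSE, nr, nc)
    if (any(lin_ok)) {
      rows_idx <- matrix(seq_len(nr), nr, nc)
      dR <- bestdR[cbind(rows_idx[lin_ok], tr_all[lin_ok])]
      consistent[lin_ok] <- abs(bestd[lin_ok] - dR) <= 1
    }
    matched <- bestd > 0 & is.finite(best) & best < big & consistent
    rr <- matrix(rows, nr, nc)
    cc <- matrix(cols, nr, nc, byrow = TRUE)
    broad <- ((rr - r0)^2 + (cc - c0)^2) <= (interior * rad)^2 & matched
    tight <- broad
    if (!is.null(own_global)) {
      own <- own_global[rows, cols, drop = FALSE]
      # erode by the block radius so matching windows stay clear of
      # occlusion boundaries
      own_er <- EBImage::erode(own * 1, EBImage::makeBrush(block, "box")) == 1
      if (sum(own & matched) >= 9) broad <- own & matched
      tight <- if (sum(own_er & matched) >= 9) own_er & matched else broad
    }
    if (sum(broad) < min_support) next  # depth not measurable
    # disparity values over one fruit are tight; a second cluster means the
    # region mixes two surfaces (bad split across an occlusion), so depth is
    # only trusted when one cluster clearly dominates the whole region
    vals <- sort(dsub[broad])
    brk <- which(diff(vals) > 1.5)
    starts <- c(1L, brk + 1L); ends <- c(brk, length(vals))
    sizes <- ends - starts + 1L
    main <- which.max(sizes)
    if (sizes[main] < 0.7 * length(vals)) next
    lo <- vals[starts[main]] - 0.75; hi <- vals[ends[main]] + 0.75
    tv <- dsub[tight]
    tv <- tv[tv >= lo & tv <= hi]
    if (length(tv) < 9) tv <- vals[starts[main]:ends[main]]
    dmed <- stats::median(tv)
    z <- disparity_to_depth(dmed, rig)
    if (is.na(z)) next
    p3 <- pixel_to_3d(c(r0, c0), z, rig)
    detections$disparity_px[i] <- dmed
    detections$X_mm[i] <- p3[["X"]]
    detections$Y_mm[i] <- p3[["Y"]]
    detections$Z_mm[i] <- p3[["Z"]]
  }
  detections
}
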