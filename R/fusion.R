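#' Fusion weights for colour, texture and morphology
#'
#' The composite recognition score is `T = a1 * colour + a2 * texture +
#' a3 * shape`; weights are normalized to sum to one at construction. The
#' defaults favour colour, the primary cue of hue-driven segmentation.
#'
#' @param alpha1,alpha2,alpha3 nonnegative weights for colour, GLCM texture
#'   and shape.
#' @return object of class `fusion_weights` (normalized numeric vector).
#' @export
fusion_weights <- function(alpha1 = 0.5, alpha2 = 0.3, alpha3 = 0.2) {
  a <- c(alpha1, alpha2, alpha3)
  if (any(a < 0) || sum(a) == 0)
    stop("weights must be nonnegative and not all zero", call. = FALSE)
  structure(a / sum(a), names = c("colour", "texture", "shape"),
            class = "fusion_weights")
}

#' GLCM texture specification
#'
#' @param window odd side length of the analysis window in pixels.
#' @param distance pixel offset of co-occurring pairs.
#' @param angles subset of `c(0, 45, 90, 135)` degrees; statistics are
#'   averaged over angles.
#' @param levels gray quantization levels (`>= 2`).
#' @param statistic `"homogeneity"`, `"energy"` or `"contrast"`.
#' @return object of class `glcm_spec`.
#' @export
glcm_spec <- function(window = 21, distance = 1,
                      angles = c(0, 45, 90, 135), levels = 16,
                      statistic = c("homogeneity", "energy", "contrast")) {
  statistic <- match.arg(statistic)
  .stopifnot_odd(window, "window")
  stopifnot(distance >= 1, levels >= 2, length(angles) >= 1,
            all(angles %in% c(0, 45, 90, 135)))
  structure(list(window = as.integer(window), distance = as.integer(distance),
                 angles = angles, levels = as.integer(levels),
                 statistic = statistic),
            class = "glcm_spec")
}

# Symmetric normalized gray-level co-occurrence matrix for one offset.
.glcm_matrix <- function(q, levels, dr, dc) {
  h <- nrow(q); w <- ncol(q)
  r1 <- max(1L, 1L - dr); r2 <- min(h, h - dr)
  c1 <- max(1L, 1L - dc); c2 <- min(w, w - dc)
  if (r1 > r2 || c1 > c2) return(NULL)
  a <- q[r1:r2, c1:c2]
  b <- q[(r1 + dr):(r2 + dr), (c1 + dc):(c2 + dc)]
  counts <- tabulate(a * levels + b + 1L, nbins = levels * levels)
  m <- matrix(counts, levels, levels, byrow = TRUE)
  m <- m + t(m)
  m / sum(m)
}

#' GLCM texture score of a grayscale window
#'
#' Quantizes the window to `spec$levels` gray levels, builds the symmetric
#' normalized co-occurrence matrix at each requested angle, computes the
#' chosen statistic and averages over angles. Contrast is normalized by its
#' maximum attainable value `(levels - 1)^2` so every statistic lies in
#' `[0, 1]`. Smooth fruit surfaces score high homogeneity/energy; cluttered
#' foliage scores high contrast.
#'
#' @param gray_window grayscale matrix, values in `[0, 255]`.
#' @param spec a [glcm_spec()].
#' @return texture score in `[0, 1]`.
#' @export
glcm_score <- function(gray_window, spec = glcm_spec()) {
  .validate_gray(gray_window)
  d <- spec$distance
  if (nrow(gray_window) <= d && ncol(gray_window) <= d)
    stop("window smaller than the GLCM distance offset", call. = FALSE)
  q <- pmin(floor(gray_window / 256 * spec$levels), spec$levels - 1L)
  storage.mode(q) <- "integer"
  offsets <- list(`0` = c(0L, 1L), `45` = c(-1L, 1L), `90` = c(-1L, 0L),
                  `135` = c(-1L, -1L))
  ii <- matrix(0:(spec$levels - 1L), spec$levels, spec$levels)
  jj <- t(ii)
  vals <- c()
  for (ang in spec$angles) {
    off <- offsets[[as.character(ang)]] * d
    m <- .glcm_matrix(q, spec$levels, off[1], off[2])
    if (is.null(m)) next
    v <- switch(spec$statistic,
                energy = sum(m^2),
                contrast = sum(m * (ii - jj)^2) / (spec$levels - 1L)^2,
                homogeneity = sum(m / (1 + (ii - jj)^2)))
    vals <- c(vals, v)
  }
  if (!length(vals))
    stop("window smaller than the GLCM distance offset", call. = FALSE)
  mean(vals)
}

#' Shape (circularity) score of a region
#'
#' Circularity `4 * pi * area / perimeter^2`, clamped to `[0, 1]`: 1 for a
#' perfect disc, small for elongated artifacts such as branches.
#'
#' @param region one row of a [connected_regions()] table (or any list with
#'   `area` and `perimeter`).
#' @return shape score in `[0, 1]`.
#' @export
shape_score <- function(region) {
  if (region$area <= 0 || region$perimeter <= 0)
    stop("degenerate region: nonpositive area or perimeter", call. = FALSE)
  min(1, 4 * pi * region$area / region$perimeter^2)
}

#' Composite multi-feature recognition score
#'
#' Convex combination `T = a1 * colour + a2 * texture + a3 * shape` deciding
#' whether a candidate region is fruit; monotone in every component and
#' bounded by the component range.
#'
#' @param h_score,glcm,shape component scores in `[0, 1]`.
#' @param weights a [fusion_weights()].
#' @return composite score in `[0, 1]`.
#' @export
composite_score <- function(h_score, glcm, shape, weights = fusion_weights()) {
  comp <- c(h_score, glcm, shape)
  if (any(comp < 0 | comp > 1))
    stop("component scores must lie in [0, 1]", call. = FALSE)
  sum(unclass(weights) * comp)
}

#' Weighted centroid of a region
#'
#' `sum(w * (row, col)) / sum(w)` over the region's pixels, giving sub-pixel
#' centers of mass weighted by per-pixel evidence (here: hue membership).
#'
#' @param mask binary matrix selecting the region's pixels.
#' @param weight_plane matrix of nonnegative weights, same shape.
#' @return numeric `(row, col)`.
#' @export
weighted_centroid <- function(mask, weight_plane = NULL) {
  idx <- which(mask != 0)
  if (!length(idx)) stop("empty region", call. = FALSE)
  w <- if (is.null(weight_plane)) rep(1, length(idx)) else weight_plane[idx]
  if (any(w < 0)) stop("weights must be nonnegative", call. = FALSE)
  tw <- sum(w)
  if (tw <= 0) stop("total weight over region is zero", call. = FALSE)
  rr <- ((idx - 1L) %% nrow(mask)) + 1L
  cc <- ((idx - 1L) %/% nrow(mask)) + 1L
  c(row = sum(w * rr) / tw, col = sum(w * cc) / tw)
}

#' Algebraic least-squares circle fit (Kasa method)
#'
#' Fits `(x - a)^2 + (y - b)^2 = r^2` to points by solving the linear system
#' `2 a x + 2 b y + c = x^2 + y^2`; fast, and exact for points lying on a
#' true circle.
#'
#' @param points `n x 2` matrix of `(row, col)` coordinates, `n >= 3`.
#' @return list with `center` `(row, col)` and `radius`.
#' @export
fit_circle <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3) stop("need at least 3 points", call. = FALSE)
  x <- points[, 1]; y <- points[, 2]
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  qr_A <- qr(A)
  if (qr_A$rank < 3)
    stop("degenerate circle fit: points are collinear", call. = FALSE)
  beta <- qr.coef(qr_A, b)
  center <- c(row = beta[[1]], col = beta[[2]])
  r2 <- beta[[3]] + beta[[1]]^2 + beta[[2]]^2
  if (r2 <= 0) stop("degenerate circle fit", call. = FALSE)
  list(center = center, radius = sqrt(r2))
}

#' Circle fit to a region's outer boundary
#'
#' Extracts the region's boundary pixels, fits a circle by the algebraic
#' least-squares (Kasa) method and adds half a pixel to the radius because
#' boundary pixel centers sit about half a pixel inside the continuous
#' region edge.
#'
#' @param mask binary matrix selecting the region.
#' @return list with `center` `(row, col)` and `radius` in pixels, or
#'   `NULL` when no stable fit exists (degenerate boundary).
#' @export
region_circle <- function(mask) {
  bnd <- which(extract_boundary(mask) == 1L)
  if (length(bnd) < 3) return(NULL)
  pts <- cbind(((bnd - 1L) %% nrow(mask)) + 1L,
               ((bnd - 1L) %/% nrow(mask)) + 1L)
  fit <- tryCatch(fit_circle(pts), error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  fit$radius <- fit$radius + 0.5
  fit
}

# Per-pixel hue membership: 1 at the reference hue, linear falloff to 0 at
# 60 degrees of circular hue distance.
.hue_membership <- function(h, hue_ref) {
  v <- 1 - .circ_dist(h, hue_ref) / 60
  v[v < 0] <- 0
  v
}

#' Detect apples in a segmented image by multi-feature fusion
#'
#' For every candidate region of the foreground mask (optionally after
#' watershed splitting of touching fruit), computes a colour score (circular
#' closeness of the region's mean hue to the variety reference), a GLCM
#' texture score on the region's bounding window and a circularity shape
#' score, fuses them with [composite_score()] and keeps regions reaching
#' `threshold`. Each surviving region yields one detection with a hue-
#' membership-weighted sub-pixel centroid and a circle-fit radius.
#'
#' @param mask binary foreground matrix from the clustering stage.
#' @param hsi an `hsi_image` of the same frame.
#' @param gray grayscale matrix of the same frame.
#' @param weights a [fusion_weights()].
#' @param spec a [glcm_spec()].
#' @param threshold composite-score acceptance threshold in `(0, 1)`.
#' @param hue_ref apple reference hue in degrees.
#' @param min_area minimum region area in px^2 (default scales 50 px^2 at
#'   1920x1080 by image area).
#' @param split split touching fruit with [split_touching()] first.
#' @param split_tolerance watershed tolerance passed to [split_touching()].
#'   Ignored when `mask` is already a label matrix and `split = FALSE`.
#' @return object of class `apple_detections`: data frame with one row per
#'   detection (`id`, `row`, `col`, `radius`, `score`, `region_id`, `area`,
#'   and component scores), label matrix as attribute `"labels"`.
#' @export
detect_apples <- function(mask, hsi, gray, weights = fusion_weights(),
                          spec = glcm_spec(), threshold = 0.6, hue_ref = 0,
                          min_area = NULL, split = TRUE,
                          split_tolerance = 1) {
  stopifnot(inherits(hsi, "hsi_image"), threshold > 0, threshold < 1)
  if (is.null(min_area))
    min_area <- .default_min_area(nrow(gray), ncol(gray))
  labels <- if (split) split_touching(mask, tolerance = split_tolerance,
                                      min_area = min_area)
            else if (max(mask) > 1L) matrix(as.integer(mask), nrow(mask), ncol(mask))
            else .label8(mask)
  regions <- .regions_from_labels(labels, min_area = min_area)
  labels <- attr(regions, "labels")
  wplane <- .hue_membership(hsi$h, hue_ref)
  out <- data.frame(id = integer(0), row = numeric(0), col = numeric(0),
                    radius = numeric(0), score = numeric(0),
                    region_id = integer(0), area = numeric(0),
                    colour_score = numeric(0), texture_score = numeric(0),
                    shape_score = numeric(0))
  for (i in seq_len(nrow(regions))) {
    rg <- regions[i, ]
    crop <- labels[rg$bbox_r1:rg$bbox_r2, rg$bbox_c1:rg$bbox_c2, drop = FALSE]
    rmask <- crop == rg$label
    hue_px <- hsi$h[rg$bbox_r1:rg$bbox_r2, rg$bbox_c1:rg$bbox_c2][rmask]
    mean_hue <- .circ_mean(hue_px)
    h_score <- max(0, 1 - min(.circ_dist(mean_hue, hue_ref), 60) / 60)
    gwin <- gray[rg$bbox_r1:rg$bbox_r2, rg$bbox_c1:rg$bbox_c2, drop = FALSE]
    t_score <- tryCatch(glcm_score(gwin, spec), error = function(e) 0)
    s_score <- shape_score(rg)
    total <- composite_score(h_score, t_score, s_score, weights)
    if (total < threshold) next
    wcrop <- wplane[rg$bbox_r1:rg$bbox_r2, rg$bbox_c1:rg$bbox_c2, drop = FALSE]
    wreg <- wcrop * rmask
    cen <- if (sum(wreg) > 0) weighted_centroid(rmask, wcrop)
           else weighted_centroid(rmask)
    cen <- cen + c(rg$bbox_r1 - 1, rg$bbox_c1 - 1)
    req_r <- sqrt(rg$area / pi)
    radius <- req_r
    fit <- region_circle(rmask)
    if (!is.null(fit) && fit$radius > 0.5 * req_r && fit$radius < 1.8 * req_r)
      radius <- fit$radius
    out <- rbind(out, data.frame(id = nrow(out) + 1L, row = cen[["row"]],
                                 col = cen[["col"]], radius = radius,
                                 score = total, region_id = rg$label,
                                 area = rg$area, colour_score = h_score,
                                 texture_score = t_score,
                                 shape_score = s_score))
  }
  rownames(out) <- NULL
  class(out) <- c("apple_detections", "data.frame")
  attr(out, "labels") <- labels
  out
}

#' @export
`[.apple_detections` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) class(out) <- "data.frame"
  out
}

#' @export
print.apple_detections <- function(x, ...) {
  cat(sprintf("<apple_detections> %d detections\n", nrow(x)))
  if (nrow(x)) {
    df <- as.data.frame(x)[, c("id", "row", "col", "radius", "score")]
    df$row <- round(df$row, 2); df$col <- round(df$col, 2)
    df$radius <- round(df$radius, 2); df$score <- round(df$score, 3)
    print(df, row.names = FALSE)
  }
  invisible(x)
}
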