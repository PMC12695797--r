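# Internal vectorized helpers shared across modules.

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Shift a matrix by (dr, dc): result[i, j] = m[i - dr, j - dc], edges replicated.
.shift_mat <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  ri <- .clamp(seq_len(h) - dr, 1L, h)
  ci <- .clamp(seq_len(w) - dc, 1L, w)
  m[ri, ci, drop = FALSE]
}

# Separable Gaussian smoothing, edge-replicated. Kernel radius = ceil(3 sigma).
.gauss_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(k)) out <- out + k[i] * .shift_mat(m, 0L, i - r - 1L)
  out2 <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(k)) out2 <- out2 + k[i] * .shift_mat(out, i - r - 1L, 0L)
  out2
}

# Exact 3x3 median, edge-replicated (C kernel).
.median3x3 <- function(m) .median3x3_cpp(m)

# Pure-R 3x3 median via a 19-comparator sorting network (Paeth); retained as
# an independent reference for tests of the C kernel.
.median3x3_r <- function(m) {
  v <- vector("list", 9L)
  idx <- 1L
  for (dr in -1:1) for (dc in -1:1) {
    v[[idx]] <- .shift_mat(m, dr, dc)
    idx <- idx + 1L
  }
  sw <- function(i, j) {
    lo <- pmin(v[[i]], v[[j]]); hi <- pmax(v[[i]], v[[j]])
    v[[i]] <<- lo; v[[j]] <<- hi
  }
  sw(2, 3); sw(5, 6); sw(8, 9)
  sw(1, 2); sw(4, 5); sw(7, 8)
  sw(2, 3); sw(5, 6); sw(8, 9)
  sw(1, 4); sw(6, 9); sw(5, 8)
  sw(4, 7); sw(2, 5); sw(3, 6)
  sw(5, 8); sw(5, 3); sw(7, 5); sw(5, 3)
  v[[5]]
}

# Circular distance between angles in degrees.
.circ_dist <- function(a, b, period = 360) {
  d <- abs(a - b) %% period
  pmin(d, period - d)
}

# Circular mean of angles in degrees.
.circ_mean <- function(a, w = NULL) {
  rad <- a * pi / 180
  if (is.null(w)) w <- rep(1, length(a))
  ang <- atan2(sum(w * sin(rad)), sum(w * cos(rad))) * 180 / pi
  ang %% 360
}

# Within-column cumulative sums of a matrix in one vectorized pass.
.colcumsum <- function(m) {
  h <- nrow(m); w <- ncol(m)
  cs <- matrix(cumsum(m), h, w)
  if (w > 1L) cs <- cs - rep(c(0, cs[h, -w]), each = h)
  cs
}

# Box-filter sum over a (2r+1)^2 window via cumulative sums, edge-replicated
# by padding with border rows/cols.
.box_sum <- function(m, r) {
  if (r == 0L) return(m)
  h <- nrow(m); w <- ncol(m)
  ri <- .clamp(seq(1L - r, h + r), 1L, h)
  ci <- .clamp(seq(1L - r, w + r), 1L, w)
  p <- m[ri, ci, drop = FALSE]
  cs <- rbind(0, .colcumsum(p))
  rowsum_w <- cs[(2L * r + 2L):(h + 2L * r + 1L), , drop = FALSE] -
    cs[1L:h, , drop = FALSE]
  cs2 <- cbind(0, t(.colcumsum(t(rowsum_w))))
  cs2[, (2L * r + 2L):(w + 2L * r + 1L), drop = FALSE] - cs2[, 1L:w, drop = FALSE]
}

.validate_rgb <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("expected an RGB array with dim c(height, width, 3)", call. = FALSE)
  if (anyNA(image) || min(image) < 0 || max(image) > 255)
    stop("RGB channel values must lie in [0, 255]", call. = FALSE)
  invisible(image)
}

.validate_gray <- function(image) {
  if (!is.matrix(image)) stop("expected a grayscale matrix", call. = FALSE)
  invisible(image)
}

# Marching-squares length of the 0.5 iso-contour of a binary matrix; used as
# the perimeter estimate entering circularity.
.ms_perimeter <- function(mask) {
  m <- matrix(0L, nrow(mask) + 2L, ncol(mask) + 2L)
  m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- as.integer(mask != 0)
  h <- nrow(m); w <- ncol(m)
  a <- m[1:(h - 1L), 1:(w - 1L)]
  b <- m[1:(h - 1L), 2:w]
  cc <- m[2:h, 1:(w - 1L)]
  d <- m[2:h, 2:w]
  code <- a + 2L * b + 4L * cc + 8L * d
  # Segment length per 2x2 cell configuration (0..15); diagonal (corner)
  # segments carry the standard 0.95 digital-perimeter correction so that
  # staircase contours of smooth shapes are not over-counted.
  s2 <- 0.95 * sqrt(2) / 2
  len <- c(0, s2, s2, 1, s2, 1, 2 * s2, s2, s2, 2 * s2, 1, s2, 1, s2, s2, 0)
  sum(len[code + 1L])
}

.stopifnot_odd <- function(x, name) {
  if (x < 1 || x %% 2 == 0)
    stop(sprintf("%s must be an odd integer >= 1", name), call. = FALSE)
}
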