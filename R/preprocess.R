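#' Denoise an RGB image
#'
#' Applies per-channel Gaussian smoothing followed by median filtering, the
#' standard pre-clustering noise reduction for orchard imagery: the Gaussian
#' suppresses sensor noise, the median removes residual impulse noise without
#' rounding fruit edges.
#'
#' @param image numeric array `[height, width, 3]`, channel values in
#'   `[0, 255]`.
#' @param gaussian_sigma standard deviation of the Gaussian kernel in pixels
#'   (`0` skips the Gaussian stage).
#' @param median_kernel side length of the square median window in pixels;
#'   must be odd (`1` skips the median stage).
#' @return denoised RGB array, same shape and range as the input.
#' @examples
#' img <- array(128, c(8, 8, 3))
#' img[4, 4, ] <- 255                       # impulse
#' out <- denoise(img, gaussian_sigma = 0, median_kernel = 3)
#' out[4, 4, 1]                             # impulse removed
#' @export
denoise <- function(image, gaussian_sigma = 1, median_kernel = 3) {
  .validate_rgb(image)
  if (gaussian_sigma < 0) stop("gaussian_sigma must be >= 0", call. = FALSE)
  .stopifnot_odd(median_kernel, "median_kernel")
  out <- image
  for (ch in 1:3) {
    m <- image[, , ch]
    if (gaussian_sigma > 0) m <- .gauss_smooth(m, gaussian_sigma)
    if (median_kernel == 3L) {
      m <- .median3x3(m)
    } else if (median_kernel > 3L) {
      r <- (median_kernel - 1L) / 2L
      m <- EBImage::medianFilter(m / 255, size = r) * 255
    }
    out[, , ch] <- m
  }
  .clamp(out, 0, 255)
}

#' Convert RGB to the HSI colour space
#'
#' Hue is computed with the two-argument arctangent
#' `H = atan2(sqrt(3) * (G - B), 2R - G - B)` mapped to `[0, 360)` degrees,
#' which is algebraically identical to the classic arccos-form HSI hue but
#' unambiguous across all four quadrants (green at 120 deg, blue at 240 deg).
#' Saturation is `1 - 3 * min(R,G,B) / (R+G+B)` and intensity
#' `(R+G+B) / (3 * 255)`. Zero-chroma pixels (R = G = B) carry the sentinel
#' hue 0 and saturation 0. Hue isolates chromatic identity from brightness,
#' which is what makes apple/foliage separation robust to lighting.
#'
#' @param image numeric array `[height, width, 3]` in `[0, 255]`.
#' @return object of class `hsi_image`: list with matrices `h` (degrees in
#'   `[0, 360)`), `s` and `i` (both in `[0, 1]`).
#' @examples
#' px <- array(c(255, 0, 0), c(1, 1, 3))
#' rgb_to_hsi(px)$h   # pure red -> 0 degrees
#' @export
rgb_to_hsi <- function(image) {
  .validate_rgb(image)
  h0 <- dim(image)[1]; w0 <- dim(image)[2]
  r <- matrix(image[, , 1], h0, w0)
  g <- matrix(image[, , 2], h0, w0)
  b <- matrix(image[, , 3], h0, w0)
  num <- sqrt(3) * (g - b)
  den <- 2 * r - g - b
  h <- atan2(num, den) * 180 / pi
  h <- h %% 360
  zero_chroma <- num == 0 & den == 0
  h[zero_chroma] <- 0
  total <- r + g + b
  s <- 1 - 3 * pmin(r, g, b) / pmax(total, .Machine$double.eps)
  s[total <= 0 | zero_chroma] <- 0
  i <- total / (3 * 255)
  structure(list(h = h, s = s, i = i), class = "hsi_image")
}

#' @export
print.hsi_image <- function(x, ...) {
  cat(sprintf("<hsi_image> %d x %d px, hue range [%.1f, %.1f] deg\n",
              nrow(x$h), ncol(x$h), min(x$h), max(x$h)))
  invisible(x)
}

#' Convert RGB to 8-bit luminance grayscale
#'
#' ITU-R BT.601 weights: `0.299 R + 0.587 G + 0.114 B`, rounded to the
#' nearest integer. Grayscale feeds the GLCM texture stage and stereo block
#' matching, giving both a representation stable under colour shifts.
#'
#' @param image numeric array `[height, width, 3]` in `[0, 255]`.
#' @return matrix of gray values in `[0, 255]`.
#' @export
to_gray <- function(image) {
  .validate_rgb(image)
  g <- round(0.299 * image[, , 1] + 0.587 * image[, , 2] +
               0.114 * image[, , 3])
  matrix(g, dim(image)[1], dim(image)[2])
}
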