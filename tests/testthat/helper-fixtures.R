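# Shared fixtures built in code; heavy batch runs are cached per session so
# several acceptance checks can share one pipeline execution.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

# A small scene for unit tests: fast to render and segment.
small_scene <- function(seed = 7, n_apples = 3, apple_color = "red",
                        noise_sigma = 2, lighting = "day", ...) {
  spec <- scene_spec(image_size = c(180, 260), n_apples = n_apples,
                     apple_color = apple_color, radius_range = c(12, 18),
                     depth_range = c(800, 1400), max_overlap = 0.3,
                     lighting = lighting, noise_sigma = noise_sigma,
                     seed = seed, ...)
  render_scene(spec, stereo_rig(image_size = c(180, 260)))
}

# Rasterized disc mask.
disc_mask <- function(h, w, r0, c0, radius) {
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  ((rr - r0)^2 + (cc - c0)^2 <= radius^2) * 1L
}

# Independent arccos-form HSI hue (the classic geometric definition), used
# as the oracle for the atan2 implementation.
hue_arccos <- function(r, g, b) {
  num <- 0.5 * ((r - g) + (r - b))
  den <- sqrt((r - g)^2 + (r - b) * (g - b))
  theta <- acos(pmin(pmax(num / den, -1), 1)) * 180 / pi
  ifelse(b > g, 360 - theta, theta)
}

# Naive per-pixel SAD block matcher (integer disparities, no refinement):
# the brute-force oracle for block_match's integer stage.
sad_oracle <- function(left, right, block, max_d) {
  r <- (block - 1) / 2
  h <- nrow(left); w <- ncol(left)
  out <- matrix(NA_real_, h, w)
  for (i in (r + 1):(h - r)) {
    for (j in (r + 1):(w - r)) {
      best <- Inf; bd <- NA_real_
      for (d in 0:min(max_d, j - 1 - r)) {
        cost <- sum(abs(left[(i - r):(i + r), (j - r):(j + r)] -
                          right[(i - r):(i + r), (j - r - d):(j + r - d)]))
        if (cost < best) { best <- cost; bd <- d }
      }
      out[i, j] <- bd
    }
  }
  out
}
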