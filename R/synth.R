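#' Stereo camera rig description
#'
#' Pinhole model of a rectified stereo pair: identical focal length (pixels),
#' horizontal baseline (mm) and shared principal point. Depth follows from
#' disparity as `Z = f * B / d`.
#'
#' @param focal_px focal length in pixels.
#' @param baseline_mm stereo baseline in millimetres.
#' @param principal_point `(row, col)` of the optical axis in pixels; default
#'   is the image center.
#' @param image_size `(height, width)` in pixels.
#' @return object of class `stereo_rig`.
#' @export
stereo_rig <- function(focal_px = 700, baseline_mm = 60,
                       principal_point = NULL, image_size = c(540, 960)) {
  stopifnot(focal_px > 0, baseline_mm > 0, length(image_size) == 2)
  if (is.null(principal_point))
    principal_point <- (image_size + 1) / 2
  if (principal_point[1] < 1 || principal_point[1] > image_size[1] ||
      principal_point[2] < 1 || principal_point[2] > image_size[2])
    stop("principal point must lie inside the image", call. = FALSE)
  structure(list(focal_px = focal_px, baseline_mm = baseline_mm,
                 principal_point = principal_point, image_size = image_size),
            class = "stereo_rig")
}

#' @export
print.stereo_rig <- function(x, ...) {
  cat(sprintf("<stereo_rig> f = %.1f px, B = %.1f mm, pp = (%.1f, %.1f), %d x %d px\n",
              x$focal_px, x$baseline_mm, x$principal_point[1],
              x$principal_point[2], x$image_size[1], x$image_size[2]))
  invisible(x)
}

#' Synthetic orchard scene specification
#'
#' Describes one stereo orchard scene: apples of a given variety rendered as
#' shaded, lightly elliptical discs over textured green foliage, with
#' controlled overlap, lighting, brightness jitter, rotation jitter and
#' additive Gaussian noise. The same `(spec, seed)` pair always renders the
#' identical scene.
#'
#' @param image_size `(height, width)` pixels.
#' @param n_apples number of apples (may be 0).
#' @param apple_color `"red"` or `"green"` (green fruit on green foliage is
#'   the hard case).
#' @param radius_range ordered positive `(min, max)` apple radius in pixels.
#' @param depth_range ordered positive `(min, max)` apple depth in mm.
#' @param max_overlap maximum allowed pairwise overlap fraction in `[0, 1]`
#'   (intersection area over the smaller disc's area).
#' @param lighting `"day"`, `"noon"` or `"night"`; global brightness scale
#'   1.0 / 1.15 / 0.45.
#' @param brightness_jitter scene-level multiplicative brightness jitter
#'   (fraction, e.g. `0.2` for +/-20 percent).
#' @param rotation_jitter apple orientation jitter in degrees (+/-).
#' @param noise_sigma additive Gaussian pixel noise, 8-bit gray levels.
#' @param view_angle_deg simulated camera elevation angle; foreshortens the
#'   horizontal apple axis by `cos(angle)`.
#' @param seed integer RNG seed; part of the scene identity.
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(image_size = c(540, 960), n_apples = 8,
                       apple_color = c("red", "green"),
                       radius_range = c(13, 30), depth_range = c(800, 1700),
                       max_overlap = 0.4,
                       lighting = c("day", "noon", "night"),
                       brightness_jitter = 0.2, rotation_jitter = 15,
                       noise_sigma = 4, view_angle_deg = 0, seed = 1) {
  apple_color <- match.arg(apple_color)
  lighting <- match.arg(lighting)
  stopifnot(length(image_size) == 2, all(image_size >= 32),
            n_apples >= 0,
            length(radius_range) == 2, radius_range[1] > 0,
            radius_range[1] <= radius_range[2],
            length(depth_range) == 2, depth_range[1] > 0,
            depth_range[1] <= depth_range[2],
            max_overlap >= 0, max_overlap <= 1,
            brightness_jitter >= 0, rotation_jitter >= 0, noise_sigma >= 0,
            view_angle_deg >= 0, view_angle_deg < 90)
  structure(list(image_size = as.integer(image_size),
                 n_apples = as.integer(n_apples), apple_color = apple_color,
                 radius_range = radius_range, depth_range = depth_range,
                 max_overlap = max_overlap, lighting = lighting,
                 brightness_jitter = brightness_jitter,
                 rotation_jitter = rotation_jitter, noise_sigma = noise_sigma,
                 view_angle_deg = view_angle_deg, seed = as.integer(seed)),
            class = "scene_spec")
}

#' Overlap fraction of two discs
#'
#' Intersection area of the two discs divided by the smaller disc's area:
#' 1 when one disc contains the other, 0 when disjoint. This is the per-pair
#' overlap (occlusion) rate used as the controlled difficulty variable of the
#' synthetic scenes.
#'
#' @param center_a,center_b `(row, col)` disc centers in pixels.
#' @param radius_a,radius_b positive disc radii in pixels.
#' @return overlap fraction in `[0, 1]`.
#' @export
overlap_fraction <- function(center_a, radius_a, center_b, radius_b) {
  stopifnot(radius_a > 0, radius_b > 0)
  d <- sqrt(sum((center_a - center_b)^2))
  r1 <- radius_a; r2 <- radius_b
  rmin <- min(r1, r2)
  if (d >= r1 + r2) return(0)
  if (d <= abs(r1 - r2)) return(1)
  lens <- r1^2 * acos((d^2 + r1^2 - r2^2) / (2 * d * r1)) +
    r2^2 * acos((d^2 + r2^2 - r1^2) / (2 * d * r2)) -
    0.5 * sqrt((-d + r1 + r2) * (d + r1 - r2) * (d - r1 + r2) * (d + r1 + r2))
  min(1, lens / (pi * rmin^2))
}

# Base RGB of each variety; scalar shading multiplies all channels and hence
# preserves hue. Foliage hue sits near 115 deg, red apples near 5 deg, green
# apples near 95 deg (yellow-green fruit vs darker leaf green).
.apple_base_rgb <- function(apple_color) {
  if (apple_color == "red") c(205, 42, 38) else c(120, 200, 60)
}

.lighting_scale <- function(lighting) {
  switch(lighting, day = 1.0, noon = 1.15, night = 0.45)
}

# Multi-octave foliage background: bilinearly upsampled uniform noise gives
# leaf-blob structure without a texture asset.
.foliage_background <- function(h, w) {
  octave <- function(cell) {
    small <- matrix(stats::runif(ceiling(h / cell) * ceiling(w / cell)),
                    ceiling(h / cell), ceiling(w / cell))
    EBImage::resize(small, w = h, h = w)
  }
  t <- 0.45 * octave(48) + 0.35 * octave(16) + 0.20 * octave(6)
  t <- (t - min(t)) / max(1e-9, diff(range(t)))
  leaf <- octave(24)
  shade <- ifelse(leaf > 0.7, 0.78, 1)
  img <- array(0, c(h, w, 3))
  img[, , 1] <- (30 + 55 * t) * shade
  img[, , 2] <- (95 + 75 * t) * shade
  img[, , 3] <- (25 + 45 * t) * shade
  img
}

# Draw one shaded elliptical apple with anti-aliased edges onto the three
# channel matrices held in environment `canvas` (r, g, b); the environment
# indirection keeps the per-apple subassignments in place instead of copying
# the full image. Center may be sub-pixel.
.draw_apple <- function(canvas, row0, col0, a_row, a_col, theta_deg, base_rgb,
                        shade_jitter) {
  h <- nrow(canvas$r); w <- ncol(canvas$r)
  rmax <- max(a_row, a_col) + 2
  r1 <- max(1L, floor(row0 - rmax)); r2 <- min(h, ceiling(row0 + rmax))
  c1 <- max(1L, floor(col0 - rmax)); c2 <- min(w, ceiling(col0 + rmax))
  if (r1 > r2 || c1 > c2) return(invisible(NULL))
  rr <- matrix(r1:r2, r2 - r1 + 1L, c2 - c1 + 1L)
  cc <- matrix(c1:c2, r2 - r1 + 1L, c2 - c1 + 1L, byrow = TRUE)
  th <- theta_deg * pi / 180
  dx <- cc - col0; dy <- rr - row0
  u <- (cos(th) * dx + sin(th) * dy) / a_col
  v <- (-sin(th) * dx + cos(th) * dy) / a_row
  rho <- sqrt(u^2 + v^2)
  rmean <- sqrt(a_row * a_col)
  alpha <- .clamp((1 - rho) * rmean + 0.5, 0, 1)
  if (all(alpha == 0)) return(invisible(NULL))
  rho_h <- sqrt((u + 0.22)^2 + (v + 0.22)^2) / 1.25
  shade <- (0.50 + 0.50 * sqrt(pmax(0, 1 - rho_h^2))) * shade_jitter
  for (ch in c("r", "g", "b")) {
    val <- base_rgb[match(ch, c("r", "g", "b"))] * shade
    canvas[[ch]][r1:r2, c1:c2] <-
      alpha * val + (1 - alpha) * canvas[[ch]][r1:r2, c1:c2]
  }
  invisible(NULL)
}

.new_canvas <- function(bg) {
  e <- new.env(parent = emptyenv())
  e$r <- bg[, , 1]; e$g <- bg[, , 2]; e$b <- bg[, , 3]
  e
}

.canvas_to_array <- function(canvas) {
  array(c(canvas$r, canvas$g, canvas$b), c(nrow(canvas$r), ncol(canvas$r), 3))
}

# Sample apple placements honouring the overlap budget. A fraction of apples
# is deliberately placed overlapping an earlier one so that overlap fractions
# span (0, max_overlap]; placement failing after max_tries signals an
# infeasible spec.
.place_apples <- function(spec, rig, max_tries = 300L) {
  h <- spec$image_size[1]; w <- spec$image_size[2]
  n <- spec$n_apples
  out <- data.frame(row = numeric(0), col = numeric(0), radius = numeric(0),
                    depth_mm = numeric(0))
  if (n == 0) return(out)
  f <- rig$focal_px; B <- rig$baseline_mm
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      radius <- stats::runif(1, spec$radius_range[1], spec$radius_range[2])
      depth <- stats::runif(1, spec$depth_range[1], spec$depth_range[2])
      d_px <- f * B / depth
      lo_col <- 1 + 0.4 * radius + d_px   # visible in both views
      hi_col <- w - 0.4 * radius
      lo_row <- 1 + 0.4 * radius
      hi_row <- h - 0.4 * radius
      if (lo_col >= hi_col || lo_row >= hi_row) next
      want_overlap <- nrow(out) > 0 && spec$max_overlap > 0 &&
        stats::runif(1) < 0.45
      if (want_overlap) {
        j <- sample.int(nrow(out), 1)
        target <- stats::runif(1, 0.05 * spec$max_overlap, spec$max_overlap)
        rj <- out$radius[j]
        frac_at <- function(d) overlap_fraction(c(0, 0), radius, c(0, d), rj)
        dist_j <- tryCatch(
          stats::uniroot(function(d) frac_at(d) - target,
                         c(abs(radius - rj) + 1e-6, radius + rj - 1e-6))$root,
          error = function(e) NA_real_)
        if (is.na(dist_j)) next
        ang <- stats::runif(1, 0, 2 * pi)
        row0 <- out$row[j] + dist_j * sin(ang)
        col0 <- out$col[j] + dist_j * cos(ang)
      } else {
        row0 <- stats::runif(1, lo_row, hi_row)
        col0 <- stats::runif(1, lo_col, hi_col)
      }
      if (row0 < lo_row || row0 > hi_row || col0 < lo_col || col0 > hi_col) next
      # the overlap budget is per apple: pairwise overlap AND the total
      # occluded fraction of every apple (sum of lens areas with nearer
      # fruit over its own area) must stay within max_overlap
      ok <- TRUE
      if (nrow(out) > 0) {
        cand <- rbind(out, data.frame(row = row0, col = col0, radius = radius,
                                      depth_mm = depth))
        nn <- nrow(cand)
        for (a in seq_len(nn)) {
          cover <- 0
          for (bb in seq_len(nn)) {
            if (a == bb) next
            ov <- overlap_fraction(c(cand$row[a], cand$col[a]), cand$radius[a],
                                   c(cand$row[bb], cand$col[bb]), cand$radius[bb])
            if (ov > spec$max_overlap + 1e-9) { ok <- FALSE; break }
            if (cand$depth_mm[bb] < cand$depth_mm[a]) {
              rmin <- min(cand$radius[a], cand$radius[bb])
              cover <- cover + ov * rmin^2 / cand$radius[a]^2
            }
          }
          if (!ok || cover > spec$max_overlap + 1e-9) { ok <- FALSE; break }
        }
      }
      if (ok) {
        out <- rbind(out, data.frame(row = row0, col = col0, radius = radius,
                                     depth_mm = depth))
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("infeasible scene spec: could not place apple ", i,
           " within the overlap budget", call. = FALSE)
  }
  out
}

#' Render a synthetic stereo orchard scene
#'
#' Renders apples as shaded, anti-aliased elliptical discs in the variety's
#' hue band over a multi-octave green-foliage background. The right image
#' shifts every apple horizontally by its exact disparity `d = f * B / Z`;
#' the background is treated as distant (zero disparity). Scene-level
#' brightness (lighting times jitter) and per-image Gaussian noise are
#' applied last. Identical `(spec, seed)` pairs give bit-identical output.
#'
#' @param spec a [scene_spec()].
#' @param rig a [stereo_rig()]; default uses the spec's image size.
#' @return object of class `orchard_scene`: list with `left` and `right` RGB
#'   arrays, `truth` data frame (one row per apple: sub-pixel `row`, `col`,
#'   `radius`, ellipse semi-axes `a_row`/`a_col`, `theta_deg`, `depth_mm`,
#'   exact `disparity_px`, `occlusion` fraction), plus `rig` and `spec`.
#' @export
render_scene <- function(spec, rig = NULL) {
  stopifnot(inherits(spec, "scene_spec"))
  if (is.null(rig))
    rig <- stereo_rig(image_size = spec$image_size)
  stopifnot(all(rig$image_size == spec$image_size))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)

  h <- spec$image_size[1]; w <- spec$image_size[2]
  bg <- .foliage_background(h, w)
  placements <- .place_apples(spec, rig)
  n <- nrow(placements)

  truth <- data.frame(apple = integer(0), row = numeric(0), col = numeric(0),
                      radius = numeric(0), a_row = numeric(0),
                      a_col = numeric(0), theta_deg = numeric(0),
                      depth_mm = numeric(0), disparity_px = numeric(0),
                      occlusion = numeric(0))
  left_cv <- .new_canvas(bg); right_cv <- .new_canvas(bg)
  base_rgb <- .apple_base_rgb(spec$apple_color)
  if (n > 0) {
    axis_ratio <- stats::runif(n, 0.92, 1)
    theta <- stats::runif(n, -spec$rotation_jitter, spec$rotation_jitter)
    tone <- stats::runif(n, 0.88, 1.08)
    a_row <- placements$radius
    a_col <- placements$radius * axis_ratio * cos(spec$view_angle_deg * pi / 180)
    d_px <- rig$focal_px * rig$baseline_mm / placements$depth_mm
    # occlusion: fraction of each disc covered by strictly nearer apples
    occ <- numeric(n)
    for (i in seq_len(n)) {
      cover <- 0
      for (j in seq_len(n)) {
        if (j == i || placements$depth_mm[j] >= placements$depth_mm[i]) next
        lens_frac <- overlap_fraction(
          c(placements$row[i], placements$col[i]), placements$radius[i],
          c(placements$row[j], placements$col[j]), placements$radius[j])
        # rescale from smaller-disc area to apple i's own area
        rmin <- min(placements$radius[i], placements$radius[j])
        cover <- cover + lens_frac * rmin^2 / placements$radius[i]^2
      }
      occ[i] <- min(1, cover)
    }
    ord <- order(placements$depth_mm, decreasing = TRUE)  # far first
    for (i in ord) {
      .draw_apple(left_cv, placements$row[i], placements$col[i],
                  a_row[i], a_col[i], theta[i], base_rgb, tone[i])
      .draw_apple(right_cv, placements$row[i], placements$col[i] - d_px[i],
                  a_row[i], a_col[i], theta[i], base_rgb, tone[i])
    }
    truth <- data.frame(apple = seq_len(n), row = placements$row,
                        col = placements$col,
                        radius = sqrt(a_row * a_col),
                        a_row = a_row, a_col = a_col, theta_deg = theta,
                        depth_mm = placements$depth_mm, disparity_px = d_px,
                        occlusion = occ)
  }
  left <- .canvas_to_array(left_cv)
  right <- .canvas_to_array(right_cv)
  bright <- .lighting_scale(spec$lighting) *
    stats::runif(1, 1 - spec$brightness_jitter, 1 + spec$brightness_jitter)
  left <- left * bright
  right <- right * bright
  if (spec$noise_sigma > 0) {
    left <- left + array(stats::rnorm(length(left), 0, spec$noise_sigma), dim(left))
    right <- right + array(stats::rnorm(length(right), 0, spec$noise_sigma), dim(right))
  }
  left <- .clamp(left, 0, 255)
  right <- .clamp(right, 0, 255)
  structure(list(left = left, right = right, truth = truth, rig = rig,
                 spec = spec),
            class = "orchard_scene")
}

#' @export
print.orchard_scene <- function(x, ...) {
  cat(sprintf("<orchard_scene> %d x %d px, %d apples (%s, %s), noise sigma %.1f\n",
              x$spec$image_size[1], x$spec$image_size[2], nrow(x$truth),
              x$spec$apple_color, x$spec$lighting, x$spec$noise_sigma))
  invisible(x)
}

#' @export
plot.orchard_scene <- function(x, which = c("left", "right"), truth = TRUE, ...) {
  which <- match.arg(which)
  img <- x[[which]] / 255
  plot(c(1, ncol(img)), c(1, nrow(img)), type = "n", asp = 1,
       xlab = "col", ylab = "row", ylim = c(nrow(img), 1), ...)
  graphics::rasterImage(grDevices::as.raster(img), 1, nrow(img), ncol(img), 1)
  if (truth && nrow(x$truth) > 0) {
    tt <- seq(0, 2 * pi, length.out = 90)
    for (i in seq_len(nrow(x$truth))) {
      cx <- if (which == "left") x$truth$col[i] else
        x$truth$col[i] - x$truth$disparity_px[i]
      graphics::lines(cx + x$truth$radius[i] * cos(tt),
                      x$truth$row[i] + x$truth$radius[i] * sin(tt),
                      col = "yellow", lwd = 1.5)
    }
  }
  invisible(x)
}

#' Write a rendered scene to disk
#'
#' Writes `left.png`, `right.png` and `truth.json` (per-apple centroid,
#' radius, depth, disparity, occlusion plus the rig parameters) into `dir`.
#'
#' @param scene an `orchard_scene`.
#' @param dir output directory, created if missing.
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "orchard_scene"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  png::writePNG(scene$left / 255, file.path(dir, "left.png"))
  png::writePNG(scene$right / 255, file.path(dir, "right.png"))
  truth <- list(
    rig = list(focal_px = scene$rig$focal_px,
               baseline_mm = scene$rig$baseline_mm,
               principal_point = scene$rig$principal_point,
               image_size = scene$rig$image_size),
    lighting = scene$spec$lighting,
    apples = lapply(seq_len(nrow(scene$truth)), function(i) {
      r <- scene$truth[i, ]
      list(centroid = c(r$row, r$col), radius = r$radius,
           depth_mm = r$depth_mm, overlap = r$occlusion)
    }))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
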