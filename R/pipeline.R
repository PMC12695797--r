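.default_config <- function() {
  list(
    preprocess = list(gaussian_sigma = 1, median_kernel = 3),
    cluster = list(k = 3, tol = 1e-4, max_iter = 100,
                   neighborhood_radius = 2, density_epsilon = 1e-3,
                   selem_radius = 2, min_area = NULL,
                   hue_origin = 240),
    fusion = list(weights = c(0.5, 0.3, 0.2), threshold = 0.6,
                  hue_ref = 0, glcm_window = 21, glcm_distance = 1,
                  glcm_levels = 16, glcm_statistic = "homogeneity",
                  split = TRUE, split_tolerance = 1, refine_circ = 0.88),
    stereo = list(block = 9, max_disparity = NULL, interior = 0.7),
    metrics = list(match_factor = 1, iou_threshold = 0.5),
    seed = 1L
  )
}

.check_keys <- function(value, template, path = "") {
  if (!is.list(template)) return(invisible(NULL))
  extra <- setdiff(names(value), names(template))
  if (length(extra))
    stop("unknown config key(s): ",
         paste0(sub("^\\.", "", paste0(path, ".", extra)), collapse = ", "),
         call. = FALSE)
  for (nm in names(value))
    if (is.list(template[[nm]]))
      .check_keys(value[[nm]], template[[nm]], paste0(path, ".", nm))
  invisible(NULL)
}

#' Pipeline configuration
#'
#' Documented defaults for every stage; supplied values are merged over the
#' defaults and unknown keys are rejected. `cluster$hue_origin` rotates the
#' hue axis so that the (unpopulated) blue band carries the circular cut,
#' keeping red fruit hues contiguous for the clustering stage;
#' `fusion$hue_ref` is the variety reference hue (0 red, 100 green fruit).
#'
#' @param ... named overrides, e.g. `fusion = list(threshold = 0.5)`.
#' @return nested config list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- .default_config()
  user <- list(...)
  .check_keys(user, cfg)
  cfg <- utils::modifyList(cfg, user)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with any subset of the [pipeline_config()] keys.
#' @return a `pipeline_config`.
#' @export
config_from_yaml <- function(path) {
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  do.call(pipeline_config, user)
}

#' Segment one frame into fruit-candidate regions
#'
#' Preprocessing (denoise, HSI), adaptive K-Means on the rotated hue plane,
#' foreground selection by reference hue, morphological cleanup and
#' watershed splitting of touching fruit.
#'
#' @param image RGB array `[h, w, 3]` in `[0, 255]`.
#' @param config a [pipeline_config()].
#' @return list with `labels` (integer region labels), `mask` (binary
#'   foreground), `seg` (the `apple_segmentation`), `hsi`, `gray`.
#' @export
segment_scene <- function(image, config = pipeline_config()) {
  pp <- config$preprocess; cl <- config$cluster; fu <- config$fusion
  den <- denoise(image, pp$gaussian_sigma, pp$median_kernel)
  hsi <- rgb_to_hsi(den)
  gray <- to_gray(den)
  hshift <- (hsi$h - cl$hue_origin) %% 360
  centers <- select_initial_centers(hshift, cl$k,
                                    neighborhood_radius = cl$neighborhood_radius,
                                    density_epsilon = cl$density_epsilon)
  seg <- kmeans_segment(hshift, k = cl$k, max_iter = cl$max_iter,
                        tol = cl$tol, centers = centers)
  ref_shift <- (fu$hue_ref - cl$hue_origin) %% 360
  fg <- foreground_mask(seg, ref_shift)
  min_area <- if (is.null(cl$min_area))
    .default_min_area(nrow(gray), ncol(gray)) else cl$min_area
  mask <- morph_clean(fg, selem_radius = cl$selem_radius, min_area = min_area)
  labels <- if (isTRUE(fu$split))
    split_touching(mask, tolerance = fu$split_tolerance, min_area = min_area,
                   refine_circ = fu$refine_circ)
  else .label8(mask)
  list(labels = labels, mask = mask, seg = seg, hsi = hsi, gray = gray,
       min_area = min_area)
}

#' Run the full detection (and optional 3D localization) pipeline
#'
#' preprocessing -> enhanced K-Means segmentation -> multi-feature fusion
#' recognition; when a right image is supplied, stereo block matching and
#' triangulation add metric 3D coordinates per detection.
#'
#' @param left RGB array `[h, w, 3]` in `[0, 255]`.
#' @param right optional rectified right RGB array.
#' @param config a [pipeline_config()].
#' @param rig a [stereo_rig()]; required when `right` is given.
#' @return object of class `apple_detection_result`: list with `detections`
#'   (an `apple_detections` data frame), `labels`, `mask`, `timing`
#'   (per-stage seconds and `fps`), `config`.
#' @export
detect_scene <- function(left, right = NULL, config = pipeline_config(),
                         rig = NULL) {
  if (!is.null(right) && is.null(rig))
    stop("stereo localization requires a rig", call. = FALSE)
  t0 <- proc.time()[[3]]
  segres <- segment_scene(left, config)
  t1 <- proc.time()[[3]]
  fu <- config$fusion
  det <- detect_apples(segres$labels, segres$hsi, segres$gray,
                       weights = do.call(fusion_weights, as.list(fu$weights)),
                       spec = glcm_spec(window = fu$glcm_window,
                                        distance = fu$glcm_distance,
                                        levels = fu$glcm_levels,
                                        statistic = fu$glcm_statistic),
                       threshold = fu$threshold, hue_ref = fu$hue_ref,
                       min_area = segres$min_area, split = FALSE)
  t2 <- proc.time()[[3]]
  if (!is.null(right)) {
    ppr <- config$preprocess
    gray_right <- to_gray(denoise(right, ppr$gaussian_sigma, ppr$median_kernel))
    det <- locate_apples_3d(det, segres$gray, gray_right, rig,
                            block = config$stereo$block,
                            max_disparity = config$stereo$max_disparity,
                            interior = config$stereo$interior,
                            labels = attr(det, "labels"))
  }
  t3 <- proc.time()[[3]]
  timing <- c(segment = t1 - t0, fusion = t2 - t1, stereo = t3 - t2,
              total = t3 - t0, fps = 1 / max(t3 - t0, 1e-9))
  structure(list(detections = det, labels = attr(det, "labels"),
                 mask = segres$mask, timing = timing, config = config),
            class = "apple_detection_result")
}

#' @export
print.apple_detection_result <- function(x, ...) {
  cat(sprintf("<apple_detection_result> %d detections, %.2f s (%.2f fps)\n",
              nrow(x$detections), x$timing[["total"]], x$timing[["fps"]]))
  print(x$detections)
  invisible(x)
}

#' @export
plot.apple_detection_result <- function(x, image, ...) {
  img <- image / 255
  plot(c(1, ncol(img)), c(1, nrow(img)), type = "n", asp = 1,
       xlab = "col", ylab = "row", ylim = c(nrow(img), 1), ...)
  graphics::rasterImage(grDevices::as.raster(img), 1, nrow(img), ncol(img), 1)
  d <- x$detections
  if (nrow(d)) {
    tt <- seq(0, 2 * pi, length.out = 90)
    for (i in seq_len(nrow(d)))
      graphics::lines(d$col[i] + d$radius[i] * cos(tt),
                      d$row[i] + d$radius[i] * sin(tt), col = "cyan", lwd = 2)
  }
  invisible(x)
}

#' Scene specifications for a standard evaluation batch
#'
#' Builds `n_scenes` scene specs alternating day/night lighting and
#' red/green variety, apple counts drawn uniformly from `n_range`, all other
#' conditions fixed by the arguments. Scene seeds derive deterministically
#' from `base_seed`.
#'
#' @param n_scenes number of scenes.
#' @param base_seed integer seed for the batch.
#' @param n_range `(min, max)` apples per scene.
#' @param max_overlap overlap budget per scene.
#' @param image_size,radius_range,depth_range,noise_sigma,brightness_jitter
#'   forwarded to [scene_spec()].
#' @param lighting,apple_color vectors cycled over scenes.
#' @param view_angle_deg camera elevation angle for every scene.
#' @return list of `scene_spec` objects.
#' @export
orchard_batch_specs <- function(n_scenes, base_seed = 42, n_range = c(5, 15),
                                max_overlap = 0.4, image_size = c(540, 960),
                                radius_range = c(13, 30),
                                depth_range = c(800, 1700), noise_sigma = 4,
                                brightness_jitter = 0.2,
                                lighting = c("day", "night"),
                                apple_color = c("red", "green"),
                                view_angle_deg = 0) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(base_seed)
  n_apples <- sample(n_range[1]:n_range[2], n_scenes, replace = TRUE)
  seeds <- sample.int(2^30, n_scenes)
  lapply(seq_len(n_scenes), function(i)
    scene_spec(image_size = image_size, n_apples = n_apples[i],
               apple_color = apple_color[(i - 1) %% length(apple_color) + 1],
               radius_range = radius_range, depth_range = depth_range,
               max_overlap = max_overlap,
               lighting = lighting[(i - 1) %% length(lighting) + 1],
               brightness_jitter = brightness_jitter,
               noise_sigma = noise_sigma, view_angle_deg = view_angle_deg,
               seed = seeds[i]))
}

#' Evaluate the pipeline on one synthetic scene
#'
#' Renders the scene, runs detection (with stereo localization when
#' requested), matches detections to truth and accumulates the per-scene
#' ingredients of RA, MCD, CRR and the 3D localization error.
#'
#' @param spec a [scene_spec()].
#' @param config a [pipeline_config()]; its `fusion$hue_ref` is set from the
#'   scene's variety automatically.
#' @param stereo run stereo 3D localization.
#' @return one-row data frame of per-scene tallies.
#' @export
evaluate_scene <- function(spec, config = pipeline_config(), stereo = TRUE) {
  scene <- render_scene(spec)
  config$fusion$hue_ref <- if (spec$apple_color == "red") 0 else 100
  res <- detect_scene(scene$left, if (stereo) scene$right else NULL,
                      config = config, rig = scene$rig)
  m <- match_detections(res$detections, scene$truth,
                        max_dist_factor = config$metrics$match_factor)
  crr_hits <- 0L
  if (nrow(scene$truth)) {
    iou <- vapply(seq_len(nrow(scene$truth)), function(i)
      .truth_region_iou(scene$truth[i, ], res$labels), numeric(1))
    crr_hits <- sum(iou >= config$metrics$iou_threshold)
  }
  sum_rel3d <- 0; n_3d <- 0L
  if (stereo && nrow(m$pairs)) {
    for (k in seq_len(nrow(m$pairs))) {
      i <- m$pairs$detection[k]; j <- m$pairs$truth[k]
      if (is.na(res$detections$Z_mm[i])) next
      real <- pixel_to_3d(c(scene$truth$row[j], scene$truth$col[j]),
                          scene$truth$depth_mm[j], scene$rig)
      calc <- c(res$detections$X_mm[i], res$detections$Y_mm[i],
                res$detections$Z_mm[i])
      sum_rel3d <- sum_rel3d +
        localization_error(real, calc) / sqrt(sum(real^2))
      n_3d <- n_3d + 1L
    }
  }
  data.frame(seed = spec$seed, lighting = spec$lighting,
             apple_color = spec$apple_color, n_truth = nrow(scene$truth),
             n_det = nrow(res$detections), tp = m$tp, fp = m$fp, fn = m$fn,
             sum_dev_px = sum(m$pairs$distance), n_pairs = nrow(m$pairs),
             crr_hits = crr_hits, sum_rel3d = sum_rel3d, n_3d = n_3d,
             diag_px = sqrt(sum(spec$image_size^2)),
             seconds = res$timing[["total"]])
}

#' Evaluate the pipeline on a batch of scenes
#'
#' @param specs list of [scene_spec()] objects.
#' @param config a [pipeline_config()].
#' @param stereo run stereo 3D localization per scene.
#' @return data frame with one row per scene (see [evaluate_scene()]).
#' @export
evaluate_batch <- function(specs, config = pipeline_config(), stereo = TRUE) {
  do.call(rbind, lapply(specs, evaluate_scene, config = config,
                        stereo = stereo))
}

#' Summarize a batch evaluation into headline metrics
#'
#' Pools the per-scene tallies of [evaluate_batch()] into RA, MCD (percent
#' of the image diagonal), CRR and the mean relative 3D localization error.
#'
#' @param batch data frame from [evaluate_batch()].
#' @return list with `ra_pct`, `mcd_pct`, `crr_pct`, `mean_rel3d_pct`,
#'   `n_truth`, `n_pairs`.
#' @export
summarize_batch <- function(batch) {
  list(ra_pct = 100 * sum(batch$tp) / sum(batch$tp + batch$fn),
       mcd_pct = 100 * sum(batch$sum_dev_px) /
         (sum(batch$n_pairs) * batch$diag_px[1]),
       crr_pct = 100 * sum(batch$crr_hits) / sum(batch$n_truth),
       mean_rel3d_pct = if (sum(batch$n_3d) > 0)
         100 * sum(batch$sum_rel3d) / sum(batch$n_3d) else NA_real_,
       n_truth = sum(batch$n_truth), n_pairs = sum(batch$n_pairs))
}
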