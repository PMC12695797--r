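#' Match detections to ground-truth apples
#'
#' Greedy nearest-first assignment: a detection may match a truth apple iff
#' their centroid distance is at most `max_dist_factor` times the truth
#' radius; candidate pairs are taken in ascending distance (ties break to
#' the lower detection index), each detection and each truth apple matching
#' at most once. Unmatched detections are false positives, unmatched truth
#' apples false negatives.
#'
#' @param detections data frame with `row`, `col` (and optionally `score`).
#' @param truth data frame with `row`, `col`, `radius` (e.g. scene truth).
#' @param max_dist_factor match radius as a multiple of the truth radius.
#' @return object of class `match_result`: list with counts `tp`, `fp`,
#'   `fn`, data frame `pairs` (`detection`, `truth`, `distance`), and the
#'   flag vector `det_matched`.
#' @export
match_detections <- function(detections, truth, max_dist_factor = 1) {
  stopifnot(max_dist_factor > 0)
  nd <- nrow(detections); nt <- nrow(truth)
  pairs <- data.frame(detection = integer(0), truth = integer(0),
                      distance = numeric(0))
  if (nd > 0 && nt > 0) {
    dd <- outer(seq_len(nd), seq_len(nt), function(i, j)
      sqrt((detections$row[i] - truth$row[j])^2 +
             (detections$col[i] - truth$col[j])^2))
    lim <- matrix(truth$radius * max_dist_factor, nd, nt, byrow = TRUE)
    cand <- which(dd <= lim, arr.ind = TRUE)
    if (nrow(cand)) {
      ord <- order(dd[cand], cand[, 1])
      used_d <- logical(nd); used_t <- logical(nt)
      for (k in ord) {
        i <- cand[k, 1]; j <- cand[k, 2]
        if (used_d[i] || used_t[j]) next
        used_d[i] <- TRUE; used_t[j] <- TRUE
        pairs <- rbind(pairs, data.frame(detection = i, truth = j,
                                         distance = dd[i, j]))
      }
    }
  }
  det_matched <- logical(nd)
  det_matched[pairs$detection] <- TRUE
  structure(list(tp = nrow(pairs), fp = nd - nrow(pairs),
                 fn = nt - nrow(pairs), pairs = pairs,
                 det_matched = det_matched, n_truth = nt),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> TP %d, FP %d, FN %d\n", x$tp, x$fp, x$fn))
  invisible(x)
}

#' Recognition accuracy
#'
#' `RA = 100 * TP / (TP + FN)`: the percentage of ground-truth fruits that
#' were detected.
#'
#' @param m a [match_detections()] result.
#' @return RA in percent (`NaN` with zero truth apples).
#' @export
recognition_accuracy <- function(m) {
  100 * m$tp / (m$tp + m$fn)
}

#' Mean coordinate deviation
#'
#' Mean centroid deviation over matched pairs, expressed as a percentage of
#' the image diagonal (a scale-free localization precision measure).
#'
#' @param m a [match_detections()] result.
#' @param image_diagonal image diagonal in pixels.
#' @return MCD in percent; `NA` (with a warning) when nothing matched.
#' @export
mean_coordinate_deviation <- function(m, image_diagonal) {
  stopifnot(image_diagonal > 0)
  if (nrow(m$pairs) == 0) {
    warning("no matched pairs: MCD undefined")
    return(NA_real_)
  }
  100 * mean(m$pairs$distance) / image_diagonal
}

# Rasterized IoU between a truth ellipse and each candidate region label.
.truth_region_iou <- function(truth_row, labels) {
  h <- nrow(labels); w <- ncol(labels)
  rad <- max(truth_row$a_row, truth_row$a_col)
  r1 <- max(1L, floor(truth_row$row - rad - 1)); r2 <- min(h, ceiling(truth_row$row + rad + 1))
  c1 <- max(1L, floor(truth_row$col - rad - 1)); c2 <- min(w, ceiling(truth_row$col + rad + 1))
  if (r1 > r2 || c1 > c2) return(0)
  rr <- matrix(r1:r2, r2 - r1 + 1L, c2 - c1 + 1L)
  cc <- matrix(c1:c2, r2 - r1 + 1L, c2 - c1 + 1L, byrow = TRUE)
  th <- truth_row$theta_deg * pi / 180
  dx <- cc - truth_row$col; dy <- rr - truth_row$row
  u <- (cos(th) * dx + sin(th) * dy) / truth_row$a_col
  v <- (-sin(th) * dx + cos(th) * dy) / truth_row$a_row
  disc <- (u^2 + v^2) <= 1
  disc_area <- sum(disc)
  if (disc_area == 0) return(0)
  crop <- labels[r1:r2, c1:c2, drop = FALSE]
  cand <- unique(crop[disc & crop > 0L])
  if (!length(cand)) return(0)
  areas <- tabulate(labels[labels > 0L])
  best <- 0
  for (lb in cand) {
    inter <- sum(disc & crop == lb)
    uni <- disc_area + areas[lb] - inter
    best <- max(best, inter / uni)
  }
  best
}

#' Correct recognition rate of a segmentation
#'
#' Percentage of ground-truth apples whose true (elliptical) disc reaches at
#' least `iou_threshold` intersection-over-union with some segmented region.
#' Regions may come from plain connected components or from watershed-split
#' labels.
#'
#' @param labels integer label matrix of segmented regions (0 background),
#'   e.g. from [split_touching()] or `attr(connected_regions(m), "labels")`.
#' @param truth scene truth data frame (`row`, `col`, `a_row`, `a_col`,
#'   `theta_deg`).
#' @param iou_threshold IoU acceptance threshold (reaching it exactly
#'   counts).
#' @return CRR in percent (`NaN` with zero truth apples).
#' @export
correct_recognition_rate <- function(labels, truth, iou_threshold = 0.5) {
  nt <- nrow(truth)
  if (nt == 0) return(NaN)
  hit <- vapply(seq_len(nt), function(i)
    .truth_region_iou(truth[i, ], labels) >= iou_threshold, logical(1))
  100 * sum(hit) / nt
}

#' Precision, recall, F1 and average precision
#'
#' Precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, their harmonic mean F1, and
#' the all-point interpolated area under the precision-recall curve obtained
#' by sweeping the detection-score threshold (single-class mAP equals this
#' AP). The TP/FP identity of each detection is fixed by the geometric
#' matching in `m`.
#'
#' @param m a [match_detections()] result.
#' @param scores per-detection confidence scores, same order as the
#'   detections given to [match_detections()].
#' @return list with `precision`, `recall`, `f1`, `ap`.
#' @export
precision_recall_f1_map <- function(m, scores) {
  stopifnot(length(scores) == length(m$det_matched))
  p <- if (m$tp + m$fp > 0) m$tp / (m$tp + m$fp) else 0
  r <- if (m$tp + m$fn > 0) m$tp / (m$tp + m$fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  ap <- 0
  if (m$n_truth > 0 && length(scores) > 0) {
    ord <- order(scores, decreasing = TRUE)
    tp_flag <- m$det_matched[ord]
    cum_tp <- cumsum(tp_flag)
    prec <- cum_tp / seq_along(cum_tp)
    rec <- cum_tp / m$n_truth
    # all-point interpolation: precision envelope from the right
    prec_env <- rev(cummax(rev(prec)))
    rec_prev <- c(0, rec[-length(rec)])
    ap <- sum((rec - rec_prev) * prec_env)
  }
  list(precision = p, recall = r, f1 = f1, ap = ap)
}

#' Stability of recognition accuracy across camera angles
#'
#' Sample standard deviation of RA over replicate scene batches at each
#' simulated view angle; smaller values mean the detector is less sensitive
#' to camera orientation.
#'
#' @param reports data frame with columns `angle` and `ra`.
#' @return data frame `(angle, n, mean_ra, sd_ra)`.
#' @export
angle_stability <- function(reports) {
  stopifnot(all(c("angle", "ra") %in% names(reports)))
  ang <- sort(unique(reports$angle))
  out <- data.frame(angle = ang, n = NA_integer_, mean_ra = NA_real_,
                    sd_ra = NA_real_)
  for (i in seq_along(ang)) {
    v <- reports$ra[reports$angle == ang[i]]
    out$n[i] <- length(v)
    out$mean_ra[i] <- mean(v)
    out$sd_ra[i] <- if (length(v) > 1) stats::sd(v) else 0
  }
  out
}
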