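#' Segmentation configuration
#'
#' Color and morphology thresholds of the deterministic baseline
#' segmenters. Inside the endoscopic view, pixels are excluded from the
#' clearly-exposed-mucosa mask when they look like specular reflection
#' (bright and unsaturated), excessive darkness, fecal material /
#' occlusion (brown hue band), or instrument metal (grey, mid-luminance);
#' these are the region classes that must never count as well-exposed
#' mucosa. Defaults were tuned on fixed-seed synthetic fixtures and live
#' here rather than in the logic.
#'
#' @param view_lum_min Luminance above which a pixel can belong to the
#'   endoscopic field of view (separates it from the near-black frame
#'   surround).
#' @param view_min_fraction Minimum fraction of the frame the detected
#'   view must cover; below it the frame is rejected as having no view.
#' @param specular_lum_min,specular_sat_max Specular rule: luminance above
#'   and saturation below these bounds.
#' @param dark_lum_max Dark-region rule: luminance below this bound.
#' @param fecal_hue_band,fecal_sat_min Fecal/occlusion rule: hue inside
#'   the band and saturation above the bound.
#' @param instrument_sat_max,instrument_lum_range Instrument rule:
#'   saturation below the bound with luminance inside the range.
#' @param cleanup_brush Diameter (pixels) of the disc brush used for
#'   morphological opening of the exposure mask; 0 disables cleanup.
#' @param miou_average `"image"` (mean foreground IoU over images, the
#'   default) or `"class"` (per pair, average the foreground and
#'   background IoU before averaging over images).
#' @return An object of class `seg_config`.
#' @export
seg_config <- function(view_lum_min = 0.03,
                       view_min_fraction = 0.05,
                       specular_lum_min = 0.90, specular_sat_max = 0.15,
                       dark_lum_max = 0.10,
                       fecal_hue_band = c(0.05, 0.17), fecal_sat_min = 0.55,
                       instrument_sat_max = 0.20,
                       instrument_lum_range = c(0.30, 0.88),
                       cleanup_brush = 3,
                       miou_average = c("image", "class")) {
  miou_average <- match.arg(miou_average)
  structure(
    list(view_lum_min = view_lum_min, view_min_fraction = view_min_fraction,
         specular_lum_min = specular_lum_min,
         specular_sat_max = specular_sat_max, dark_lum_max = dark_lum_max,
         fecal_hue_band = fecal_hue_band, fecal_sat_min = fecal_sat_min,
         instrument_sat_max = instrument_sat_max,
         instrument_lum_range = instrument_lum_range,
         cleanup_brush = cleanup_brush, miou_average = miou_average),
    class = "seg_config"
  )
}

# Fill the convex hull of a mask (even-odd rasterization of the hull
# polygon, then union with the input so hull-boundary pixels are kept).
convex_fill <- function(mask) {
  pts <- which(mask, arr.ind = TRUE)
  if (nrow(pts) < 3L) return(mask)
  hull <- grDevices::chull(pts[, 2], pts[, 1])
  vx <- pts[hull, 2]; vy <- pts[hull, 1]
  h <- nrow(mask); w <- ncol(mask)
  py <- rep(seq_len(h), w); px <- rep(seq_len(w), each = h)
  inside <- rep(FALSE, h * w)
  j <- length(vx)
  for (i in seq_along(vx)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  matrix(inside, h, w) | mask
}

largest_component <- function(mask) {
  lab <- EBImage::bwlabel(mask + 0)
  if (max(lab) < 1) return(mask & FALSE)
  areas <- tabulate(lab[lab > 0])
  lab == which.max(areas)
}

#' Segment the endoscopic field of view
#'
#' Baseline view segmenter: pixels above the near-black luminance floor,
#' largest connected component, hole filling, convex closure. The view
#' mask is the denominator of the per-frame exposure ratio; segmenting it
#' per frame removes the bias of different scope vendors/types masking
#' different portions of the video frame.
#'
#' @param frame RGB array or `ccmea_phantom`.
#' @param config A [seg_config()].
#' @return A logical matrix (single connected, hole-free region).
#' @export
segment_view <- function(frame, config = seg_config()) {
  frame <- as_rgb_frame(frame)
  assert_frame(frame)
  y <- luminance(frame)
  mask <- y > config$view_lum_min
  mask <- largest_component(mask)
  if (sum(mask) < config$view_min_fraction * length(mask)) {
    stop("no endoscopic view detected (frame near-black); ",
         "treat frame as unqualified", call. = FALSE)
  }
  mask <- EBImage::fillHull(mask + 0) > 0
  convex_fill(mask)
}

#' Segment the clearly exposed mucosa within the view
#'
#' Baseline exposure segmenter: removes, inside the view mask, pixels
#' matching the specular, dark, fecal/occlusion and instrument color
#' rules of the [seg_config()], then applies a small-object morphological
#' opening. The result is always a subset of the view.
#'
#' @param frame RGB array or `ccmea_phantom`.
#' @param view Logical matrix from [segment_view()] (or ground truth).
#' @param config A [seg_config()].
#' @return A logical matrix, subset of `view`.
#' @export
segment_exposure <- function(frame, view, config = seg_config()) {
  frame <- as_rgb_frame(frame)
  assert_frame(frame)
  assert_mask(view, "view")
  assert_same_shape(frame, view, c("frame", "view"))
  if (!any(view)) stop("view mask is empty", call. = FALSE)
  y <- luminance(frame)
  hsv <- frame_hsv(frame)
  specular <- y > config$specular_lum_min & hsv$s < config$specular_sat_max
  dark <- y < config$dark_lum_max
  fecal <- hue_in_band(hsv$h, config$fecal_hue_band[1], config$fecal_hue_band[2]) &
    hsv$s > config$fecal_sat_min
  instrument <- hsv$s < config$instrument_sat_max &
    y >= config$instrument_lum_range[1] & y <= config$instrument_lum_range[2]
  exposure <- view & !specular & !dark & !fecal & !instrument
  if (config$cleanup_brush >= 2 && any(exposure)) {
    brush <- EBImage::makeBrush(config$cleanup_brush, shape = "disc")
    exposure <- EBImage::opening(exposure + 0, brush) > 0
  }
  exposure & view
}

#' Dice coefficient of two binary masks
#'
#' `2|A∩B| / (|A| + |B|)`. Symmetric, in `[0, 1]`, and 1 exactly when the
#' masks are identical (given at least one non-empty mask). Two empty
#' masks are defined as perfect agreement on absence (Dice 1), reported
#' via a message per occurrence.
#'
#' @param a,b Logical matrices of the same shape.
#' @return A single number in `[0, 1]`.
#' @export
dice <- function(a, b) {
  assert_mask(a, "a"); assert_mask(b, "b")
  assert_same_shape(a, b, c("a", "b"))
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) {
    message("dice: both masks empty; returning 1 by convention")
    return(1)
  }
  2 * sum(a & b) / (sa + sb)
}

iou_pair <- function(a, b, class_average = FALSE) {
  assert_mask(a, "prediction"); assert_mask(b, "truth")
  assert_same_shape(a, b, c("prediction", "truth"))
  one <- function(x, y) {
    u <- sum(x | y)
    if (u == 0) 1 else sum(x & y) / u
  }
  if (class_average) (one(a, b) + one(!a, !b)) / 2 else one(a, b)
}

#' Mean intersection-over-union of prediction/truth mask pairs
#'
#' Averages the per-image foreground IoU `|A∩B| / |A∪B|` over a list of
#' `(prediction, truth)` pairs. With `config$miou_average = "class"`, each
#' pair contributes the mean of its foreground and background IoU
#' instead.
#'
#' @param pairs Non-empty list; each element a list/pair of two logical
#'   matrices `(prediction, truth)`.
#' @param config A [seg_config()] (controls the averaging convention).
#' @return A single number in `[0, 1]`; equals 1 iff every pair is
#'   identical.
#' @export
miou <- function(pairs, config = seg_config()) {
  if (length(pairs) == 0L) stop("miou needs at least one mask pair", call. = FALSE)
  vals <- vapply(pairs, function(p) {
    iou_pair(p[[1]], p[[2]], class_average = config$miou_average == "class")
  }, numeric(1))
  mean(vals)
}

#' Evaluate a segmenter against ground truth
#'
#' Computes per-image Dice and IoU plus their means for a list of
#' prediction/truth mask pairs — the standard report for judging a
#' view or exposure segmenter.
#'
#' @param predictions,truths Lists of logical matrices, same length.
#' @param config A [seg_config()].
#' @return An object of class `seg_eval_report`: list with `dice`,
#'   `miou`, and `per_image` (data frame of per-image dice and iou).
#' @export
seg_evaluate <- function(predictions, truths, config = seg_config()) {
  stopifnot(length(predictions) == length(truths), length(predictions) > 0)
  per <- data.frame(
    image = seq_along(predictions),
    dice = mapply(function(p, t) suppressMessages(dice(p, t)),
                  predictions, truths),
    iou = mapply(function(p, t) {
      iou_pair(p, t, class_average = config$miou_average == "class")
    }, predictions, truths)
  )
  structure(
    list(dice = mean(per$dice), miou = mean(per$iou), per_image = per),
    class = "seg_eval_report"
  )
}

#' @export
print.seg_eval_report <- function(x, ...) {
  cat(sprintf("Segmentation evaluation over %d images: Dice %.4f, mIoU %.4f\n",
              nrow(x$per_image), x$dice, x$miou))
  invisible(x)
}
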