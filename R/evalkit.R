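# Recall-first evaluation: confusion-matrix metrics, the false-negative
# reduction statistic, improvement percentages, per-organ reporting, paired
# significance tests and probability heatmap export.

#' Pixel confusion counts at a fixed threshold
#'
#' @param prob probability raster.
#' @param mask binary raster of the same shape.
#' @param threshold decision threshold (default 0.5; prediction is
#'   \code{prob >= threshold}).
#' @return a \code{ConfusionCounts}.
#' @export
confusionCounts <- function(prob, mask, threshold = 0.5) {
  if (!identical(dim(prob), dim(mask))) stop("prob and mask shapes differ")
  if (!isBinary(mask)) stop("mask must be binary")
  pred <- prob >= threshold
  pos <- mask > 0.5
  new("ConfusionCounts",
      tp = sum(pred & pos), fp = sum(pred & !pos),
      fn = sum(!pred & pos), tn = sum(!pred & !pos))
}

#' Confusion-matrix metrics
#'
#' recall = TP/(TP+FN), precision = TP/(TP+FP), dice = 2TP/(2TP+FP+FN),
#' iou = TP/(TP+FP+FN). Empty-denominator convention: an image with no
#' positive ground truth scores 1.0 on a metric if the prediction is also
#' empty, else 0 (documented convention for degenerate images).
#'
#' @param c a \code{ConfusionCounts}.
#' @return list(recall, precision, dice, iou).
#' @export
segMetrics <- function(c) {
  safe <- function(num, den) {
    if (den > 0) num / den else if (c@fp + c@fn == 0) 1 else 0
  }
  list(
    recall = safe(c@tp, c@tp + c@fn),
    precision = safe(c@tp, c@tp + c@fp),
    dice = safe(2 * c@tp, 2 * c@tp + c@fp + c@fn),
    iou = safe(c@tp, c@tp + c@fp + c@fn)
  )
}

#' False-negative reduction relative to a baseline
#'
#' Under the equal-true-positive assumption, recall R implies FN =
#' TP (1/R - 1); the relative reduction of missed detections is
#' \code{1 - (1/rOurs - 1) / (1/rBaseline - 1)}. Positive values mean fewer
#' missed detections than the baseline, negative values a more sensitive
#' baseline.
#'
#' @param rOurs,rBaseline recall fractions in (0, 1]; \code{rBaseline} must
#'   be < 1 (a perfect baseline has no false negatives to reduce).
#' @return fraction (multiply by 100 for percent).
#' @export
fnReduction <- function(rOurs, rBaseline) {
  if (rOurs <= 0 || rBaseline <= 0) stop("recalls must be strictly positive")
  if (rBaseline >= 1) stop("baseline recall of 1 leaves the statistic undefined")
  1 - (1 / rOurs - 1) / (1 / rBaseline - 1)
}

#' Relative improvement in percent
#'
#' \code{100 * (after - before) / before}.
#'
#' @param before,after metric values; \code{before} must be > 0.
#' @return percent change.
#' @export
improvementPct <- function(before, after) {
  if (before <= 0) stop("baseline value must be > 0")
  100 * (after - before) / before
}

#' Per-organ metric report
#'
#' Computes per-image metrics, averages them within each organ and reports an
#' aggregate row equal to the mean over all images.
#'
#' @param probs list of probability rasters.
#' @param masks list of matching binary masks.
#' @param organs organ label per sample.
#' @param threshold decision threshold.
#' @return data.frame with one row per organ plus an "all" aggregate row,
#'   columns organ, n, recall, precision, dice, iou.
#' @export
perOrganReport <- function(probs, masks, organs, threshold = 0.5) {
  stopifnot(length(probs) == length(masks), length(probs) == length(organs))
  per <- do.call(rbind, mapply(function(p, m) {
    as.data.frame(segMetrics(confusionCounts(p, m, threshold)))
  }, probs, masks, SIMPLIFY = FALSE))
  per$organ <- organs
  rows <- lapply(sort(unique(organs)), function(org) {
    sub <- per[per$organ == org, c("recall", "precision", "dice", "iou")]
    cbind(data.frame(organ = org, n = nrow(sub)), t(colMeans(sub)))
  })
  agg <- cbind(data.frame(organ = "all", n = nrow(per)),
               t(colMeans(per[, c("recall", "precision", "dice", "iou")])))
  out <- do.call(rbind, c(rows, list(agg)))
  rownames(out) <- NULL
  out
}

#' Paired significance tests on per-organ metric vectors
#'
#' Two-sided paired t-test and Wilcoxon signed-rank test, with the mean
#' difference and its 95% confidence interval. All-zero differences leave the
#' Wilcoxon statistic undefined and are reported as NA.
#'
#' @param before,after equal-length paired metric vectors (n >= 5).
#' @return list(tP, wilcoxonP, meanDiff, ci).
#' @export
pairedTests <- function(before, after) {
  stopifnot(length(before) == length(after), length(before) >= 5)
  d <- after - before
  if (all(d == 0)) {
    return(list(tP = NA_real_, wilcoxonP = NA_real_, meanDiff = 0,
                ci = c(0, 0)))
  }
  wp <- tryCatch(
    stats::wilcox.test(after, before, paired = TRUE, exact = FALSE)$p.value,
    error = function(e) NA_real_)
  # a perfectly constant non-zero shift has zero variance: the t statistic is
  # undefined, the mean difference exact
  if (stats::sd(d) == 0)
    return(list(tP = NA_real_, wilcoxonP = wp, meanDiff = mean(d),
                ci = c(mean(d), mean(d))))
  tt <- stats::t.test(after, before, paired = TRUE)
  list(tP = tt$p.value, wilcoxonP = wp, meanDiff = mean(d),
       ci = as.numeric(tt$conf.int))
}

#' Probability heatmap overlaid on the greyscale image
#'
#' Colour-maps the probability raster (cold blue through warm red/yellow) and
#' alpha-blends it over the greyscale base with alpha proportional to the
#' probability, so zero probability leaves the base untouched. Writes a PNG.
#'
#' @param image greyscale (or RGB) raster.
#' @param prob probability raster of the same H x W.
#' @param out output PNG path.
#' @return invisibly, the blended RGB array.
#' @export
heatmapOverlay <- function(image, prob, out) {
  g <- toGreyscale(image)
  if (!identical(dim(g), dim(prob))) stop("image and prob shapes differ")
  p <- clamp(prob, 0, 1)
  # warm colormap: hue from 240 deg (blue) down to 0 deg (red)
  col <- hsv2rgbNum(as.vector(240 * (1 - p)), rep(1, length(p)),
                    rep(1, length(p)))
  h <- nrow(g); w <- ncol(g)
  blend <- function(cmat) (1 - as.vector(p)) * as.vector(g) + as.vector(p) * cmat
  rgb <- array(c(blend(col$r), blend(col$g), blend(col$b)), dim = c(h, w, 3))
  png::writePNG(clamp(rgb, 0, 1), out)
  invisible(rgb)
}
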