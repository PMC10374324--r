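# Detection scoring: greedy matching at an IoU threshold, precision /
# recall / F1, and average precision as the area under the P-R curve.
#
# Detections are data frames with columns imageId, class, score, xmin, ymin,
# xmax, ymax. Ground truth is a data frame with imageId, class, xmin, ymin,
# xmax, ymax (or a list of ImageAnnotation objects, converted internally).

gt_frame <- function(gts) {
  if (is.data.frame(gts)) return(gts)
  do.call(rbind, lapply(gts, function(a) {
    b <- boundingBoxes(a)
    if (!nrow(b)) return(NULL)
    cbind(data.frame(imageId = imageId(a), stringsAsFactors = FALSE), b)
  })) %||% data.frame(imageId = character(), xmin = numeric(), ymin = numeric(),
                      xmax = numeric(), ymax = numeric(), class = character())
}

empty_dets <- function() {
  data.frame(imageId = character(), class = character(), score = numeric(),
             xmin = numeric(), ymin = numeric(), xmax = numeric(),
             ymax = numeric(), stringsAsFactors = FALSE)
}

#' Match detections to ground truth (VOC protocol)
#'
#' Detections are processed in descending score order; a detection is a true
#' positive when its best-IoU unmatched ground-truth box of the same class
#' and image reaches the IoU threshold, otherwise a false positive. Each
#' ground-truth box is matched at most once, so duplicate detections of one
#' object are penalized. Unmatched ground truth counts as false negatives.
#'
#' @param dets detection data.frame (imageId, class, score, xmin..ymax).
#' @param gts ground truth data.frame or list of ImageAnnotation.
#' @param iou_thresh matching threshold, default 0.5.
#' @return list with counts \code{tp, fp, fn} and logical vector
#'   \code{tp_flags} over detections in descending-score order (with the
#'   ordering in \code{order}).
#' @export
matchDetections <- function(dets, gts, iou_thresh = 0.5) {
  gts <- gt_frame(gts)
  if (is.null(dets) || !nrow(dets)) {
    return(list(tp = 0L, fp = 0L, fn = nrow(gts),
                tp_flags = logical(), order = integer()))
  }
  ord <- order(-dets$score)
  d <- dets[ord, , drop = FALSE]
  matched <- rep(FALSE, nrow(gts))
  flags <- logical(nrow(d))
  gm <- as.matrix(gts[, c("xmin", "ymin", "xmax", "ymax"), drop = FALSE])
  for (i in seq_len(nrow(d))) {
    cand <- which(!matched & gts$imageId == d$imageId[i] & gts$class == d$class[i])
    if (!length(cand)) next
    ious <- iou_one_many(as.numeric(d[i, c("xmin", "ymin", "xmax", "ymax")]),
                         gm[cand, , drop = FALSE])
    j <- which.max(ious)
    if (ious[j] >= iou_thresh) {
      matched[cand[j]] <- TRUE
      flags[i] <- TRUE
    }
  }
  list(tp = sum(flags), fp = sum(!flags), fn = sum(!matched),
       tp_flags = flags, order = ord)
}

#' Precision, recall and F1 from TP/FP/FN counts
#'
#' P = TP / (TP + FP), R = TP / (TP + FN), F1 = 2PR / (P + R). When both
#' P and R are zero (or their denominators vanish with \code{zero_division}
#' set), the affected metrics are 0.
#'
#' @param tp,fp,fn non-negative counts.
#' @param zero_division if TRUE (default), return 0 for metrics whose
#'   denominator is zero instead of raising an error.
#' @return named numeric vector (precision, recall, f1).
#' @examples
#' precisionRecallF1(21, 0, 3)   # P 1.0, R 0.875, F1 0.9333
#' @export
precisionRecallF1 <- function(tp, fp, fn, zero_division = TRUE) {
  if (any(c(tp, fp, fn) < 0)) stop("counts must be non-negative")
  pden <- tp + fp; rden <- tp + fn
  if ((pden == 0 || rden == 0) && !zero_division)
    stop("undefined metric: zero denominator (set zero_division = TRUE to return 0)")
  p <- if (pden > 0) tp / pden else 0
  r <- if (rden > 0) tp / rden else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f1 = f1)
}

# ranked TP flags + number of GT -> cumulative P/R points
pr_points_from_flags <- function(flags, n_gt) {
  if (!length(flags)) return(data.frame(recall = numeric(), precision = numeric()))
  tp_cum <- cumsum(flags)
  fp_cum <- cumsum(!flags)
  data.frame(recall = tp_cum / n_gt, precision = tp_cum / (tp_cum + fp_cum))
}

ap_from_points <- function(pts, n_gt, interpolation = "all") {
  if (!nrow(pts)) return(0)
  r <- c(0, pts$recall)
  p <- pts$precision
  # interpolated precision: max precision at recall >= r
  pint <- rev(cummax(rev(p)))
  if (interpolation == "all") {
    sum((r[-1] - r[-length(r)]) * pint)
  } else {  # 11-point
    mean(vapply(seq(0, 1, by = 0.1), function(rt) {
      ok <- pts$recall >= rt - 1e-12
      if (any(ok)) max(pint[ok]) else 0
    }, 0))
  }
}

#' Average precision of a scored detection set
#'
#' Sorts all detections by descending score, forms the cumulative
#' precision-recall curve, and integrates it. The default all-point
#' interpolation (max precision at recall >= r) evaluates the area under the
#' step curve exactly; the VOC2007 11-point variant is available.
#'
#' @param dets detections over the whole dataset.
#' @param gts ground truth (data.frame or list of ImageAnnotation).
#' @param iou_thresh matching threshold.
#' @param interpolation "all" (default) or "11point".
#' @param per_class if TRUE return a per-class vector plus its unweighted
#'   mean (mAP) as attribute; default reports the single-class/micro AP.
#' @return AP in [0, 1].
#' @export
averagePrecision <- function(dets, gts, iou_thresh = 0.5,
                             interpolation = c("all", "11point"),
                             per_class = FALSE) {
  interpolation <- match.arg(interpolation)
  gts <- gt_frame(gts)
  if (!nrow(gts)) stop("average precision needs at least one ground-truth box")
  if (is.null(dets)) dets <- empty_dets()
  if (per_class) {
    classes <- sort(unique(gts$class))
    aps <- vapply(classes, function(cl) {
      averagePrecision(dets[dets$class == cl, , drop = FALSE],
                       gts[gts$class == cl, , drop = FALSE],
                       iou_thresh, interpolation)
    }, 0)
    names(aps) <- classes
    attr(aps, "mAP") <- mean(aps)
    return(aps)
  }
  m <- matchDetections(dets, gts, iou_thresh)
  ap_from_points(pr_points_from_flags(m$tp_flags, nrow(gts)), nrow(gts),
                 interpolation)
}

#' Points of the precision-recall curve
#'
#' One (recall, precision) point per detection rank, in descending score
#' order. The recall sequence is non-decreasing; integrating the curve with
#' all-point interpolation reproduces \code{\link{averagePrecision}} exactly.
#'
#' @inheritParams averagePrecision
#' @param path optional CSV path; when given, the points are also written.
#' @return data.frame with columns recall, precision.
#' @export
prCurvePoints <- function(dets, gts, iou_thresh = 0.5, path = NULL) {
  gts <- gt_frame(gts)
  if (!nrow(gts)) stop("precision-recall curve needs ground truth")
  m <- matchDetections(dets, gts, iou_thresh)
  pts <- pr_points_from_flags(m$tp_flags, nrow(gts))
  if (!is.null(path)) utils::write.csv(pts, path, row.names = FALSE)
  pts
}

#' Full evaluation report for a detection set
#'
#' @inheritParams averagePrecision
#' @param score_thresh confidence threshold for the P/R/F1 operating point.
#' @return list: counts at the threshold, precision/recall/f1, AP, curve.
#' @export
evaluateDetections <- function(dets, gts, iou_thresh = 0.5, score_thresh = 0.5) {
  gts <- gt_frame(gts)
  if (is.null(dets)) dets <- empty_dets()
  keep <- dets[dets$score >= score_thresh, , drop = FALSE]
  m <- matchDetections(keep, gts, iou_thresh)
  prf <- precisionRecallF1(m$tp, m$fp, m$fn)
  list(tp = m$tp, fp = m$fp, fn = m$fn,
       precision = prf["precision"], recall = prf["recall"], f1 = prf["f1"],
       ap = averagePrecision(dets, gts, iou_thresh),
       curve = prCurvePoints(dets, gts, iou_thresh))
}
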