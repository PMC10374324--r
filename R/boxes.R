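#' Intersection over union of two axis-aligned boxes
#'
#' Boxes are length-4 numeric vectors (or 1-row data frames) in
#' \code{(xmin, ymin, xmax, ymax)} pixel coordinates.
#'
#' @param a,b boxes with xmin < xmax and ymin < ymax.
#' @return IoU in [0, 1]; 0 for disjoint boxes.
#' @examples
#' boxIoU(c(0, 0, 2, 2), c(1, 1, 3, 3))  # 1/7
#' @export
boxIoU <- function(a, b) {
  a <- as_box(a); b <- as_box(b)
  inter_w <- min(a[3], b[3]) - max(a[1], b[1])
  inter_h <- min(a[4], b[4]) - max(a[2], b[2])
  if (inter_w <= 0 || inter_h <= 0) return(0)
  inter <- inter_w * inter_h
  union <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  inter / union
}

as_box <- function(b) {
  if (is.data.frame(b)) b <- unlist(b[1, c("xmin", "ymin", "xmax", "ymax")])
  b <- as.numeric(b)[1:4]
  if (any(!is.finite(b))) stop("box coordinates must be finite")
  if (b[1] >= b[3] || b[2] >= b[4]) stop("degenerate box: need xmin < xmax and ymin < ymax")
  b
}

# Vectorized IoU of one box against a matrix of boxes (rows: xmin,ymin,xmax,ymax)
iou_one_many <- function(a, m) {
  iw <- pmin(a[3], m[, 3]) - pmax(a[1], m[, 1])
  ih <- pmin(a[4], m[, 4]) - pmax(a[2], m[, 2])
  inter <- pmax(iw, 0) * pmax(ih, 0)
  union <- (a[3] - a[1]) * (a[4] - a[2]) +
    (m[, 3] - m[, 1]) * (m[, 4] - m[, 2]) - inter
  ifelse(union > 0, inter / union, 0)
}

#' Convert a YOLO-format record to pixel-coordinate box
#'
#' A YOLO record is \code{(class_index, cx, cy, w, h)} with all of cx, cy, w,
#' h normalized to [0, 1] and the class index 0-based. Coordinates are scaled
#' to pixels and clipped to the image bounds (records that protrude, e.g.
#' after augmentation, are clipped rather than rejected).
#'
#' @param rec numeric vector (class_index, cx, cy, w, h).
#' @param width,height image size in pixels.
#' @param classes character vector of class names; \code{classes[index + 1]}
#'   names the record's class.
#' @return data.frame row with xmin, ymin, xmax, ymax, class.
#' @examples
#' yoloToBox(c(0, 0.5, 0.5, 0.5, 0.5), 100, 100, "grape")
#' @export
yoloToBox <- function(rec, width, height, classes) {
  rec <- as.numeric(rec)
  idx <- rec[1]
  if (idx < 0 || idx != round(idx)) stop("class_index must be a non-negative integer")
  if (idx + 1 > length(classes)) {
    stop(sprintf("class_index %d out of range for %d class(es)", idx, length(classes)))
  }
  cx <- rec[2]; cy <- rec[3]; w <- rec[4]; h <- rec[5]
  if (any(!is.finite(c(cx, cy, w, h)))) stop("YOLO record fields must be finite")
  if (cx < 0 || cx > 1 || cy < 0 || cy > 1) stop("cx, cy must lie in [0, 1]")
  if (w <= 0 || w > 1 || h <= 0 || h > 1) stop("w, h must lie in (0, 1]")
  xmin <- clamp((cx - w / 2) * width, 0, width)
  xmax <- clamp((cx + w / 2) * width, 0, width)
  ymin <- clamp((cy - h / 2) * height, 0, height)
  ymax <- clamp((cy + h / 2) * height, 0, height)
  data.frame(xmin = xmin, ymin = ymin, xmax = xmax, ymax = ymax,
             class = classes[idx + 1], stringsAsFactors = FALSE)
}

#' Convert a pixel-coordinate box to a YOLO-format record
#'
#' Inverse of \code{\link{yoloToBox}} for in-bounds boxes: returns the
#' normalized center/size encoding and 0-based class index.
#'
#' @param box data.frame row (or named vector) with xmin, ymin, xmax, ymax
#'   and class.
#' @param width,height image size in pixels.
#' @param classes class vocabulary.
#' @return numeric vector (class_index, cx, cy, w, h).
#' @export
boxToYolo <- function(box, width, height, classes) {
  cls <- if (is.data.frame(box)) box$class[1] else box[["class"]]
  idx <- match(cls, classes)
  if (is.na(idx)) stop(sprintf("class '%s' not in vocabulary", cls))
  b <- as_box(box)
  c(idx - 1,
    (b[1] + b[3]) / 2 / width, (b[2] + b[4]) / 2 / height,
    (b[3] - b[1]) / width, (b[4] - b[2]) / height)
}

#' Read a YOLO label file
#'
#' Parses a whitespace-delimited label file with one
#' \code{class_index cx cy w h} record per line into an
#' \linkS4class{ImageAnnotation}. An empty (or absent-object) file yields an
#' annotation with zero boxes.
#'
#' @param path label file.
#' @param width,height pixel size of the image the labels belong to.
#' @param classes class vocabulary (index 0 is the first entry).
#' @param imageId identifier for the annotation; defaults to the file stem.
#' @return An \linkS4class{ImageAnnotation}.
#' @export
readYoloLabels <- function(path, width, height, classes,
                           imageId = sub("\\.[^.]*$", "", basename(path))) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  boxes <- lapply(seq_along(lines), function(i) {
    fields <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(fields))
    if (length(fields) != 5L || any(is.na(vals))) {
      stop(sprintf("malformed YOLO record at line %d of %s: '%s'",
                   i, path, lines[i]))
    }
    yoloToBox(vals, width, height, classes)
  })
  boxes <- if (length(boxes)) do.call(rbind, boxes) else
    data.frame(xmin = numeric(), ymin = numeric(), xmax = numeric(),
               ymax = numeric(), class = character())
  imageAnnotation(imageId, width, height, boxes)
}

#' Write an annotation as a YOLO label file
#'
#' @param ann an \linkS4class{ImageAnnotation}.
#' @param path output .txt path.
#' @param classes class vocabulary defining the indices.
#' @export
writeYoloLabels <- function(ann, path, classes) {
  b <- boundingBoxes(ann)
  sz <- imageSize(ann)
  lines <- vapply(seq_len(nrow(b)), function(i) {
    r <- boxToYolo(b[i, ], sz["width"], sz["height"], classes)
    sprintf("%d %.10g %.10g %.10g %.10g", as.integer(r[1]), r[2], r[3], r[4], r[5])
  }, "")
  writeLines(lines, path)
  invisible(path)
}
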