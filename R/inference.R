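# Decoding raw head grids to scored boxes, non-maximum suppression, and the
# end-to-end detect() pipeline with aspect-preserving letterbox resizing.

#' Decode one raw prediction grid to detections
#'
#' Standard YOLO decoding: \code{bx = (sigmoid(tx) + cell_x) * stride},
#' \code{bw = anchor_w * exp(tw)}, score = sigmoid(objectness) *
#' sigmoid(class logit). Returns every (cell, anchor, class) candidate,
#' unfiltered.
#'
#' @param grid raw head array (S, S, 3 * (5 + C)).
#' @param anchors_scale 3 x 2 matrix of this scale's anchor (w, h) in input
#'   pixels.
#' @param stride grid stride in pixels (input_size / S).
#' @param classes class vocabulary (length C).
#' @param imageId id attached to the detections.
#' @return data.frame (imageId, class, score, xmin, ymin, xmax, ymax) in
#'   model-input pixel coordinates.
#' @export
decodeGrid <- function(grid, anchors_scale, stride, classes,
                       imageId = "image") {
  d <- dim(grid)
  C <- length(classes)
  if (d[3] != 3L * (5L + C))
    stop(sprintf("grid has %d channels, expected %d", d[3], 3L * (5L + C)))
  S <- d[1]
  anchors_scale <- as.matrix(anchors_scale)
  cell_x <- matrix(rep(0:(S - 1), each = S), S, S)   # column index, 0-based
  cell_y <- matrix(rep(0:(S - 1), times = S), S, S)
  out <- vector("list", 3L * C)
  k <- 0L
  for (a in 1:3) {
    off <- (a - 1L) * (5L + C)
    bx <- (plogis(grid[, , off + 1L]) + cell_x) * stride
    by <- (plogis(grid[, , off + 2L]) + cell_y) * stride
    bw <- anchors_scale[a, 1] * exp(clamp(grid[, , off + 3L], -10, 10))
    bh <- anchors_scale[a, 2] * exp(clamp(grid[, , off + 4L], -10, 10))
    pobj <- plogis(grid[, , off + 5L])
    for (cc in seq_len(C)) {
      score <- pobj * plogis(grid[, , off + 5L + cc])
      k <- k + 1L
      out[[k]] <- data.frame(
        imageId = imageId, class = classes[cc],
        score = as.numeric(score),
        xmin = as.numeric(bx - bw / 2), ymin = as.numeric(by - bh / 2),
        xmax = as.numeric(bx + bw / 2), ymax = as.numeric(by + bh / 2),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Non-maximum suppression
#'
#' Per class: keep the highest-scoring detection, suppress others whose IoU
#' with a kept box exceeds the threshold. Output is sorted by score
#' descending and is always a subset of the input.
#'
#' @param detections detection data.frame.
#' @param iou_threshold suppression IoU, default 0.45.
#' @param score_threshold minimum score kept, default 0.5.
#' @return filtered detection data.frame.
#' @export
nonMaxSuppression <- function(detections, iou_threshold = 0.45,
                              score_threshold = 0.5) {
  if (is.null(detections) || !nrow(detections)) return(empty_dets())
  d <- detections[detections$score >= score_threshold, , drop = FALSE]
  if (!nrow(d)) return(empty_dets())
  keep_all <- list()
  for (cl in unique(d$class)) {
    for (im in unique(d$imageId)) {
      s <- d[d$class == cl & d$imageId == im, , drop = FALSE]
      s <- s[order(-s$score), , drop = FALSE]
      m <- as.matrix(s[, c("xmin", "ymin", "xmax", "ymax")])
      alive <- rep(TRUE, nrow(s))
      for (i in seq_len(nrow(s))) {
        if (!alive[i]) next
        if (i < nrow(s)) {
          rest <- (i + 1):nrow(s)
          ious <- iou_one_many(m[i, ], m[rest, , drop = FALSE])
          alive[rest][ious > iou_threshold] <- FALSE
        }
      }
      keep_all[[length(keep_all) + 1L]] <- s[alive, , drop = FALSE]
    }
  }
  out <- do.call(rbind, keep_all)
  out <- out[order(-out$score), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Letterbox an image to a square canvas
#'
#' Aspect-preserving bilinear resize, centered with neutral-gray padding.
#'
#' @param image (H, W, 3) array.
#' @param size target side.
#' @param fill pad value, default 128.
#' @return list(image, scale, pad_x, pad_y) where
#'   \code{canvas = original * scale + pad}.
#' @export
letterboxImage <- function(image, size, fill = 128) {
  assert_image(image)
  d <- dim(image)
  sc <- min(size / d[1], size / d[2])
  nh <- max(1L, round(d[1] * sc)); nw <- max(1L, round(d[2] * sc))
  resized <- resize_image(image, nh, nw)
  canvas <- array(fill, c(size, size, d[3]))
  py <- (size - nh) %/% 2L; px <- (size - nw) %/% 2L
  canvas[py + seq_len(nh), px + seq_len(nw), ] <- resized
  list(image = canvas, scale = sc, pad_x = px, pad_y = py)
}

# map letterbox-canvas boxes back to original-image coordinates
unletterbox_boxes <- function(boxes, lb, width, height) {
  if (!nrow(boxes)) return(boxes)
  boxes$xmin <- clamp((boxes$xmin - lb$pad_x) / lb$scale, 0, width)
  boxes$xmax <- clamp((boxes$xmax - lb$pad_x) / lb$scale, 0, width)
  boxes$ymin <- clamp((boxes$ymin - lb$pad_y) / lb$scale, 0, height)
  boxes$ymax <- clamp((boxes$ymax - lb$pad_y) / lb$scale, 0, height)
  boxes[boxes$xmax > boxes$xmin & boxes$ymax > boxes$ymin, , drop = FALSE]
}

#' Detect objects in an image
#'
#' Letterboxes the image to the model input size, runs the network in
#' inference mode, decodes all three scales, applies the confidence
#' threshold and per-class NMS, and maps boxes back to original-image
#' coordinates (clipped to the image).
#'
#' @param model a \linkS4class{YoloModel}.
#' @param image (H, W, 3) array or an image file path.
#' @param conf_threshold minimum score, default 0.5.
#' @param nms_threshold NMS IoU, default 0.45.
#' @param imageId id for the detections; defaults to the file stem or
#'   "image".
#' @return detection data.frame in original-image coordinates.
#' @export
detectObjects <- function(model, image, conf_threshold = 0.5,
                          nms_threshold = 0.45, imageId = NULL) {
  if (is.character(image)) {
    if (!file.exists(image)) stop(sprintf("cannot read image '%s'", image))
    if (is.null(imageId)) imageId <- sub("\\.[^.]*$", "", basename(image))
    image <- readImageArray(image)
  }
  if (is.null(imageId)) imageId <- "image"
  assert_image(image)
  cfg <- model@config
  lb <- letterboxImage(image, cfg$input_size)
  heads <- model_forward(model, lb$image, training = FALSE)
  am <- as.matrix(anchors(cfg$anchors))
  groups <- list(am[1:3, , drop = FALSE], am[4:6, , drop = FALSE],
                 am[7:9, , drop = FALSE])
  strides <- c(8L, 16L, 32L)
  dets <- do.call(rbind, lapply(1:3, function(g) {
    decodeGrid(heads[[g]], groups[[g]], strides[g], cfg$classes, imageId)
  }))
  dets <- nonMaxSuppression(dets, nms_threshold, conf_threshold)
  d <- dim(image)
  unletterbox_boxes(dets, lb, d[2], d[1])
}
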