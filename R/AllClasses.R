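#' ImageAnnotation: one image's bounding-box ground truth
#'
#' Container for the annotation of a single image: its identifier, pixel
#' dimensions and a data frame of axis-aligned bounding boxes. Coordinates
#' are 0-based continuous pixel-edge coordinates, so a box spanning the whole
#' of a 100-px-wide image has \code{xmin = 0, xmax = 100}.
#'
#' @slot imageId character scalar identifying the image (file stem).
#' @slot width,height image size in pixels.
#' @slot boxes data.frame with columns \code{xmin, ymin, xmax, ymax}
#'   (numeric) and \code{class} (character); one row per object.
#'
#' @export
setClass("ImageAnnotation",
  representation(imageId = "character", width = "numeric",
                 height = "numeric", boxes = "data.frame"),
  prototype(imageId = "image", width = 1, height = 1,
            boxes = data.frame(xmin = numeric(), ymin = numeric(),
                               xmax = numeric(), ymax = numeric(),
                               class = character())))

setValidity("ImageAnnotation", function(object) {
  b <- object@boxes
  msg <- character()
  if (length(object@imageId) != 1L) msg <- c(msg, "imageId must be a single string")
  if (object@width <= 0 || object@height <= 0)
    msg <- c(msg, "width and height must be positive")
  need <- c("xmin", "ymin", "xmax", "ymax", "class")
  if (!all(need %in% names(b))) {
    msg <- c(msg, sprintf("boxes must have columns %s", paste(need, collapse = ", ")))
  } else if (nrow(b)) {
    if (any(!is.finite(b$xmin) | !is.finite(b$ymin) |
            !is.finite(b$xmax) | !is.finite(b$ymax)))
      msg <- c(msg, "box coordinates must be finite")
    else {
      if (any(b$xmin >= b$xmax | b$ymin >= b$ymax))
        msg <- c(msg, "every box needs xmin < xmax and ymin < ymax")
      if (any(b$xmin < 0 | b$ymin < 0 |
              b$xmax > object@width + 1e-6 | b$ymax > object@height + 1e-6))
        msg <- c(msg, "boxes must lie within the image bounds")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct an ImageAnnotation
#'
#' @param imageId image identifier (string).
#' @param width,height image size in pixels.
#' @param boxes data.frame with columns xmin, ymin, xmax, ymax, class.
#' @return An \linkS4class{ImageAnnotation} object.
#' @examples
#' imageAnnotation("img1", 100, 100,
#'                 data.frame(xmin = 10, ymin = 20, xmax = 40, ymax = 70,
#'                            class = "grape"))
#' @export
imageAnnotation <- function(imageId, width, height,
                            boxes = data.frame(xmin = numeric(), ymin = numeric(),
                                               xmax = numeric(), ymax = numeric(),
                                               class = character())) {
  boxes <- as.data.frame(boxes)
  if (nrow(boxes)) boxes$class <- as.character(boxes$class)
  rownames(boxes) <- NULL
  methods::new("ImageAnnotation", imageId = as.character(imageId),
               width = as.numeric(width), height = as.numeric(height),
               boxes = boxes)
}

#' AnchorSet: K-means anchor priors for the three detection scales
#'
#' Nine (width, height) anchor priors sorted by area, the mean-best-IoU
#' clustering accuracy over the boxes they were fitted to, and the grouping
#' of anchors onto the three prediction scales (smallest three anchors on the
#' finest grid).
#'
#' @slot anchors data.frame with columns \code{width}, \code{height}, sorted
#'   by area ascending (ties broken by width).
#' @slot accuracy mean over boxes of the best IoU to any anchor, in [0, 1].
#' @slot scaleGroups list of three integer vectors indexing \code{anchors};
#'   element 1 belongs to the stride-8 (finest) head.
#'
#' @export
setClass("AnchorSet",
  representation(anchors = "data.frame", accuracy = "numeric",
                 scaleGroups = "list"))

setValidity("AnchorSet", function(object) {
  a <- object@anchors
  msg <- character()
  if (!all(c("width", "height") %in% names(a)))
    msg <- c(msg, "anchors needs width and height columns")
  else if (any(a$width <= 0 | a$height <= 0))
    msg <- c(msg, "anchor dimensions must be positive")
  ar <- a$width * a$height
  if (is.unsorted(ar)) msg <- c(msg, "anchors must be sorted by area ascending")
  if (length(object@scaleGroups) && nrow(a) %% length(object@scaleGroups) != 0)
    msg <- c(msg, "anchors must divide evenly across scale groups")
  if (length(object@accuracy) == 1 && !is.na(object@accuracy) &&
      (object@accuracy < 0 || object@accuracy > 1))
    msg <- c(msg, "accuracy must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct an AnchorSet from widths and heights
#'
#' Anchors are sorted by area (ties broken by width) and, when there are
#' exactly nine, grouped three-per-scale with the largest anchors on the
#' coarsest (stride-32) grid.
#'
#' @param widths,heights anchor dimensions in pixels.
#' @param accuracy optional mean-best-IoU score of the set.
#' @return An \linkS4class{AnchorSet}.
#' @export
anchorSet <- function(widths, heights, accuracy = NA_real_) {
  a <- data.frame(width = as.numeric(widths), height = as.numeric(heights))
  ord <- order(a$width * a$height, a$width)
  a <- a[ord, , drop = FALSE]
  rownames(a) <- NULL
  n <- nrow(a)
  groups <- if (n %% 3 == 0) split(seq_len(n), rep(1:3, each = n / 3)) else list()
  names(groups) <- NULL
  methods::new("AnchorSet", anchors = a, accuracy = as.numeric(accuracy),
               scaleGroups = groups)
}

#' YoloModel: the assembled detection network
#'
#' Holds the architecture configuration and the network state (parameters and
#' batch-norm running statistics). The network state lives in an environment,
#' so a YoloModel has reference semantics: training updates it in place.
#'
#' @slot config list of architecture settings (input size, class vocabulary,
#'   stage repeats, base width, attention flag, anchors).
#' @slot net environment holding the layer graph and parameter tensors.
#'
#' @export
setClass("YoloModel",
  representation(config = "list", net = "environment"))
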