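# Anchor-box K-means. Boxes and centers are compared corner-anchored: two
# (w, h) pairs laid over the same corner, so IoU depends only on the shapes.

wh_iou <- function(w1, h1, w2, h2) {
  inter <- pmin(w1, w2) * pmin(h1, h2)
  inter / (w1 * h1 + w2 * h2 - inter)
}

# distance matrix boxes x centers under the chosen metric
anchor_dist <- function(boxes, centers, metric) {
  n <- nrow(boxes); k <- nrow(centers)
  if (metric == "iou") {
    d <- matrix(0, n, k)
    for (j in seq_len(k)) {
      d[, j] <- 1 - wh_iou(boxes[, 1], boxes[, 2], centers[j, 1], centers[j, 2])
    }
    d
  } else {
    outer(boxes[, 1], centers[, 1], "-")^2 + outer(boxes[, 2], centers[, 2], "-")^2
  }
}

#' Cluster ground-truth box sizes into anchor priors
#'
#' Lloyd-style K-means on (width, height) pairs with the 1 - IoU distance
#' (boxes corner-anchored), the standard metric for YOLO anchor fitting:
#' assignments go to the nearest center, centers are updated to the
#' per-cluster mean, and iteration stops when assignments no longer change.
#' Runs \code{restarts} seeded restarts and keeps the solution with the
#' lowest total within-cluster distance. Empty clusters are reseeded from the
#' point farthest from its current center.
#'
#' @param boxes two-column matrix or data.frame of box widths and heights
#'   (pixels), one row per ground-truth box.
#' @param k number of anchors (9 for the three-scale detector).
#' @param seed RNG seed for center initialization.
#' @param max_iter iteration cap per restart.
#' @param restarts number of random restarts.
#' @param metric "iou" (default) or "euclidean".
#' @return An \linkS4class{AnchorSet}; attribute \code{"history"} carries the
#'   total within-cluster distance after each Lloyd iteration of the winning
#'   restart.
#' @export
kmeansAnchors <- function(boxes, k = 9L, seed = 0L, max_iter = 300L,
                          restarts = 10L, metric = c("iou", "euclidean")) {
  metric <- match.arg(metric)
  boxes <- as.matrix(boxes)[, 1:2, drop = FALSE]
  storage.mode(boxes) <- "double"
  if (any(boxes <= 0)) stop("box widths and heights must be positive")
  distinct <- unique(boxes)
  if (nrow(distinct) < k) {
    stop(sprintf("k = %d exceeds the %d distinct box shapes", k, nrow(distinct)))
  }
  best <- NULL
  with_local_seed(seed, {
    for (r in seq_len(restarts)) {
      res <- lloyd_once(boxes, distinct, k, max_iter, metric)
      if (is.null(best) || res$total < best$total) best <- res
    }
  })
  acc <- anchorAccuracy(boxes, best$centers)
  out <- anchorSet(best$centers[, 1], best$centers[, 2], accuracy = acc)
  attr(out, "history") <- best$history
  out
}

lloyd_once <- function(boxes, distinct, k, max_iter, metric) {
  centers <- distinct[sample(nrow(distinct), k), , drop = FALSE]
  assign_prev <- rep(0L, nrow(boxes))
  history <- numeric()
  for (it in seq_len(max_iter)) {
    d <- anchor_dist(boxes, centers, metric)
    assign_cur <- max.col(-d, ties.method = "first")
    nearest <- d[cbind(seq_len(nrow(boxes)), assign_cur)]
    for (j in seq_len(k)) {                       # empty-cluster repair
      if (!any(assign_cur == j)) {
        far <- which.max(nearest)
        centers[j, ] <- boxes[far, ]
        assign_cur[far] <- j
        nearest[far] <- 0
      }
    }
    history <- c(history, sum(nearest))
    if (identical(assign_cur, assign_prev)) break
    assign_prev <- assign_cur
    for (j in seq_len(k)) {
      centers[j, ] <- colMeans(boxes[assign_cur == j, , drop = FALSE])
    }
  }
  d <- anchor_dist(boxes, centers, metric)
  list(centers = centers, total = sum(d[cbind(seq_len(nrow(boxes)),
                                              max.col(-d, ties.method = "first"))]),
       history = history)
}

#' Mean best IoU of a box population against an anchor set
#'
#' For each box, the best corner-anchored IoU to any anchor; averaged over
#' boxes. This is the clustering quality score reported alongside the
#' anchors.
#'
#' @param boxes two-column matrix/data.frame of (width, height).
#' @param anchors an \linkS4class{AnchorSet} or two-column matrix.
#' @return mean best IoU in [0, 1].
#' @export
anchorAccuracy <- function(boxes, anchors) {
  boxes <- as.matrix(boxes)[, 1:2, drop = FALSE]
  if (methods::is(anchors, "AnchorSet")) anchors <- as.matrix(anchors(anchors))
  anchors <- as.matrix(anchors)[, 1:2, drop = FALSE]
  if (!nrow(boxes) || !nrow(anchors)) stop("boxes and anchors must be non-empty")
  best <- rep(-Inf, nrow(boxes))
  for (j in seq_len(nrow(anchors))) {
    best <- pmax(best, wh_iou(boxes[, 1], boxes[, 2], anchors[j, 1], anchors[j, 2]))
  }
  mean(best)
}

#' Assign nine anchors to the three prediction scales
#'
#' Sorts anchors by area (ties broken by width) and groups them three per
#' scale: the smallest on the finest (stride-8) grid, the largest on the
#' coarsest (stride-32) grid.
#'
#' @param anchors an \linkS4class{AnchorSet} or 9-row (width, height) matrix.
#' @return list of three data.frames (fine, medium, coarse).
#' @export
assignAnchorsToScales <- function(anchors) {
  a <- if (methods::is(anchors, "AnchorSet")) anchors(anchors) else {
    m <- as.matrix(anchors)
    data.frame(width = m[, 1], height = m[, 2])
  }
  if (nrow(a) != 9L) stop("expected exactly 9 anchors")
  ord <- order(a$width * a$height, a$width)
  a <- a[ord, , drop = FALSE]
  rownames(a) <- NULL
  list(fine = a[1:3, ], medium = a[4:6, ], coarse = a[7:9, ])
}
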