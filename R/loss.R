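# Composite training loss: focal-modulated binary cross-entropy for
# confidence and class, Complete-IoU for box regression, summed over the
# three prediction scales and divided by the batch size. The natural
# logarithm is used throughout; predicted probabilities are clamped to
# [1e-7, 1 - 1e-7].

#' Focal loss configuration
#'
#' @param alpha positive-class weight in (0, 1), default 0.75.
#' @param gamma focusing exponent >= 0, default 2.
#' @param enabled if FALSE the plain (unweighted, gamma = 0) BCE is used.
#' @return list of class "FocalConfig".
#' @export
focalConfig <- function(alpha = 0.75, gamma = 2, enabled = TRUE) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (gamma < 0) stop("gamma must be non-negative")
  structure(list(alpha = alpha, gamma = gamma, enabled = enabled),
            class = "FocalConfig")
}

#' Loss configuration
#'
#' @param lambda_conf,lambda_cls,lambda_loc balance coefficients of the
#'   three terms (all default 1).
#' @param label_smoothing class-target smoothing epsilon, default 0.005:
#'   positives become 1 - eps/2, negatives eps/2.
#' @param focal a \code{\link{focalConfig}}.
#' @return list of class "LossConfig".
#' @export
lossConfig <- function(lambda_conf = 1, lambda_cls = 1, lambda_loc = 1,
                       label_smoothing = 0.005, focal = focalConfig()) {
  if (any(c(lambda_conf, lambda_cls, lambda_loc) < 0))
    stop("balance coefficients must be non-negative")
  structure(list(lambda_conf = lambda_conf, lambda_cls = lambda_cls,
                 lambda_loc = lambda_loc, label_smoothing = label_smoothing,
                 focal = focal),
            class = "LossConfig")
}

PROB_EPS <- 1e-7

#' Focal binary cross-entropy (elementwise)
#'
#' For a positive target: \code{-alpha (1-p)^gamma log(p)}; for a negative:
#' \code{-(1-alpha) p^gamma log(1-p)}. With gamma = 0 and alpha = 0.5 this is
#' half the standard BCE. Probabilities are clamped to [1e-7, 1 - 1e-7].
#'
#' @param p predicted probabilities.
#' @param y targets in \{0, 1\} (or soft targets in [0, 1], which mix the
#'   two branches linearly as under label smoothing).
#' @param alpha,gamma focal hyperparameters (defaults 0.75, 2).
#' @return elementwise losses, same shape as p.
#' @examples
#' focalBce(0.5, 1)  # 0.75 * 0.25 * log(2) ~ 0.1300
#' @export
focalBce <- function(p, y, alpha = 0.75, gamma = 2) {
  p <- clamp(p, PROB_EPS, 1 - PROB_EPS)
  pos <- -alpha * (1 - p)^gamma * log(p)
  neg <- -(1 - alpha) * p^gamma * log(1 - p)
  y * pos + (1 - y) * neg
}

#' Complete-IoU loss of a predicted box against ground truth
#'
#' \code{1 - IoU + rho^2/c^2 + alpha v}: the IoU shortfall plus the squared
#' center distance normalized by the enclosing-box diagonal and an
#' aspect-ratio-consistency penalty
#' \code{v = (4/pi^2)(atan(w_gt/h_gt) - atan(w/h))^2} with
#' \code{alpha = v / ((1 - IoU) + v)}. Zero iff the boxes coincide.
#'
#' @param pred,gt boxes as (xmin, ymin, xmax, ymax) vectors or 1-row
#'   data frames.
#' @return non-negative scalar.
#' @examples
#' ciouLoss(c(0, 0, 2, 2), c(1, 1, 3, 3))  # ~0.9683
#' @export
ciouLoss <- function(pred, gt) {
  a <- as_box(pred); b <- as_box(gt)
  iou <- boxIoU(a, b)
  rho2 <- ((a[1] + a[3]) / 2 - (b[1] + b[3]) / 2)^2 +
    ((a[2] + a[4]) / 2 - (b[2] + b[4]) / 2)^2
  cw <- max(a[3], b[3]) - min(a[1], b[1])
  ch <- max(a[4], b[4]) - min(a[2], b[2])
  c2 <- cw^2 + ch^2
  wa <- a[3] - a[1]; ha <- a[4] - a[2]
  wb <- b[3] - b[1]; hb <- b[4] - b[2]
  v <- 4 / pi^2 * (atan(wb / hb) - atan(wa / ha))^2
  alpha <- if (v > 0) v / ((1 - iou) + v) else 0
  unname(1 - iou + rho2 / c2 + alpha * v)
}

#' Assign ground-truth boxes to grid cells and anchors
#'
#' Each ground-truth box goes to its best wh-IoU anchor at the cell
#' containing its center, on that anchor's scale. Anchors with wh-IoU above
#' the ignore threshold to some box but not its best are removed from the
#' no-object mask, so they are neither pushed up nor down.
#'
#' @param ann \linkS4class{ImageAnnotation} (boxes in model input
#'   coordinates) or a box data.frame.
#' @param anchors an \linkS4class{AnchorSet} with 9 anchors.
#' @param input_size model input side (pixels).
#' @param classes class vocabulary.
#' @param ignore_thresh wh-IoU ignore threshold, default 0.5.
#' @return list of three per-scale target lists with elements \code{S},
#'   \code{stride}, masks \code{obj}/\code{noobj} (S, S, 3), regression
#'   targets \code{gx, gy, gw, gh} (S, S, 3) and class targets \code{cls}
#'   (S, S, 3 * C).
#' @export
buildTargets <- function(ann, anchors, input_size, classes,
                         ignore_thresh = 0.5) {
  boxes <- if (methods::is(ann, "ImageAnnotation")) boundingBoxes(ann) else ann
  am <- as.matrix(anchors(anchors))
  if (nrow(am) != 9L) stop("expected 9 anchors")
  C <- length(classes)
  strides <- c(8L, 16L, 32L)
  tg <- lapply(1:3, function(g) {
    S <- input_size %/% strides[g]
    list(S = S, stride = strides[g],
         obj = array(0, c(S, S, 3)), noobj = array(1, c(S, S, 3)),
         gx = array(0, c(S, S, 3)), gy = array(0, c(S, S, 3)),
         gw = array(1, c(S, S, 3)), gh = array(1, c(S, S, 3)),
         cls = array(0, c(S, S, 3 * C)))
  })
  for (i in seq_len(nrow(boxes))) {
    bw <- boxes$xmax[i] - boxes$xmin[i]
    bh <- boxes$ymax[i] - boxes$ymin[i]
    cx <- (boxes$xmin[i] + boxes$xmax[i]) / 2
    cy <- (boxes$ymin[i] + boxes$ymax[i]) / 2
    if (cx < 0 || cx > input_size || cy < 0 || cy > input_size)
      stop("box center outside the image")
    cidx <- match(boxes$class[i], classes)
    if (is.na(cidx)) stop(sprintf("class '%s' not in vocabulary", boxes$class[i]))
    ious <- wh_iou(bw, bh, am[, 1], am[, 2])
    jbest <- which.max(ious)
    for (j in seq_len(9L)) {
      g <- (j - 1L) %/% 3L + 1L
      a <- (j - 1L) %% 3L + 1L
      S <- tg[[g]]$S
      ix <- min(max(floor(cx / tg[[g]]$stride) + 1, 1), S)
      iy <- min(max(floor(cy / tg[[g]]$stride) + 1, 1), S)
      if (j == jbest) {
        tg[[g]]$obj[iy, ix, a] <- 1
        tg[[g]]$noobj[iy, ix, a] <- 0
        tg[[g]]$gx[iy, ix, a] <- cx
        tg[[g]]$gy[iy, ix, a] <- cy
        tg[[g]]$gw[iy, ix, a] <- bw
        tg[[g]]$gh[iy, ix, a] <- bh
        tg[[g]]$cls[iy, ix, (a - 1L) * C + cidx] <- 1
      } else if (ious[j] > ignore_thresh) {
        tg[[g]]$noobj[iy, ix, a] <- 0
      }
    }
  }
  tg
}

# ---- tensor-side loss -------------------------------------------------------

# elementwise focal positive/negative branches on a probability tensor
ad_focal_branches <- function(p, focal) {
  p <- ad_clamp(p, PROB_EPS, 1 - PROB_EPS)
  one <- ad_tensor(array(1, dim(p$value)))
  q <- ad_sub(one, p)
  if (isTRUE(focal$enabled)) {
    list(pos = ad_scale(ad_mul(ad_powc(q, focal$gamma), ad_log(p)), -focal$alpha),
         neg = ad_scale(ad_mul(ad_powc(p, focal$gamma), ad_log(q)), -(1 - focal$alpha)))
  } else {
    list(pos = ad_neg(ad_log(p)), neg = ad_neg(ad_log(q)))
  }
}

# elementwise CIoU from center/size tensors (pred) and constant arrays (gt);
# the alpha coefficient is detached, following standard CIoU practice
ad_ciou_grid <- function(px, py, pw, ph, gx, gy, gw, gh) {
  half <- function(t) ad_scale(t, 0.5)
  x1a <- ad_sub(px, half(pw)); x2a <- ad_add(px, half(pw))
  y1a <- ad_sub(py, half(ph)); y2a <- ad_add(py, half(ph))
  x1b <- gx - gw / 2; x2b <- gx + gw / 2
  y1b <- gy - gh / 2; y2b <- gy + gh / 2
  iw <- ad_relu(ad_sub(ad_min2(x2a, ad_tensor(x2b)), ad_max2(x1a, ad_tensor(x1b))))
  ih <- ad_relu(ad_sub(ad_min2(y2a, ad_tensor(y2b)), ad_max2(y1a, ad_tensor(y1b))))
  inter <- ad_mul(iw, ih)
  union <- ad_add(ad_sub(ad_mul(pw, ph), inter), gw * gh)
  iou <- ad_div(inter, ad_add(union, 1e-9))
  rho2 <- ad_add(ad_square(ad_sub(px, ad_tensor(gx))),
                 ad_square(ad_sub(py, ad_tensor(gy))))
  cw <- ad_sub(ad_max2(x2a, ad_tensor(x2b)), ad_min2(x1a, ad_tensor(x1b)))
  chh <- ad_sub(ad_max2(y2a, ad_tensor(y2b)), ad_min2(y1a, ad_tensor(y1b)))
  c2 <- ad_add(ad_add(ad_square(cw), ad_square(chh)), 1e-9)
  v <- ad_scale(ad_square(ad_sub(ad_tensor(atan(gw / gh)),
                                 ad_atan(ad_div(pw, ad_add(ph, 1e-9))))),
                4 / pi^2)
  one <- ad_tensor(array(1, dim(iou$value)))
  alpha <- ad_detach(ad_div(v, ad_add(ad_add(ad_sub(one, iou), v), 1e-9)))
  ad_add(ad_add(ad_sub(one, iou), ad_div(rho2, c2)), ad_mul(alpha, v))
}

# per-scale loss components; head is an (S, S, 3*(5+C)) tensor
loss_for_scale <- function(head, tgt, anchors_scale, cfg, num_classes) {
  S <- tgt$S
  stride <- tgt$stride
  C <- num_classes
  grid_x <- array(rep(0:(S - 1), each = S), c(S, S, 1))   # column index
  grid_y <- array(rep(0:(S - 1), times = S), c(S, S, 1))  # row index
  conf <- NULL; clsl <- NULL; locl <- NULL
  add0 <- function(acc, t) if (is.null(acc)) t else ad_add(acc, t)
  for (a in 1:3) {
    off <- (a - 1L) * (5L + C)
    obj_m <- array(tgt$obj[, , a], c(S, S, 1))
    noobj_m <- array(tgt$noobj[, , a], c(S, S, 1))
    # confidence
    p_obj <- ad_sigmoid(ad_slice_c(head, off + 5L))
    br <- ad_focal_branches(p_obj, cfg$focal)
    conf <- add0(conf, ad_sum(ad_add(ad_mul(ad_tensor(obj_m), br$pos),
                                     ad_mul(ad_tensor(noobj_m), br$neg))))
    # classification (label-smoothed soft targets)
    if (C > 0 && sum(obj_m) > 0) {
      eps <- cfg$label_smoothing
      for (cc in seq_len(C)) {
        y <- array(tgt$cls[, , (a - 1L) * C + cc], c(S, S, 1))
        yhat <- y * (1 - eps) + eps / 2
        p_cls <- ad_sigmoid(ad_slice_c(head, off + 5L + cc))
        brc <- ad_focal_branches(p_cls, cfg$focal)
        el <- ad_add(ad_mul(ad_tensor(yhat), brc$pos),
                     ad_mul(ad_tensor(1 - yhat), brc$neg))
        clsl <- add0(clsl, ad_sum(ad_mul(ad_tensor(obj_m), el)))
      }
    }
    # location (CIoU on decoded boxes, object cells only)
    if (sum(obj_m) > 0) {
      tx <- ad_slice_c(head, off + 1L)
      ty <- ad_slice_c(head, off + 2L)
      tw <- ad_clamp_st(ad_slice_c(head, off + 3L), -10, 10)
      th <- ad_clamp_st(ad_slice_c(head, off + 4L), -10, 10)
      px <- ad_scale(ad_add(ad_sigmoid(tx), ad_tensor(grid_x)), stride)
      py <- ad_scale(ad_add(ad_sigmoid(ty), ad_tensor(grid_y)), stride)
      pw <- ad_scale(ad_exp(tw), anchors_scale[a, 1])
      ph <- ad_scale(ad_exp(th), anchors_scale[a, 2])
      gx <- array(tgt$gx[, , a], c(S, S, 1)); gy <- array(tgt$gy[, , a], c(S, S, 1))
      gw <- array(tgt$gw[, , a], c(S, S, 1)); gh <- array(tgt$gh[, , a], c(S, S, 1))
      ci <- ad_ciou_grid(px, py, pw, ph, gx, gy, gw, gh)
      locl <- add0(locl, ad_sum(ad_mul(ad_tensor(obj_m), ci)))
    }
  }
  zero <- function(x) if (is.null(x)) ad_tensor(0) else x
  list(conf = zero(conf), cls = zero(clsl), loc = zero(locl))
}

# full tensor loss over the three scales (heads: list of tensors)
loss_tensor <- function(heads, targets, anchors, cfg, num_classes, batch_size = 1) {
  am <- as.matrix(anchors(anchors))
  groups <- list(am[1:3, , drop = FALSE], am[4:6, , drop = FALSE],
                 am[7:9, , drop = FALSE])
  total <- NULL
  comp <- c(conf = 0, cls = 0, loc = 0)
  for (g in 1:3) {
    l <- loss_for_scale(heads[[g]], targets[[g]], groups[[g]], cfg, num_classes)
    term <- ad_add(ad_add(ad_scale(l$conf, cfg$lambda_conf),
                          ad_scale(l$cls, cfg$lambda_cls)),
                   ad_scale(l$loc, cfg$lambda_loc))
    total <- if (is.null(total)) term else ad_add(total, term)
    comp <- comp + c(conf = as.numeric(l$conf$value),
                     cls = as.numeric(l$cls$value),
                     loc = as.numeric(l$loc$value))
  }
  total <- ad_scale(total, 1 / batch_size)
  list(total = total, components = comp / batch_size)
}

# ---- numeric (array) API ----------------------------------------------------

head_as_tensor <- function(head) {
  if (is_ad(head)) head else ad_tensor(head)
}

#' Confidence loss of one prediction scale
#'
#' Focal-modulated BCE of the objectness channel: positive branch over
#' object cells, negative branch over no-object cells, ignore-region cells
#' excluded; sum reduction.
#'
#' @param head raw head grid, (S, S, 3 * (5 + C)) array of logits.
#' @param target one per-scale element of \code{\link{buildTargets}}.
#' @param cfg a \code{\link{lossConfig}}.
#' @param num_classes number of classes C.
#' @return non-negative scalar.
#' @export
confidenceLoss <- function(head, target, cfg = lossConfig(), num_classes = 1L) {
  check_head_shape(head, target, num_classes)
  l <- loss_for_scale(head_as_tensor(head), target,
                      matrix(1, 3, 2), cfg, num_classes)
  as.numeric(l$conf$value)
}

#' Classification loss of one prediction scale
#'
#' Focal-modulated BCE of the class channels over object cells only, with
#' label-smoothed targets (positive 1 - eps/2, negative eps/2).
#'
#' @inheritParams confidenceLoss
#' @return non-negative scalar.
#' @export
classificationLoss <- function(head, target, cfg = lossConfig(), num_classes = 1L) {
  check_head_shape(head, target, num_classes)
  l <- loss_for_scale(head_as_tensor(head), target,
                      matrix(1, 3, 2), cfg, num_classes)
  as.numeric(l$cls$value)
}

#' Total composite loss over the three scales
#'
#' \code{(sum over scales of lambda_conf L_conf + lambda_cls L_cls +
#' lambda_loc L_loc) / batch_size}, with the location term the CIoU sum over
#' object cells of boxes decoded against the scale's anchors.
#'
#' @param heads list of three raw head grids (arrays of logits).
#' @param targets output of \code{\link{buildTargets}}.
#' @param anchors the \linkS4class{AnchorSet} used for decoding.
#' @param cfg a \code{\link{lossConfig}}.
#' @param num_classes number of classes.
#' @param batch_size divisor, default 1.
#' @return list(total, components) with the per-term breakdown.
#' @export
totalLoss <- function(heads, targets, anchors, cfg = lossConfig(),
                      num_classes = 1L, batch_size = 1) {
  ht <- lapply(heads, head_as_tensor)
  l <- loss_tensor(ht, targets, anchors, cfg, num_classes, batch_size)
  list(total = as.numeric(l$total$value), components = l$components)
}

check_head_shape <- function(head, target, num_classes) {
  d <- if (is_ad(head)) dim(head$value) else dim(head)
  if (d[1] != target$S || d[2] != target$S || d[3] != 3L * (5L + num_classes))
    stop(sprintf("head shape (%d,%d,%d) does not match target S=%d, C=%d",
                 d[1], d[2], d[3], target$S, num_classes))
}
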