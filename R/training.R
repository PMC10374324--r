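# Two-stage training: a frozen-backbone stage then a full fine-tune, each
# with a cosine-annealed learning rate restarting at the stage boundary.
# Optimization is Adam; batches are processed one sample at a time with
# gradient accumulation (deterministic under the run seed).

#' Training schedule
#'
#' Defaults follow the two-stage recipe: stage 1 trains the neck and heads
#' with the backbone frozen (30 epochs, batch 8, initial learning rate
#' 1e-3), stage 2 fine-tunes everything (10 epochs, batch 2, 1e-4). Input
#' content is randomly rescaled within the letterboxed canvas by a factor
#' drawn from \code{scale_range} (0.7-0.9).
#'
#' @param stage1,stage2 lists with \code{epochs}, \code{batch}, \code{lr0},
#'   \code{frozen}; set a stage to NULL to skip it.
#' @param scale_range random-scale magnification range, or NULL to disable.
#' @param mosaic logical: compose 4-image mosaics at batch time.
#' @param seed run seed.
#' @return list of class "TrainingSchedule".
#' @export
trainingSchedule <- function(
    stage1 = list(epochs = 30L, batch = 8L, lr0 = 1e-3, frozen = TRUE),
    stage2 = list(epochs = 10L, batch = 2L, lr0 = 1e-4, frozen = FALSE),
    scale_range = c(0.7, 0.9), mosaic = FALSE, seed = 0L) {
  stages <- Filter(Negate(is.null), list(stage1, stage2))
  for (s in stages) {
    if (s$epochs <= 0 || s$batch <= 0 || s$lr0 <= 0)
      stop("each stage needs positive epochs, batch and lr0")
  }
  if (!is.null(scale_range) &&
      (any(scale_range <= 0) || any(scale_range > 1) ||
       scale_range[1] > scale_range[2]))
    stop("scale_range must lie within (0, 1]")
  structure(list(stages = stages, scale_range = scale_range,
                 mosaic = isTRUE(mosaic), seed = as.integer(seed)),
            class = "TrainingSchedule")
}

#' Cosine-annealed learning rate
#'
#' \code{lr_min + 0.5 (lr0 - lr_min)(1 + cos(pi step / total))}; steps past
#' the end clamp to \code{lr_min}.
#'
#' @param step current step (0-based).
#' @param total_steps schedule length.
#' @param lr0 initial rate.
#' @param lr_min floor, default \code{0.01 * lr0}.
#' @return learning rate.
#' @examples
#' cosineLr(0, 100, 1e-3)    # 1e-3
#' cosineLr(100, 100, 1e-3)  # 1e-5
#' @export
cosineLr <- function(step, total_steps, lr0, lr_min = 0.01 * lr0) {
  if (step < 0) stop("step must be non-negative")
  if (step >= total_steps) return(lr_min)
  lr_min + 0.5 * (lr0 - lr_min) * (1 + cos(pi * step / total_steps))
}

#' Random-scale letterbox resize
#'
#' Letterboxes the image into a square canvas, then shrinks the content by a
#' magnification factor drawn uniformly from \code{scale_range} (so box
#' areas scale by exactly s^2 relative to the plain letterbox). The content
#' stays centered; boxes are mapped through the same similarity transform.
#'
#' @param image (H, W, 3) array.
#' @param boxes box data.frame (xmin..ymax, class) in image coordinates.
#' @param size canvas side in pixels.
#' @param scale_range range of s; c(1, 1) is a plain letterbox.
#' @param seed RNG seed for the draw.
#' @param fill pad value.
#' @return list(image, boxes, scale) in canvas coordinates.
#' @export
randomScaleResize <- function(image, boxes, size, scale_range = c(0.7, 0.9),
                              seed = 0L, fill = 128) {
  assert_image(image)
  s <- with_local_seed(seed, stats::runif(1, scale_range[1], scale_range[2]))
  d <- dim(image)
  sc <- min(size / d[1], size / d[2]) * s
  nh <- max(1L, round(d[1] * sc)); nw <- max(1L, round(d[2] * sc))
  resized <- resize_image(image, nh, nw)
  canvas <- array(fill, c(size, size, 3))
  py <- (size - nh) %/% 2L; px <- (size - nw) %/% 2L
  canvas[py + seq_len(nh), px + seq_len(nw), ] <- resized
  if (nrow(boxes)) {
    boxes$xmin <- boxes$xmin * sc + px; boxes$xmax <- boxes$xmax * sc + px
    boxes$ymin <- boxes$ymin * sc + py; boxes$ymax <- boxes$ymax * sc + py
  }
  list(image = canvas, boxes = boxes, scale = s)
}

# 4-image mosaic composite on the training canvas
mosaic_sample <- function(samples, size, seed) {
  with_local_seed(seed, {
    idx <- sample(length(samples), 4, replace = length(samples) < 4)
    cx <- round(stats::runif(1, 0.3, 0.7) * size)
    cy <- round(stats::runif(1, 0.3, 0.7) * size)
    canvas <- array(128, c(size, size, 3))
    quads <- list(c(1, cy, 1, cx), c(1, cy, cx + 1, size),
                  c(cy + 1, size, 1, cx), c(cy + 1, size, cx + 1, size))
    boxes <- NULL
    for (q in 1:4) {
      s <- samples[[idx[q]]]
      qd <- quads[[q]]
      qh <- qd[2] - qd[1] + 1L; qw <- qd[4] - qd[3] + 1L
      if (qh < 2 || qw < 2) next
      d <- dim(s$image)
      sc <- max(qh / d[1], qw / d[2])   # cover the quadrant
      rs <- resize_image(s$image, max(qh, round(d[1] * sc)),
                         max(qw, round(d[2] * sc)))
      canvas[qd[1]:qd[2], qd[3]:qd[4], ] <- rs[seq_len(qh), seq_len(qw), ]
      b <- boundingBoxes(s$annotation)
      if (nrow(b)) {
        b$xmin <- clamp(b$xmin * sc + qd[3] - 1, qd[3] - 1, qd[4])
        b$xmax <- clamp(b$xmax * sc + qd[3] - 1, qd[3] - 1, qd[4])
        b$ymin <- clamp(b$ymin * sc + qd[1] - 1, qd[1] - 1, qd[2])
        b$ymax <- clamp(b$ymax * sc + qd[1] - 1, qd[1] - 1, qd[2])
        b <- b[b$xmax - b$xmin > 2 & b$ymax - b$ymin > 2, , drop = FALSE]
        boxes <- rbind(boxes, b)
      }
    }
    list(image = canvas,
         boxes = boxes %||% data.frame(xmin = numeric(), ymin = numeric(),
                                       xmax = numeric(), ymax = numeric(),
                                       class = character()))
  })
}

#' Train a model
#'
#' Runs the staged schedule with Adam. Stage 1 (if \code{frozen}) leaves
#' every backbone parameter untouched; stage 2 updates all parameters. The
#' cosine annealing restarts at each stage boundary. Per-epoch mean total
#' loss and its confidence/class/location components are recorded; training
#' aborts with a diagnostic if the loss turns non-finite.
#'
#' @param model a \linkS4class{YoloModel} (updated in place and returned).
#' @param dataset list of \code{list(image =, annotation =)} samples, or a
#'   VOC-layout directory.
#' @param schedule a \code{\link{trainingSchedule}}.
#' @param loss_cfg a \code{\link{lossConfig}}.
#' @param checkpoint_dir optional directory for per-stage weight files.
#' @param verbose print per-epoch losses.
#' @return list(model, history) where history is a data.frame with one row
#'   per epoch (stage, epoch, lr, loss, conf, cls, loc).
#' @export
fitYolo <- function(model, dataset, schedule = trainingSchedule(),
                    loss_cfg = lossConfig(), checkpoint_dir = NULL,
                    verbose = FALSE) {
  if (is.character(dataset)) dataset <- load_voc_samples(dataset)
  if (!length(dataset)) stop("empty dataset")
  cfg <- model@config
  net <- model@net
  opt <- new.env(parent = emptyenv())
  opt$m <- list(); opt$v <- list(); opt$t <- 0
  history <- list()
  step_seed <- schedule$seed
  for (si in seq_along(schedule$stages)) {
    st <- schedule$stages[[si]]
    trainable <- names(net$params)
    if (isTRUE(st$frozen)) trainable <- grep("^backbone\\.", trainable,
                                             invert = TRUE, value = TRUE)
    n <- length(dataset)
    steps_per_epoch <- max(1L, ceiling(n / st$batch))
    total_steps <- st$epochs * steps_per_epoch
    gstep <- 0L
    for (ep in seq_len(st$epochs)) {
      ord <- with_local_seed(step_seed + 1000L * si + ep, sample(n))
      ep_loss <- c(total = 0, conf = 0, cls = 0, loc = 0)
      lr <- NA_real_
      for (bs in seq_len(steps_per_epoch)) {
        take <- ord[((bs - 1L) * st$batch + 1L):min(bs * st$batch, n)]
        take <- take[!is.na(take)]
        lr <- cosineLr(gstep, total_steps, st$lr0)
        ad_zero_grad(net$params)
        bl <- c(total = 0, conf = 0, cls = 0, loc = 0)
        for (ii in seq_along(take)) {
          sseed <- (step_seed + 7L * gstep + 13L * ii) %% .Machine$integer.max
          smp <- dataset[[take[ii]]]
          use_mosaic <- schedule$mosaic &&
            with_local_seed(sseed + 1L, stats::runif(1)) < 0.5
          if (use_mosaic) {
            ms <- mosaic_sample(dataset, cfg$input_size, sseed)
            canvas <- ms$image; boxes <- ms$boxes
          } else {
            rr <- randomScaleResize(smp$image, boundingBoxes(smp$annotation),
                                    cfg$input_size,
                                    schedule$scale_range %||% c(1, 1), sseed)
            canvas <- rr$image; boxes <- rr$boxes
          }
          tgt <- buildTargets(boxes, cfg$anchors, cfg$input_size, cfg$classes)
          heads <- model_forward(model, canvas, training = TRUE)
          l <- loss_tensor(heads, tgt, cfg$anchors, loss_cfg,
                           cfg$num_classes, batch_size = length(take))
          if (!is.finite(l$total$value))
            stop(sprintf("non-finite loss at stage %d epoch %d step %d (components: %s)",
                         si, ep, bs, paste(round(l$components, 4), collapse = "/")))
          ad_backward(l$total)
          bl <- bl + c(total = as.numeric(l$total$value), l$components)
        }
        adam_step(net$params, trainable, opt, lr)
        ep_loss <- ep_loss + bl
        gstep <- gstep + 1L
      }
      ep_loss <- ep_loss / steps_per_epoch
      history[[length(history) + 1L]] <- data.frame(
        stage = si, epoch = ep, lr = lr, loss = ep_loss["total"],
        conf = ep_loss["conf"], cls = ep_loss["cls"], loc = ep_loss["loc"])
      if (verbose)
        message(sprintf("stage %d epoch %3d lr %.2e loss %.4f (conf %.3f cls %.3f loc %.3f)",
                        si, ep, lr, ep_loss["total"], ep_loss["conf"],
                        ep_loss["cls"], ep_loss["loc"]))
    }
    if (!is.null(checkpoint_dir)) {
      dir.create(checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
      saveModelWeights(model, file.path(checkpoint_dir,
                                        sprintf("stage%d.rds", si)))
    }
  }
  hist <- do.call(rbind, history)
  rownames(hist) <- NULL
  list(model = model, history = hist)
}

adam_step <- function(params, trainable, opt, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1
  b1t <- 1 - beta1^opt$t
  b2t <- 1 - beta2^opt$t
  for (nm in trainable) {
    p <- params[[nm]]
    if (is.null(p$grad)) next
    g <- p$grad
    m <- opt$m[[nm]] %||% (g * 0)
    v <- opt$v[[nm]] %||% (g * 0)
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    opt$m[[nm]] <- m
    opt$v[[nm]] <- v
    p$value <- p$value - lr * (m / b1t) / (sqrt(v / b2t) + eps)
  }
  invisible(NULL)
}
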