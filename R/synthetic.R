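# Seeded synthetic orchard scenes: leafy-textured backgrounds, grape
# bunches rendered as clusters of shaded berry ellipses with a stem, and
# leaf-shaped occluders covering a requested fraction of each bunch. The
# ground-truth box always covers the full bunch extent, occluded or not,
# mirroring how whole clusters are annotated in vineyard datasets.

#' Specify a synthetic orchard scene
#'
#' @param image_size square image side in pixels (default 256).
#' @param n_bunches number of grape bunches (default 3).
#' @param occlusion_fraction target fraction of each bunch's area hidden by
#'   leaf occluders, in [0, 0.8].
#' @param illumination "front", "back" or "low".
#' @param background_clutter leafy-texture contrast in [0, 1].
#' @param seed RNG seed; the scene is a pure function of the spec.
#' @return list of class "SceneSpec".
#' @export
sceneSpec <- function(image_size = 256L, n_bunches = 3L,
                      occlusion_fraction = 0, illumination = "front",
                      background_clutter = 0.5, seed = 0L) {
  if (occlusion_fraction < 0 || occlusion_fraction > 0.8)
    stop("occlusion_fraction must lie in [0, 0.8]")
  if (!illumination %in% c("front", "back", "low"))
    stop("illumination must be front, back or low")
  structure(list(image_size = as.integer(image_size),
                 n_bunches = as.integer(n_bunches),
                 occlusion_fraction = occlusion_fraction,
                 illumination = illumination,
                 background_clutter = background_clutter,
                 seed = as.integer(seed)),
            class = "SceneSpec")
}

# filled-ellipse pixel mask on an S x S grid
ellipse_mask <- function(S, cy, cx, ry, rx, theta = 0) {
  y <- matrix(seq_len(S), S, S) - cy
  x <- matrix(seq_len(S), S, S, byrow = TRUE) - cx
  yr <- cos(theta) * y + sin(theta) * x
  xr <- -sin(theta) * y + cos(theta) * x
  (yr / ry)^2 + (xr / rx)^2 <= 1
}

paint <- function(img, mask, rgb, shade = NULL) {
  for (c in 1:3) {
    ch <- img[, , c]
    v <- rgb[c]
    ch[mask] <- if (is.null(shade)) v else clamp(v * shade[mask], 0, 255)
    img[, , c] <- ch
  }
  img
}

#' Render a synthetic orchard scene
#'
#' Deterministically renders the scene described by a \code{\link{sceneSpec}}:
#' a mottled green background, each bunch as 18-35 overlapping shaded berry
#' ellipses under a stem, leaf occluders grown until the measured cover of
#' the bunch mask is within 2 percent of the requested occlusion fraction,
#' and a global illumination grade. Bunches are placed by rejection sampling;
#' an error is raised if they cannot fit without crossing the image bounds.
#'
#' @param spec a \code{\link{sceneSpec}}.
#' @return list(image, annotation, occlusion) where occlusion is the
#'   measured per-bunch occluder coverage of the bunch mask.
#' @export
generateScene <- function(spec) {
  S <- spec$image_size
  with_local_seed(spec$seed, {
    # background: green mottle driven by two smooth fields
    f1 <- smooth_field(S, S, seed = spec$seed * 3L + 1L, waves = 4L)
    f2 <- smooth_field(S, S, seed = spec$seed * 3L + 2L, waves = 6L)
    cl <- spec$background_clutter
    img <- array(0, c(S, S, 3))
    img[, , 1] <- 55 + 45 * cl * f1
    img[, , 2] <- 95 + 70 * cl * f2
    img[, , 3] <- 45 + 30 * cl * f1 * f2
    boxes <- NULL
    occ_measured <- numeric(0)
    placed <- matrix(0, 0, 4)   # cy, cx, ry, rx of bunch envelopes
    for (b in seq_len(spec$n_bunches)) {
      ok <- FALSE
      for (try in 1:200) {
        w <- stats::runif(1, 0.10, 0.16) * S
        h <- stats::runif(1, 1.25, 1.7) * w
        cx <- stats::runif(1, w / 2 + 2, S - w / 2 - 2)
        cy <- stats::runif(1, h / 2 + 8, S - h / 2 - 2)
        if (nrow(placed)) {
          dy <- abs(placed[, 1] - cy); dx <- abs(placed[, 2] - cx)
          if (any(dy < (placed[, 3] + h / 2) & dx < (placed[, 4] + w / 2))) next
        }
        ok <- TRUE
        break
      }
      if (!ok) stop(sprintf("cannot place %d bunches in a %d px scene",
                            spec$n_bunches, S))
      placed <- rbind(placed, c(cy, cx, h / 2, w / 2))
      env <- ellipse_mask(S, cy, cx, h / 2, w / 2)
      # stem above the bunch
      stem <- ellipse_mask(S, cy - h / 2 - 3, cx, 5, 1.5)
      img <- paint(img, stem, c(90, 70, 40))
      # berries: shaded circles sampled inside the envelope
      bunch_mask <- matrix(FALSE, S, S)
      n_berry <- sample(18:35, 1)
      r <- w / 5.2
      gy <- matrix(seq_len(S), S, S)
      gx <- matrix(seq_len(S), S, S, byrow = TRUE)
      for (k in seq_len(n_berry)) {
        a <- stats::runif(1, 0, 2 * pi)
        rr <- sqrt(stats::runif(1))
        by <- cy + rr * (h / 2 - r) * sin(a)
        bx <- cx + rr * (w / 2 - r) * cos(a)
        m <- ellipse_mask(S, by, bx, r, r)
        # radial highlight toward the upper-left of each berry
        shade <- 0.65 + 0.6 * exp(-(((gy - by + r / 3)^2 + (gx - bx + r / 3)^2) /
                                      (0.5 * r^2)))
        img <- paint(img, m, c(80, 35, 95), shade)
        bunch_mask <- bunch_mask | m
      }
      bunch_mask <- bunch_mask | env
      # ground-truth box covers the full bunch extent (including occlusion)
      ys <- range(which(rowSums(bunch_mask) > 0))
      xs <- range(which(colSums(bunch_mask) > 0))
      boxes <- rbind(boxes, data.frame(
        xmin = xs[1] - 1, ymin = ys[1] - 1, xmax = xs[2], ymax = ys[2],
        class = "grape", stringsAsFactors = FALSE))
      # leaf occluders drawn over the bunch until the target cover is met
      target <- spec$occlusion_fraction
      covered <- matrix(FALSE, S, S)
      if (target > 0) {
        area <- sum(bunch_mask)
        for (it in 1:400) {
          cov <- sum(covered & bunch_mask) / area
          if (cov >= target - 0.02) break
          frac_left <- target - cov
          lr <- sqrt(min(frac_left, 0.15) * area / pi)
          ly <- stats::runif(1, cy - h / 2, cy + h / 2)
          lx <- stats::runif(1, cx - w / 2, cx + w / 2)
          leaf <- ellipse_mask(S, ly, lx, lr * stats::runif(1, 0.8, 1.3),
                               lr * stats::runif(1, 0.8, 1.3),
                               theta = stats::runif(1, 0, pi))
          new_cov <- sum((covered | leaf) & bunch_mask) / area
          if (new_cov > target + 0.02) next
          covered <- covered | leaf
          img <- paint(img, leaf, c(60, 130, 50))
        }
        occ_measured <- c(occ_measured, sum(covered & bunch_mask) / area)
      } else {
        occ_measured <- c(occ_measured, 0)
      }
    }
    # illumination grade
    img <- switch(spec$illumination,
      front = img,
      back = {
        grad <- matrix(seq(60, 0, length.out = S), S, S)
        out <- img * 0.65
        for (c in 1:3) out[, , c] <- out[, , c] + grad
        out
      },
      low = img * 0.45)
    img <- clamp(img, 0, 255)
    ann <- imageAnnotation(sprintf("scene_%04d", spec$seed), S, S,
                           boxes %||% data.frame(xmin = numeric(), ymin = numeric(),
                                                 xmax = numeric(), ymax = numeric(),
                                                 class = character()))
    list(image = img, annotation = ann, occlusion = occ_measured)
  })
}

#' Generate a VOC-layout synthetic dataset
#'
#' Renders \code{n_images} scenes with per-image specs drawn from
#' \code{spec_distribution}, writes PNG images, VOC XML annotations and a
#' train/val split, and returns a manifest of per-image specs.
#'
#' @param n_images number of scenes.
#' @param out_dir output directory (gets JPEGImages/, Annotations/,
#'   ImageSets/Main/).
#' @param seed master seed.
#' @param spec_distribution function(i, seed) returning a
#'   \code{\link{sceneSpec}} for image i; the default varies bunch count 2-5
#'   and occlusion 0-0.4.
#' @param val_fraction fraction of images put in the val split.
#' @return manifest data.frame, also written to \code{manifest.csv}.
#' @export
generateDataset <- function(n_images, out_dir, seed = 0L,
                            spec_distribution = NULL, val_fraction = 0.2) {
  if (n_images < 1) stop("n_images must be at least 1")
  if (is.null(spec_distribution)) {
    spec_distribution <- function(i, s) {
      sceneSpec(image_size = 256L,
                n_bunches = 2L + (i %% 4L),
                occlusion_fraction = 0.4 * ((i %% 3L) / 2),
                seed = s)
    }
  }
  for (d in c("JPEGImages", "Annotations", file.path("ImageSets", "Main"))) {
    dir.create(file.path(out_dir, d), showWarnings = FALSE, recursive = TRUE)
  }
  rows <- list()
  for (i in seq_len(n_images)) {
    sp <- spec_distribution(i, (seed * 1009L + i) %% .Machine$integer.max)
    sc <- generateScene(sp)
    id <- sprintf("synthetic_%04d", i)
    sc$annotation@imageId <- id
    writeImageArray(sc$image, file.path(out_dir, "JPEGImages", paste0(id, ".png")))
    writeVocXml(sc$annotation, file.path(out_dir, "Annotations", paste0(id, ".xml")))
    rows[[i]] <- data.frame(imageId = id, image_size = sp$image_size,
                            n_bunches = sp$n_bunches,
                            occlusion = sp$occlusion_fraction,
                            illumination = sp$illumination,
                            seed = sp$seed,
                            n_boxes = length(sc$annotation),
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  n_val <- max(0L, round(val_fraction * n_images))
  ids <- manifest$imageId
  val <- if (n_val > 0) ids[seq(n_images - n_val + 1L, n_images)] else character()
  writeLines(setdiff(ids, val), file.path(out_dir, "ImageSets", "Main", "train.txt"))
  writeLines(val, file.path(out_dir, "ImageSets", "Main", "val.txt"))
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  manifest
}

#' Recall of planted bunches from a detection set
#'
#' Fraction of ground-truth bunches recovered at the IoU threshold, using
#' the same greedy matching as the evaluation module.
#'
#' @param detections detection data.frame (imageId, class, score, xmin..ymax).
#' @param gts ground truth: list of ImageAnnotation or a VOC directory path.
#' @param iou matching threshold, default 0.5.
#' @return recall in [0, 1].
#' @export
plantedRecoveryCheck <- function(detections, gts, iou = 0.5) {
  if (is.character(gts)) gts <- readVocDataset(gts)
  gtf <- gt_frame(gts)
  if (!nrow(gtf)) stop("no planted boxes in ground truth")
  if (nrow(detections) &&
      !any(detections$imageId %in% gtf$imageId))
    stop("detection image ids do not match the manifest/ground truth")
  m <- matchDetections(detections, gtf, iou_thresh = iou)
  unname(precisionRecallF1(m$tp, m$fp, m$fn)["recall"])
}
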