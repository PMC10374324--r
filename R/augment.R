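# Box-aware dataset-expansion operators: brightness, Gaussian blur, affine,
# mirror, raindrop streaks, and a fog overlay. Photometric operators leave
# annotations untouched; geometric operators map each box through the same
# transform and keep the axis-aligned hull.

#' Photometric transforms: brightness gain or Gaussian blur
#'
#' Brightness multiplies every pixel by \code{strength} and clips to
#' [0, 255]. Blur applies an isotropic Gaussian of sigma \code{strength}
#' (a sigma below 0.1 is treated as the identity). Neither affects boxes.
#'
#' @param image (H, W, 3) array, values 0-255.
#' @param mode "brightness" or "blur".
#' @param strength gain (> 0) for brightness; Gaussian sigma (> 0) for blur.
#' @return transformed image, same shape.
#' @export
photometricTransform <- function(image, mode = c("brightness", "blur"),
                                 strength) {
  mode <- match.arg(mode)
  assert_image(image)
  if (strength <= 0) stop("strength must be positive")
  if (mode == "brightness") {
    clamp(image * strength, 0, 255)
  } else {
    if (strength < 0.1) return(image)
    blurred <- EBImage::gblur(image / 255, sigma = strength, boundary = "replicate")
    clamp(array(blurred, dim(image)) * 255, 0, 255)
  }
}

# forward-map the 4 corners of each box through a 2x3 affine (row, col
# convention: p' = A %*% p + t) and take the clipped axis-aligned hull;
# boxes keeping < min_visible of their area are dropped.
map_boxes_affine <- function(boxes, A, t, width, height, min_visible = 0.25) {
  if (!nrow(boxes)) return(boxes)
  keep <- logical(nrow(boxes))
  out <- boxes
  for (i in seq_len(nrow(boxes))) {
    xs <- c(boxes$xmin[i], boxes$xmax[i], boxes$xmin[i], boxes$xmax[i])
    ys <- c(boxes$ymin[i], boxes$ymin[i], boxes$ymax[i], boxes$ymax[i])
    p <- A %*% rbind(ys, xs) + t          # rows: (y', x')
    xmin <- min(p[2, ]); xmax <- max(p[2, ])
    ymin <- min(p[1, ]); ymax <- max(p[1, ])
    area <- (xmax - xmin) * (ymax - ymin)
    cxmin <- clamp(xmin, 0, width); cxmax <- clamp(xmax, 0, width)
    cymin <- clamp(ymin, 0, height); cymax <- clamp(ymax, 0, height)
    carea <- max(cxmax - cxmin, 0) * max(cymax - cymin, 0)
    if (area > 0 && carea / area >= min_visible && cxmax > cxmin && cymax > cymin) {
      keep[i] <- TRUE
      out$xmin[i] <- cxmin; out$xmax[i] <- cxmax
      out$ymin[i] <- cymin; out$ymax[i] <- cymax
    }
  }
  out[keep, , drop = FALSE]
}

#' Geometric transforms: random affine or horizontal mirror
#'
#' The affine mode draws rotation, isotropic scale and translation from the
#' configured ranges (seeded), warps the image, and maps each box through the
#' same transform, taking the axis-aligned hull of its transformed corners.
#' Boxes with less than \code{min_visible} of their area left in frame are
#' dropped (a transform can legitimately leave zero boxes). Mirror reflects
#' left-right; applying it twice restores the input.
#'
#' @param image (H, W, 3) array.
#' @param ann matching \linkS4class{ImageAnnotation}.
#' @param mode "affine" or "mirror".
#' @param params list for affine: \code{max_rotation} (degrees, default 15),
#'   \code{scale_range} (default c(0.8, 1.2)), \code{max_translate}
#'   (fraction of image size, default 0.1), \code{min_visible} (default
#'   0.25). Ignored for mirror.
#' @param seed RNG seed for the affine draw.
#' @return list(image, annotation).
#' @export
geometricTransform <- function(image, ann, mode = c("affine", "mirror"),
                               params = list(), seed = 0L) {
  mode <- match.arg(mode)
  assert_image(image)
  d <- dim(image)
  H <- d[1]; W <- d[2]
  if (mode == "mirror") {
    out <- image[, rev(seq_len(W)), , drop = FALSE]
    b <- boundingBoxes(ann)
    if (nrow(b)) {
      xmin <- W - b$xmax
      b$xmax <- W - b$xmin
      b$xmin <- xmin
    }
    return(list(image = out,
                annotation = imageAnnotation(imageId(ann), W, H, b)))
  }
  p <- utils::modifyList(list(max_rotation = 15, scale_range = c(0.8, 1.2),
                              max_translate = 0.1, min_visible = 0.25), params)
  draw <- with_local_seed(seed, {
    c(theta = stats::runif(1, -p$max_rotation, p$max_rotation) * pi / 180,
      s = stats::runif(1, p$scale_range[1], p$scale_range[2]),
      ty = stats::runif(1, -p$max_translate, p$max_translate) * H,
      tx = stats::runif(1, -p$max_translate, p$max_translate) * W)
  })
  A <- draw["s"] * rbind(c(cos(draw["theta"]), -sin(draw["theta"])),
                         c(sin(draw["theta"]), cos(draw["theta"])))
  ctr <- c(H / 2, W / 2)
  t <- ctr - A %*% ctr + c(draw["ty"], draw["tx"])
  # EBImage::affine forward-maps coordinates in (dim1, dim2) space
  m <- rbind(t(A), as.numeric(t))
  warped <- EBImage::affine(image / 255, m, output.dim = c(H, W),
                            bg.col = 0)
  warped <- clamp(array(warped, d) * 255, 0, 255)
  b <- map_boxes_affine(boundingBoxes(ann), A, as.numeric(t), W, H,
                        p$min_visible)
  list(image = warped,
       annotation = imageAnnotation(imageId(ann), W, H, b))
}

# smooth spatial field in [0,1] from a seeded mixture of cosine waves
smooth_field <- function(H, W, seed, waves = 3L) {
  with_local_seed(seed, {
    y <- matrix(seq_len(H), H, W)
    x <- matrix(seq_len(W), H, W, byrow = TRUE)
    f <- matrix(0, H, W)
    for (i in seq_len(waves)) {
      th <- stats::runif(1, 0, 2 * pi)
      freq <- stats::runif(1, 0.5, 1.5) / max(H, W)
      ph <- stats::runif(1, 0, 2 * pi)
      f <- f + cos(2 * pi * freq * (cos(th) * y + sin(th) * x) + ph)
    }
    rng <- range(f)
    if (diff(rng) < 1e-12) matrix(1, H, W) else (f - rng[1]) / diff(rng)
  })
}

#' Weather overlays: raindrop streaks or fog
#'
#' Fog blends each pixel toward a bright airlight A = 240 with transmission
#' t = 1 - intensity * g(x, y), where g is a smooth seeded spatial field
#' rescaled into \code{field_range}. Raindrop draws
#' \code{round(200 * intensity)} translucent elongated streaks with alpha
#' blending. Both are deterministic given the seed and leave boxes valid
#' (annotations are not modified by weather).
#'
#' @param image (H, W, 3) array.
#' @param mode "raindrop" or "fog".
#' @param intensity in [0, 1]; 0 is the identity.
#' @param seed RNG seed.
#' @param airlight fog airlight value, default 240.
#' @param field_range range the fog field g is mapped into, default
#'   c(0.5, 1); c(1, 1) gives spatially uniform fog.
#' @return transformed image.
#' @export
weatherOverlay <- function(image, mode = c("raindrop", "fog"), intensity,
                           seed = 0L, airlight = 240, field_range = c(0.5, 1)) {
  mode <- match.arg(mode)
  assert_image(image)
  if (intensity < 0 || intensity > 1) stop("intensity must lie in [0, 1]")
  if (intensity == 0) return(image)
  d <- dim(image)
  H <- d[1]; W <- d[2]
  if (mode == "fog") {
    g <- smooth_field(H, W, seed)
    g <- field_range[1] + g * (field_range[2] - field_range[1])
    tr <- 1 - intensity * g
    out <- image
    for (c in 1:3) out[, , c] <- image[, , c] * tr + airlight * (1 - tr)
    return(clamp(out, 0, 255))
  }
  n <- round(200 * intensity)
  out <- image
  with_local_seed(seed, {
    for (k in seq_len(n)) {
      x0 <- stats::runif(1, 1, W)
      y0 <- stats::runif(1, 1, H)
      len <- stats::runif(1, 10, 30)
      ang <- stats::rnorm(1, 75, 5) * pi / 180   # near-vertical streaks
      alpha <- stats::runif(1, 0.25, 0.55)
      hw <- sample(1:2, 1)                       # streak half-width
      steps <- ceiling(len)
      xs <- round(x0 + cos(ang) * seq(0, len, length.out = steps))
      ys <- round(y0 + sin(ang) * seq(0, len, length.out = steps))
      for (dx in -hw:hw) {
        xi <- xs + dx
        ok <- xi >= 1 & xi <= W & ys >= 1 & ys <= H
        if (!any(ok)) next
        for (c in 1:3) {
          idx <- cbind(ys[ok], xi[ok], c)
          out[idx] <- (1 - alpha) * out[idx] + alpha * 210
        }
      }
    }
  })
  clamp(out, 0, 255)
}

#' Expand a dataset sixfold with the five augmentation operators
#'
#' For every input sample the original is copied and one variant per
#' operator (brightness, blur, affine, mirror, raindrop) is generated, so
#' the output holds exactly six times the input image count. Each variant
#' gets a paired VOC XML annotation; a manifest records operator, parameters
#' and per-sample seed.
#'
#' @param samples list of \code{list(image =, annotation =)} pairs, or a
#'   VOC-layout directory (Annotations/ + JPEGImages/).
#' @param output_dir writable output directory.
#' @param seed master seed; per-sample seeds are derived from it.
#' @param params optional operator parameter overrides: \code{gain_range}
#'   (default c(0.6, 1.4)), \code{sigma_range} (c(1, 3)),
#'   \code{raindrop_intensity} (c(0.3, 0.8)), plus affine params as in
#'   \code{\link{geometricTransform}}.
#' @return manifest data.frame (file, source, op, params, seed), invisibly
#'   also written to \code{manifest.csv}.
#' @export
expandDataset <- function(samples, output_dir, seed = 0L, params = list()) {
  if (is.character(samples)) samples <- load_voc_samples(samples)
  if (!length(samples)) stop("need at least one input sample")
  ok <- dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(output_dir)) stop(sprintf("cannot create output dir '%s'", output_dir))
  p <- utils::modifyList(list(gain_range = c(0.6, 1.4), sigma_range = c(1, 3),
                              raindrop_intensity = c(0.3, 0.8)), params)
  ops <- c("original", "brightness", "blur", "affine", "mirror", "raindrop")
  rows <- list()
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    id <- imageId(s$annotation)
    sseed <- (seed * 7919L + i * 104729L) %% .Machine$integer.max
    draws <- with_local_seed(sseed, list(
      gain = stats::runif(1, p$gain_range[1], p$gain_range[2]),
      sigma = stats::runif(1, p$sigma_range[1], p$sigma_range[2]),
      rain = stats::runif(1, p$raindrop_intensity[1], p$raindrop_intensity[2])))
    for (op in ops) {
      res <- switch(op,
        original = list(image = s$image, annotation = s$annotation),
        brightness = list(image = photometricTransform(s$image, "brightness", draws$gain),
                          annotation = s$annotation),
        blur = list(image = photometricTransform(s$image, "blur", draws$sigma),
                    annotation = s$annotation),
        affine = geometricTransform(s$image, s$annotation, "affine",
                                    params = p, seed = sseed),
        mirror = geometricTransform(s$image, s$annotation, "mirror"),
        raindrop = list(image = weatherOverlay(s$image, "raindrop", draws$rain,
                                               seed = sseed),
                        annotation = s$annotation))
      out_id <- if (op == "original") id else paste0(id, "_", op)
      ann <- res$annotation
      ann@imageId <- out_id
      writeImageArray(res$image, file.path(output_dir, paste0(out_id, ".png")))
      writeVocXml(ann, file.path(output_dir, paste0(out_id, ".xml")))
      prm <- switch(op, brightness = sprintf("gain=%.3f", draws$gain),
                    blur = sprintf("sigma=%.3f", draws$sigma),
                    raindrop = sprintf("intensity=%.3f", draws$rain), "")
      rows[[length(rows) + 1L]] <- data.frame(
        file = paste0(out_id, ".png"), source = id, op = op,
        params = prm, seed = sseed, stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(output_dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}

load_voc_samples <- function(dir) {
  anns <- readVocDataset(dir)
  idir <- if (dir.exists(file.path(dir, "JPEGImages"))) file.path(dir, "JPEGImages") else dir
  lapply(anns, function(a) {
    candidates <- file.path(idir, paste0(imageId(a), c(".png", ".jpg", ".jpeg")))
    f <- candidates[file.exists(candidates)][1]
    if (is.na(f)) stop(sprintf("no image found for annotation '%s'", imageId(a)))
    list(image = readImageArray(f), annotation = a)
  })
}
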