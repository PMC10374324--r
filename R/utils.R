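# Shared internal helpers: seeded RNG scoping and image array I/O.
#
# Images are numeric arrays with dim (H, W, 3) and values in [0, 255]
# throughout the package; EBImage handles file formats.

# Run expr under a local RNG seed, restoring the caller's RNG state after.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

assert_image <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3L)
    stop("image must be an (H, W, C) array")
  invisible(image)
}

#' Read an image file into an (H, W, 3) array
#'
#' @param path image file (PNG or JPEG).
#' @return numeric array, dim (H, W, 3), values in [0, 255].
#' @export
readImageArray <- function(path) {
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3), dim = c(dim(a), 3))
  if (dim(a)[3] > 3) a <- a[, , 1:3, drop = FALSE]
  aperm(a, c(2, 1, 3)) * 255
}

#' Write an (H, W, 3) array to an image file
#'
#' @param image numeric array, dim (H, W, 3), values in [0, 255].
#' @param path output file; format follows the extension (PNG recommended).
#' @export
writeImageArray <- function(image, path) {
  assert_image(image)
  a <- aperm(clamp(image, 0, 255) / 255, c(2, 1, 3))
  EBImage::writeImage(EBImage::Image(a, colormode = "Color"), path)
  invisible(path)
}

# Bilinear resize of an (H, W, C) array via the compiled kernel.
resize_image <- function(image, height, width) {
  assert_image(image)
  d <- dim(image)
  array(cpp_resize_bilinear(image, d[1], d[2], d[3],
                            as.integer(height), as.integer(width)),
        dim = c(height, width, d[3]))
}
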