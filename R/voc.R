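# Pascal VOC XML reading/writing. Coordinates are emitted as integers
# (round half-up); on reading, values are taken verbatim (both 0- and
# 1-based files are accepted without a shift).

round_half_up <- function(x) floor(x + 0.5)

#' Write an annotation as Pascal VOC XML
#'
#' Emits the usual \code{annotation/size/object/name/bndbox} layout.
#' Box coordinates are rounded half-up to integers.
#'
#' @param ann an \linkS4class{ImageAnnotation}.
#' @param path output .xml path.
#' @export
writeVocXml <- function(ann, path) {
  stopifnot(methods::is(ann, "ImageAnnotation"))
  doc <- xml2::xml_new_root("annotation")
  xml2::xml_add_child(doc, "filename", paste0(imageId(ann), ".png"))
  size <- xml2::xml_add_child(doc, "size")
  sz <- imageSize(ann)
  xml2::xml_add_child(size, "width", format(round_half_up(sz["width"])))
  xml2::xml_add_child(size, "height", format(round_half_up(sz["height"])))
  xml2::xml_add_child(size, "depth", "3")
  b <- boundingBoxes(ann)
  for (i in seq_len(nrow(b))) {
    obj <- xml2::xml_add_child(doc, "object")
    xml2::xml_add_child(obj, "name", b$class[i])
    xml2::xml_add_child(obj, "difficult", "0")
    bb <- xml2::xml_add_child(obj, "bndbox")
    xml2::xml_add_child(bb, "xmin", format(round_half_up(b$xmin[i])))
    xml2::xml_add_child(bb, "ymin", format(round_half_up(b$ymin[i])))
    xml2::xml_add_child(bb, "xmax", format(round_half_up(b$xmax[i])))
    xml2::xml_add_child(bb, "ymax", format(round_half_up(b$ymax[i])))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

voc_num <- function(node, xpath) {
  txt <- xml2::xml_text(xml2::xml_find_first(node, xpath))
  v <- suppressWarnings(as.numeric(txt))
  if (is.na(v)) stop(sprintf("non-numeric or missing VOC field '%s'", xpath))
  v
}

#' Read a Pascal VOC XML annotation
#'
#' Requires a \code{size} node with width/height; each \code{object} node
#' contributes one box. Coordinates are validated (xmin < xmax, ymin < ymax)
#' but otherwise preserved verbatim.
#'
#' @param path .xml file.
#' @return An \linkS4class{ImageAnnotation}.
#' @export
readVocXml <- function(path) {
  doc <- xml2::read_xml(path)
  size <- xml2::xml_find_first(doc, ".//size")
  if (inherits(size, "xml_missing")) stop(sprintf("%s: missing <size> node", path))
  width <- voc_num(size, "./width")
  height <- voc_num(size, "./height")
  fname <- xml2::xml_text(xml2::xml_find_first(doc, "./filename"))
  id <- if (is.na(fname) || !nzchar(fname)) {
    sub("\\.[^.]*$", "", basename(path))
  } else sub("\\.[^.]*$", "", basename(fname))
  objs <- xml2::xml_find_all(doc, ".//object")
  boxes <- lapply(objs, function(o) {
    data.frame(
      xmin = voc_num(o, "./bndbox/xmin"), ymin = voc_num(o, "./bndbox/ymin"),
      xmax = voc_num(o, "./bndbox/xmax"), ymax = voc_num(o, "./bndbox/ymax"),
      class = xml2::xml_text(xml2::xml_find_first(o, "./name")),
      stringsAsFactors = FALSE)
  })
  boxes <- if (length(boxes)) do.call(rbind, boxes) else
    data.frame(xmin = numeric(), ymin = numeric(), xmax = numeric(),
               ymax = numeric(), class = character())
  if (nrow(boxes) && any(boxes$xmin >= boxes$xmax | boxes$ymin >= boxes$ymax))
    stop(sprintf("%s: degenerate bndbox (xmin >= xmax or ymin >= ymax)", path))
  imageAnnotation(id, width, height, boxes)
}

#' Read every annotation of a VOC-layout directory
#'
#' @param dir directory containing an \code{Annotations/} folder of .xml
#'   files (or .xml files directly).
#' @return list of \linkS4class{ImageAnnotation} objects, named by image id.
#' @export
readVocDataset <- function(dir) {
  adir <- if (dir.exists(file.path(dir, "Annotations"))) file.path(dir, "Annotations") else dir
  files <- sort(list.files(adir, pattern = "\\.xml$", full.names = TRUE))
  anns <- lapply(files, readVocXml)
  names(anns) <- vapply(anns, imageId, "")
  anns
}
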