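#' @rdname ImageAnnotation-class
#' @param object,x an \linkS4class{ImageAnnotation}.
#' @export
setGeneric("imageId", function(x) standardGeneric("imageId"))

#' @rdname ImageAnnotation-class
#' @export
setMethod("imageId", "ImageAnnotation", function(x) x@imageId)

#' @rdname ImageAnnotation-class
#' @export
setGeneric("imageSize", function(x) standardGeneric("imageSize"))

#' @rdname ImageAnnotation-class
#' @export
setMethod("imageSize", "ImageAnnotation",
          function(x) c(width = x@width, height = x@height))

#' @rdname ImageAnnotation-class
#' @export
setGeneric("boundingBoxes", function(x) standardGeneric("boundingBoxes"))

#' @rdname ImageAnnotation-class
#' @export
setMethod("boundingBoxes", "ImageAnnotation", function(x) x@boxes)

#' @rdname ImageAnnotation-class
#' @export
setMethod("length", "ImageAnnotation", function(x) nrow(x@boxes))

setMethod("show", "ImageAnnotation", function(object) {
  cat(sprintf("ImageAnnotation '%s' (%g x %g px), %d box(es)\n",
              object@imageId, object@width, object@height, nrow(object@boxes)))
  if (nrow(object@boxes)) {
    print(utils::head(object@boxes, 6))
    if (nrow(object@boxes) > 6) cat("...\n")
  }
})

#' @rdname AnchorSet-class
#' @param x an \linkS4class{AnchorSet}.
#' @export
setGeneric("anchors", function(x) standardGeneric("anchors"))

#' @rdname AnchorSet-class
#' @export
setMethod("anchors", "AnchorSet", function(x) x@anchors)

#' @rdname AnchorSet-class
#' @export
setGeneric("clusterAccuracy", function(x) standardGeneric("clusterAccuracy"))

#' @rdname AnchorSet-class
#' @export
setMethod("clusterAccuracy", "AnchorSet", function(x) x@accuracy)

#' @rdname AnchorSet-class
#' @export
setGeneric("scaleGroups", function(x) standardGeneric("scaleGroups"))

#' @rdname AnchorSet-class
#' @export
setMethod("scaleGroups", "AnchorSet", function(x) x@scaleGroups)

setMethod("show", "AnchorSet", function(object) {
  cat(sprintf("AnchorSet with %d anchors", nrow(object@anchors)))
  if (!is.na(object@accuracy))
    cat(sprintf(", mean best IoU %.4f", object@accuracy))
  cat("\n")
  print(round(object@anchors, 2))
})

#' @rdname YoloModel-class
#' @param x,object a \linkS4class{YoloModel}.
#' @export
setGeneric("modelConfig", function(x) standardGeneric("modelConfig"))

#' @rdname YoloModel-class
#' @export
setMethod("modelConfig", "YoloModel", function(x) x@config)

#' Number of learnable parameters in a model
#'
#' Counts every entry of every weight, bias and batch-norm affine parameter.
#' The SimAM attention block contributes nothing: toggling it leaves this
#' count unchanged.
#'
#' @param x a \linkS4class{YoloModel}.
#' @return integer parameter count.
#' @export
setGeneric("parameterCount", function(x) standardGeneric("parameterCount"))

#' @rdname parameterCount
#' @export
setMethod("parameterCount", "YoloModel", function(x) {
  sum(vapply(x@net$params, function(p) length(p$value), 0))
})

setMethod("show", "YoloModel", function(object) {
  cfg <- object@config
  cat(sprintf("YoloModel: input %dx%d, %d class(es), base width %d, SimAM %s\n",
              cfg$input_size, cfg$input_size, cfg$num_classes,
              cfg$base_channels,
              if (all(cfg$attention)) "on"
              else if (any(cfg$attention)) "partial" else "off"))
  cat(sprintf("  stage repeats: %s; parameters: %s\n",
              paste(cfg$stage_repeats, collapse = ","),
              format(parameterCount(object), big.mark = ",")))
})
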