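#' @rdname areaUm2
#' @export
setGeneric("areaUm2", function(x) standardGeneric("areaUm2"))

#' @rdname perimeterUm
#' @export
setGeneric("perimeterUm", function(x) standardGeneric("perimeterUm"))

#' @rdname centroidUm
#' @export
setGeneric("centroidUm", function(x) standardGeneric("centroidUm"))

#' @rdname pixelSize
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname straightness
#' @export
setGeneric("straightness", function(x, ...) standardGeneric("straightness"))

#' @rdname elongationIndex
#' @export
setGeneric("elongationIndex", function(x) standardGeneric("elongationIndex"))

#' @rdname aspectRatio
#' @export
setGeneric("aspectRatio", function(x) standardGeneric("aspectRatio"))

#' @rdname medialAxis
#' @export
setGeneric("medialAxis", function(x, ...) standardGeneric("medialAxis"))

#' @rdname boundaryPosition
#' @export
setGeneric("boundaryPosition", function(x, ...) standardGeneric("boundaryPosition"))

#' @rdname callPoles
#' @export
setGeneric("callPoles", function(x, ...) standardGeneric("callPoles"))
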