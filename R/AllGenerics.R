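#' @include AllClasses.R
NULL

#' Accessors for eyereg classes
#'
#' `pixelData()` returns the intensity matrix of an [EyeImage];
#' `pixelSize()` its calibration in um/pixel. `roiMask()` and `roiArea()`
#' return the boolean mask and its pixel area. `maximaCoords()` returns the
#' `n x 2` coordinate matrix of a [MaximaSet], `gridCells()` the cell-origin
#' matrix of an [EyeGrid], and `modelCoefficients()` the 4x4 coefficient
#' matrix of an [EyeModel].
#'
#' @param x an eyereg object.
#' @name accessors
#' @aliases pixelData pixelSize roiMask roiArea maximaCoords gridCells
#'   modelCoefficients
NULL

#' @rdname accessors
#' @export
setGeneric("pixelData", function(x) standardGeneric("pixelData"))
#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setGeneric("roiMask", function(x) standardGeneric("roiMask"))
#' @rdname accessors
#' @export
setGeneric("roiArea", function(x) standardGeneric("roiArea"))
#' @rdname accessors
#' @export
setGeneric("maximaCoords", function(x) standardGeneric("maximaCoords"))
#' @rdname accessors
#' @export
setGeneric("gridCells", function(x) standardGeneric("gridCells"))
#' @rdname accessors
#' @export
setGeneric("modelCoefficients", function(x) standardGeneric("modelCoefficients"))

#' @rdname accessors
#' @export
setMethod("pixelData", "EyeImage", function(x) x@pixels)
#' @rdname accessors
#' @export
setMethod("pixelSize", "EyeImage", function(x) x@pixelSize)
#' @rdname accessors
#' @export
setMethod("pixelSize", "MaximaSet", function(x) x@pixelSize)
#' @rdname accessors
#' @export
setMethod("roiMask", "EyeROI", function(x) x@mask)
#' @rdname accessors
#' @export
setMethod("roiArea", "EyeROI", function(x) sum(x@mask))
#' @rdname accessors
#' @export
setMethod("maximaCoords", "MaximaSet", function(x) x@points)
#' @rdname accessors
#' @export
setMethod("gridCells", "EyeGrid", function(x) x@origins)
#' @rdname accessors
#' @export
setMethod("modelCoefficients", "EyeModel", function(x) x@coefficients)

#' @describeIn accessors image dimensions as `c(height, width)`.
#' @export
setMethod("dim", "EyeImage", function(x) dim(x@pixels))

#' @describeIn accessors number of detected maxima.
#' @export
setMethod("length", "MaximaSet", function(x) nrow(x@points))
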