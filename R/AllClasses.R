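#' @include RcppExports.R
NULL

#' EyeImage: a calibrated grayscale eye-surface image
#'
#' A 2-D grid of intensities on the 8-bit scale (0--255) together with its
#' pixel calibration in micrometres per pixel. Intensities are carried as
#' floating point so that background subtraction and filtering do not
#' accumulate rounding error; values are only quantized to integers on
#' export. Pixel coordinates are 0-based, `(x = column, y = row)`, origin at
#' the top-left corner, throughout the package.
#'
#' @slot pixels numeric matrix, `height x width` (row = y, column = x),
#'   values in `[0, 255]`.
#' @slot pixelSize micrometres per pixel; the reference calibration of the
#'   built-in statistical model is 1.85 um/pixel.
#' @export
setClass("EyeImage",
  representation(pixels = "matrix", pixelSize = "numeric"),
  prototype(pixelSize = 1.85)
)

setValidity("EyeImage", function(object) {
  p <- object@pixels
  if (!is.numeric(p)) return("pixels must be a numeric matrix")
  if (nrow(p) < 1L || ncol(p) < 1L) return("image has zero size")
  if (anyNA(p)) return("pixels contain NA")
  if (min(p) < 0 || max(p) > 255) return("intensities must lie in [0, 255]")
  if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0) return("pixelSize must be a single positive number")
  TRUE
})

#' EyeROI: a region of interest on an eye image
#'
#' The in-focus area of the eye that is analyzed; stored as a boolean mask
#' with the same dimensions as the image it belongs to, optionally keeping
#' the polygon it was rasterized from. Rasterization uses the even-odd rule
#' sampled at pixel centers `(x + 0.5, y + 0.5)`.
#'
#' @slot mask logical matrix, same orientation as [EyeImage] pixels.
#' @slot polygon numeric matrix with columns `x`, `y` (0-based pixel
#'   coordinates) or a 0-row matrix when the ROI was defined as a mask.
#' @export
setClass("EyeROI",
  representation(mask = "matrix", polygon = "matrix")
)

setValidity("EyeROI", function(object) {
  m <- object@mask
  if (!is.logical(m)) return("mask must be a logical matrix")
  if (anyNA(m)) return("mask contains NA")
  if (!any(m)) return("ROI area must be positive")
  TRUE
})

#' MaximaSet: detected ommatidial reflections
#'
#' Planar point coordinates of prominence-filtered intensity maxima inside a
#' region of interest; the positions approximate the ommatidia of the eye.
#'
#' @slot points numeric matrix with columns `x`, `y` (0-based pixel
#'   coordinates); zero rows for a flat image.
#' @slot tolerance the prominence (noise tolerance) threshold used.
#' @slot pixelSize micrometres per pixel inherited from the source image.
#' @export
setClass("MaximaSet",
  representation(points = "matrix", tolerance = "numeric",
                 pixelSize = "numeric")
)

setValidity("MaximaSet", function(object) {
  p <- object@points
  if (ncol(p) != 2L) return("points must have two columns (x, y)")
  if (nrow(p) > 0L && anyDuplicated(p)) return("points must be distinct")
  if (object@tolerance <= 0) return("tolerance must be positive")
  TRUE
})

#' EyeGrid: the square analysis grid over a region of interest
#'
#' Axis-aligned square cells of side `cellSize` on a regular lattice
#' anchored at the top-left corner of the ROI bounding box; only squares
#' that fit completely inside the ROI mask are kept, so regions near the
#' ROI edge are discarded.
#'
#' @slot cellSize side of each square cell in pixels.
#' @slot origins integer matrix with columns `x0`, `y0`: top-left pixel of
#'   each retained cell (0-based); cell `i` covers
#'   `[x0, x0 + cellSize) x [y0, y0 + cellSize)`.
#' @export
setClass("EyeGrid",
  representation(cellSize = "numeric", origins = "matrix")
)

setValidity("EyeGrid", function(object) {
  if (object@cellSize < 2) return("cellSize must be >= 2")
  if (nrow(object@origins) < 1L) return("grid holds no cells")
  TRUE
})

#' EyeModel: multinomial logistic model for degeneration classes
#'
#' Coefficients of the five-class multinomial logistic model on the three
#' model features DISTM, DISTSKEW and LOGNNVAR, with the fully degenerate
#' class 4 as reference (implied all-zero row). Sixteen free parameters:
#' four classes times (intercept + three slopes).
#'
#' @slot coefficients numeric 4x4 matrix; rows `class0`..`class3`, columns
#'   `independent`, `distm`, `distskew`, `lognnvar`.
#' @slot description free-text provenance of the coefficients.
#' @export
setClass("EyeModel",
  representation(coefficients = "matrix", description = "character")
)

setValidity("EyeModel", function(object) {
  b <- object@coefficients
  if (!is.numeric(b) || any(dim(b) != c(4L, 4L)))
    return("coefficients must be a numeric 4x4 matrix (16 free parameters)")
  if (anyNA(b)) return("coefficients contain NA")
  TRUE
})

#' @export
setMethod("show", "EyeImage", function(object) {
  cat(sprintf("EyeImage: %d x %d px, %.3g um/pixel, intensity [%.1f, %.1f]\n",
              ncol(object@pixels), nrow(object@pixels), object@pixelSize,
              min(object@pixels), max(object@pixels)))
})

#' @export
setMethod("show", "EyeROI", function(object) {
  cat(sprintf("EyeROI: %d px^2 within a %d x %d frame (%s)\n",
              sum(object@mask), ncol(object@mask), nrow(object@mask),
              if (nrow(object@polygon)) sprintf("polygon, %d vertices",
                                                nrow(object@polygon))
              else "mask"))
})

#' @export
setMethod("show", "MaximaSet", function(object) {
  cat(sprintf("MaximaSet: %d maxima (prominence tolerance %.3g)\n",
              nrow(object@points), object@tolerance))
})

#' @export
setMethod("show", "EyeGrid", function(object) {
  cat(sprintf("EyeGrid: %d cells of %g x %g px\n",
              nrow(object@origins), object@cellSize, object@cellSize))
})

#' @export
setMethod("show", "EyeModel", function(object) {
  cat("EyeModel (multinomial logistic, reference class 4):",
      object@description, "\n")
  print(round(object@coefficients, 4))
})
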