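#' Rolling-ball background subtraction
#'
#' Estimates the smooth background of the intensity surface as its grayscale
#' opening by a ball-shaped structuring element of the given radius (the
#' classic rolling-ball construction: the background is the upper envelope
#' of a ball rolled beneath the surface) and subtracts it. Features narrower
#' than the ball are preserved; slowly varying illumination trends are
#' removed. No pre-smoothing is applied. Output is clipped to `[0, 255]`
#' (the opening never exceeds the image, so clipping only guards float
#' noise at 0).
#'
#' @param image an [EyeImage].
#' @param rollingRadius ball radius in pixels (default 50, the conventional
#'   default of the lineage implementation; tuned per image set by
#'   [calibrateDetection()]).
#' @return the background-subtracted [EyeImage] (same dimensions and
#'   calibration).
#' @examples
#' img <- generateEyeImage(syntheticEyeSpec(seed = 1))$image
#' flat <- subtractBackground(img, 25)
#' @export
subtractBackground <- function(image, rollingRadius = 50) {
  stopifnot(methods::is(image, "EyeImage"))
  if (rollingRadius < 1) stop("rollingRadius must be >= 1")
  d <- dim(image@pixels)
  if (rollingRadius > max(d))
    stop("rollingRadius (", rollingRadius, ") exceeds both image dimensions (",
         d[1], " x ", d[2], ")")
  background <- .cpp_ball_open(image@pixels, rollingRadius)
  .as_eye_image(image@pixels - background, image@pixelSize)
}

#' Inverted-shift averaging ("surface-like") filter
#'
#' Contrast normalization for reflection spots: the image is averaged with
#' an intensity-inverted copy of itself displaced horizontally, i.e.
#' `out(x, y) = (img(x, y) + (255 - img(x - displacement, y))) / 2`.
#' A constant image maps to uniform 127.5 for any displacement, so slowly
#' varying intensity offsets between photographs are removed while spot
#' edges survive as local contrast. Columns shifted in from outside the
#' frame are filled by edge replication, so no frame column is undefined
#' (avoiding spurious maxima at the border).
#'
#' @param image an [EyeImage].
#' @param displacement horizontal shift in pixels (non-negative integer;
#'   default 1). Must be smaller than the image width.
#' @return the filtered [EyeImage].
#' @export
surfaceFilter <- function(image, displacement = 1) {
  stopifnot(methods::is(image, "EyeImage"))
  displacement <- as.integer(displacement)
  if (displacement < 0) stop("displacement must be >= 0")
  width <- ncol(image@pixels)
  if (displacement >= width)
    stop("displacement (", displacement, ") must be smaller than the image ",
         "width (", width, ")")
  src_col <- pmax(seq_len(width) - displacement, 1L)  # edge replication
  shifted_inverted <- (255 - image@pixels)[, src_col, drop = FALSE]
  .as_eye_image((image@pixels + shifted_inverted) / 2, image@pixelSize)
}
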