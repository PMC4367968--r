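#' Read an eye-surface image
#'
#' Reads a TIFF (primary format) or PNG photograph and converts it to the
#' 8-bit grayscale representation every later stage works on. RGB images are
#' collapsed with the ITU-R BT.601 luminance weights
#' `0.299 R + 0.587 G + 0.114 B`; 16-bit grayscale is rescaled linearly to
#' the 0--255 range.
#'
#' @param path path to a `.tif`/`.tiff` or `.png` file.
#' @param pixelSize calibration in micrometres per pixel. The built-in
#'   statistical model was developed at 1.85 um/pixel (the default); images
#'   at other calibrations are normalized onto that scale during feature
#'   extraction.
#' @return an [EyeImage].
#' @examples
#' img <- generateEyeImage(syntheticEyeSpec(seed = 1))$image
#' path <- tempfile(fileext = ".tif")
#' writeEyeImage(img, path)
#' identical(pixelData(readEyeImage(path)), pixelData(img))
#' @export
readEyeImage <- function(path, pixelSize = 1.85) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  pixels <- switch(ext,
    tif = , tiff = .tiff_read_raw(path),
    png = {
      arr <- png::readPNG(path) * 255
      if (length(dim(arr)) == 3L) {
        if (dim(arr)[3] >= 3L) {
          0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
        } else {
          arr[, , 1]
        }
      } else {
        arr
      }
    },
    stop("unsupported image format '", ext, "': ", path)
  )
  if (length(pixels) == 0L || nrow(pixels) == 0L || ncol(pixels) == 0L)
    stop("zero-size image: ", path)
  methods::new("EyeImage", pixels = pixels, pixelSize = pixelSize)
}

#' Write an eye-surface image
#'
#' Quantizes the floating-point intensities to 8 bits (rounding to nearest)
#' and writes an uncompressed grayscale TIFF, or a grayscale PNG.
#'
#' @param image an [EyeImage].
#' @param path destination ending in `.tif`, `.tiff` or `.png`.
#' @return `path`, invisibly.
#' @export
writeEyeImage <- function(image, path) {
  stopifnot(methods::is(image, "EyeImage"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = , tiff = .tiff_write_gray8(image@pixels, path),
    png = png::writePNG(pmin(pmax(round(image@pixels), 0), 255) / 255, path),
    stop("unsupported image format '", ext, "'")
  )
  invisible(path)
}

# Construct an EyeImage from a plain matrix (clamping guard for float noise).
.as_eye_image <- function(pixels, pixelSize) {
  methods::new("EyeImage", pixels = pmin(pmax(pixels, 0), 255),
               pixelSize = pixelSize)
}
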