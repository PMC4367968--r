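#' Rasterize a polygon into a region-of-interest mask
#'
#' Uses the even-odd (crossing-number) rule sampled at pixel centers: pixel
#' `(x, y)` (0-based column/row) belongs to the region iff the point
#' `(x + 0.5, y + 0.5)` lies inside the polygon. This makes ROI areas
#' reproducible: a rectangle with vertices `(0,0)-(w,0)-(w,h)-(0,h)` covers
#' exactly `w * h` pixels.
#'
#' @param polygon numeric matrix or two-column data frame of vertices
#'   `(x, y)` in 0-based pixel coordinates, in drawing order (closing edge
#'   implied).
#' @param dim image dimensions `c(height, width)` in pixels.
#' @return logical matrix of the given dimensions.
#' @export
polygonToMask <- function(polygon, dim) {
  polygon <- as.matrix(polygon)
  if (nrow(polygon) < 3L) stop("polygon needs at least 3 vertices")
  height <- dim[1]; width <- dim[2]
  px <- matrix(rep(seq_len(width) - 0.5, each = height), height, width)
  py <- matrix(rep(seq_len(height) - 0.5, times = width), height, width)
  crossings <- matrix(0L, height, width)
  n <- nrow(polygon)
  for (i in seq_len(n)) {
    x1 <- polygon[i, 1]; y1 <- polygon[i, 2]
    j <- if (i == n) 1L else i + 1L
    x2 <- polygon[j, 1]; y2 <- polygon[j, 2]
    if (y1 == y2) next  # horizontal edge: no upward/downward crossing
    straddles <- (y1 > py) != (y2 > py)
    xint <- (x2 - x1) * (py - y1) / (y2 - y1) + x1
    crossings <- crossings + (straddles & (px < xint))
  }
  crossings %% 2L == 1L
}

#' Construct a region of interest
#'
#' From either a polygon (rasterized via [polygonToMask()]) or a ready-made
#' logical mask. Vertices must lie within the image frame
#' `[0, width] x [0, height]`.
#'
#' @param image the [EyeImage] the region belongs to.
#' @param polygon vertex matrix (columns x, y; 0-based pixel coordinates).
#' @param mask logical matrix with the image's dimensions (alternative to
#'   `polygon`).
#' @return an [EyeROI].
#' @export
eyeROI <- function(image, polygon = NULL, mask = NULL) {
  stopifnot(methods::is(image, "EyeImage"))
  d <- dim(image@pixels)
  if (!is.null(polygon)) {
    polygon <- as.matrix(polygon)
    if (nrow(polygon) < 3L)
      stop("polygon needs at least 3 vertices (got ", nrow(polygon), ")")
    if (any(polygon[, 1] < 0) || any(polygon[, 1] > d[2]) ||
        any(polygon[, 2] < 0) || any(polygon[, 2] > d[1]))
      stop("polygon extends outside the image bounds")
    mask <- polygonToMask(polygon, d)
  } else if (!is.null(mask)) {
    if (!identical(dim(mask), d))
      stop("mask dimensions do not match the image")
    polygon <- matrix(numeric(0), 0, 2)
  } else stop("supply either a polygon or a mask")
  colnames(polygon) <- c("x", "y")
  methods::new("EyeROI", mask = mask, polygon = polygon)
}

#' Read a region-of-interest file
#'
#' Native format is a JSON object `{"vertices": [[x, y], ...]}` (0-based
#' pixel coordinates); run-length encoded masks written by [writeROI()] and
#' ImageJ `.roi` polygon records are also accepted. Regions are matched to
#' images by identical base filename, the convention the batch runner
#' enforces.
#'
#' @param path `.json` or ImageJ `.roi` file.
#' @param image the [EyeImage] the region belongs to (bounds validation and
#'   rasterization frame).
#' @return an [EyeROI].
#' @export
readROI <- function(path, image) {
  if (!file.exists(path)) stop("ROI file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "roi") return(eyeROI(image, polygon = .read_imagej_roi(path)))
  obj <- jsonlite::fromJSON(path)
  if (!is.null(obj$vertices)) {
    v <- matrix(unlist(obj$vertices), ncol = 2, byrow = !is.matrix(obj$vertices))
    if (is.matrix(obj$vertices)) v <- obj$vertices
    return(eyeROI(image, polygon = v))
  }
  if (!is.null(obj$mask)) {
    m <- obj$mask
    runs <- matrix(unlist(m$runs), ncol = 2, byrow = !is.matrix(m$runs))
    if (is.matrix(m$runs)) runs <- m$runs
    flat <- logical(m$height * m$width)
    for (i in seq_len(nrow(runs)))
      flat[runs[i, 1]:(runs[i, 1] + runs[i, 2] - 1L)] <- TRUE
    return(eyeROI(image, mask = matrix(flat, m$height, m$width)))
  }
  stop("unrecognized ROI JSON (need 'vertices' or 'mask'): ", path)
}

#' Write a region of interest
#'
#' Polygon-backed regions are written as the native JSON vertex list;
#' mask-only regions as a run-length encoding of the mask (column-major
#' 1-based start/length pairs). Both round-trip exactly through [readROI()].
#'
#' @param roi an [EyeROI].
#' @param path destination `.json` path.
#' @return `path`, invisibly.
#' @export
writeROI <- function(roi, path) {
  stopifnot(methods::is(roi, "EyeROI"))
  if (nrow(roi@polygon) > 0L) {
    obj <- list(vertices = unname(roi@polygon))
  } else {
    flat <- as.logical(roi@mask)
    d <- diff(c(FALSE, flat, FALSE))
    starts <- which(d == 1L); ends <- which(d == -1L)
    obj <- list(mask = list(height = nrow(roi@mask), width = ncol(roi@mask),
                            runs = cbind(starts, ends - starts)))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ImageJ .roi polygon/freehand record: big-endian; "Iout" magic, type at
# byte 6 (0 = polygon, 7 = freehand), bounds as shorts at 8..15, n at 16,
# relative x then y short arrays from byte 64.
.read_imagej_roi <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 64L || rawToChar(raw[1:4]) != "Iout")
    stop("not an ImageJ ROI file: ", path)
  short_at <- function(off, n = 1L)
    readBin(raw[(off + 1L):(off + 2L * n)], "integer", n = n, size = 2L,
            signed = TRUE, endian = "big")
  type <- as.integer(raw[7L])
  if (!type %in% c(0L, 7L))
    stop("only polygon/freehand ImageJ ROIs are supported (type ", type,
         "): ", path)
  top <- short_at(8L); left <- short_at(10L)
  n <- short_at(16L)
  if (n < 3L) stop("ImageJ ROI has fewer than 3 vertices: ", path)
  xs <- short_at(64L, n) + left
  ys <- short_at(64L + 2L * n, n) + top
  cbind(x = xs, y = ys)
}
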