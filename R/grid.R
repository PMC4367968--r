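#' Build the square analysis grid inside a region of interest
#'
#' Lays a regular lattice of axis-aligned squares of side `cellSize` over
#' the ROI, anchored at the top-left corner of the ROI bounding box, and
#' keeps only the squares whose every pixel lies inside the ROI mask --
#' regions near the ROI edge are discarded.
#'
#' @param roi an [EyeROI].
#' @param cellSize cell side in pixels (>= 2). The package default of 50 px
#'   is expressed at the reference calibration of 1.85 um/pixel (about
#'   92.5 um, several ommatidia per cell); see [analyzeEyeImage()] for the
#'   rescaling applied at other calibrations.
#' @return an [EyeGrid].
#' @export
makeGrid <- function(roi, cellSize = 50) {
  stopifnot(methods::is(roi, "EyeROI"))
  cellSize <- as.integer(cellSize)
  if (cellSize < 2L) stop("cellSize must be >= 2")
  mask <- roi@mask
  rows <- which(rowSums(mask) > 0); cols <- which(colSums(mask) > 0)
  y0min <- rows[1] - 1L; y0max <- rows[length(rows)] - 1L
  x0min <- cols[1] - 1L; x0max <- cols[length(cols)] - 1L

  # integral image for O(1) full-containment tests
  s <- rbind(0, apply(mask, 2, cumsum))
  s <- cbind(0, t(apply(s, 1, cumsum)))
  cell_full <- function(x0, y0) {
    r1 <- y0 + 1L; r2 <- y0 + cellSize; c1 <- x0 + 1L; c2 <- x0 + cellSize
    inside <- s[r2 + 1L, c2 + 1L] - s[r1, c2 + 1L] - s[r2 + 1L, c1] + s[r1, c1]
    inside == cellSize * cellSize
  }
  if (x0max - x0min + 1L < cellSize || y0max - y0min + 1L < cellSize)
    stop("no ", cellSize, " px cell fits inside the ROI bounding box")
  xs <- seq(x0min, x0max - cellSize + 1L, by = cellSize)
  ys <- seq(y0min, y0max - cellSize + 1L, by = cellSize)
  origins <- expand.grid(x0 = xs, y0 = ys)
  keep <- mapply(cell_full, origins$x0, origins$y0)
  origins <- as.matrix(origins[keep, , drop = FALSE])
  if (nrow(origins) == 0L)
    stop("no ", cellSize, " px cell fits completely inside the ROI (area ",
         sum(mask), " px^2)")
  rownames(origins) <- NULL
  methods::new("EyeGrid", cellSize = as.numeric(cellSize), origins = origins)
}
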