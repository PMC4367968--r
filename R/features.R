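# The 18 spatial regularity variables: one ROI-global nearest-neighbor
# statistic and seventeen grid-cell statistics of the detected maxima.
#
# Distance normalization: pixel distances are converted to micrometres via
# the image calibration and divided by the reference pitch 1.85 um (the
# calibration the built-in model was developed at), so images acquired at
# any resolution feed the model on the development scale. At the reference
# calibration normalized units coincide with pixels.

.REFERENCE_PITCH_UM <- 1.85

.norm_units <- function(px, pixelSize) px * pixelSize / .REFERENCE_PITCH_UM

# population (biased) standardized moments; variance uses n - 1 throughout
.pop_skew <- function(x) {
  m2 <- mean((x - mean(x))^2)
  if (m2 == 0) return(0)  # a constant sample carries no asymmetry
  mean((x - mean(x))^3) / m2^1.5
}
.pop_kurt <- function(x) {  # non-excess
  m2 <- mean((x - mean(x))^2)
  if (m2 == 0) return(NA_real_)
  mean((x - mean(x))^4) / m2^2
}

#' Nearest-neighbor distances between maxima
#'
#' For every detected maximum, the Euclidean distance to its closest other
#' maximum, in normalized units: micrometres divided by the 1.85 um
#' reference pitch of the model-development images.
#'
#' @param maxima a [MaximaSet] with at least two points.
#' @param pixelSize calibration override (um/pixel); defaults to the
#'   calibration carried by `maxima`.
#' @return numeric vector, one distance per maximum.
#' @export
nearestNeighborDistances <- function(maxima, pixelSize = NULL) {
  stopifnot(methods::is(maxima, "MaximaSet"))
  if (is.null(pixelSize)) pixelSize <- maxima@pixelSize
  p <- maxima@points
  n <- nrow(p)
  if (n < 2L)
    stop("nearest-neighbor distances need at least 2 maxima (got ", n, ")")
  d2 <- as.matrix(stats::dist(p))^2
  diag(d2) <- Inf
  unname(.norm_units(sqrt(apply(d2, 1, min)), pixelSize))
}

#' Per-cell spatial statistics of the maxima
#'
#' For every grid cell: the number of maxima whose pixel falls inside it,
#' the distance from the cell's geometric centroid to the center of mass of
#' its maxima (on the single-pixel maxima image all points carry equal
#' weight, so the brightness-weighted and unweighted centers coincide), and
#' the within-cell skewness and kurtosis of the point-to-centroid distance
#' distribution (population standardized third and fourth moments; defined
#' for >= 3 and >= 4 points respectively, `NA` otherwise or when all
#' distances coincide).
#'
#' @param maxima a [MaximaSet].
#' @param grid an [EyeGrid].
#' @param pixelSize calibration override (um/pixel).
#' @return data frame with one row per cell: `n`, `dist` (normalized
#'   units), `skew`, `kurt`.
#' @export
cellStatistics <- function(maxima, grid, pixelSize = NULL) {
  stopifnot(methods::is(maxima, "MaximaSet"), methods::is(grid, "EyeGrid"))
  if (is.null(pixelSize)) pixelSize <- maxima@pixelSize
  p <- maxima@points
  cs <- grid@cellSize
  out <- data.frame(n = integer(nrow(grid@origins)), dist = NA_real_,
                    skew = NA_real_, kurt = NA_real_)
  for (i in seq_len(nrow(grid@origins))) {
    x0 <- grid@origins[i, 1]; y0 <- grid@origins[i, 2]
    inside <- p[, 1] >= x0 & p[, 1] < x0 + cs &
              p[, 2] >= y0 & p[, 2] < y0 + cs
    pts <- p[inside, , drop = FALSE]
    out$n[i] <- nrow(pts)
    if (nrow(pts) == 0L) next
    centroid <- c(x0 + cs / 2, y0 + cs / 2)
    centers <- pts + 0.5  # pixel centers
    com <- colMeans(centers)
    out$dist[i] <- .norm_units(sqrt(sum((com - centroid)^2)), pixelSize)
    r <- sqrt((centers[, 1] - centroid[1])^2 + (centers[, 2] - centroid[2])^2)
    if (nrow(pts) >= 3L && stats::var(r) > 0) out$skew[i] <- .pop_skew(r)
    if (nrow(pts) >= 4L && stats::var(r) > 0) out$kurt[i] <- .pop_kurt(r)
  }
  out
}

#' Extract the 18 regularity variables of one image
#'
#' Computes the full regularity feature vector from the detected maxima and
#' the analysis grid:
#' \itemize{
#'   \item `PCT_LT2`, `PCT_LT4`, `PCT_LT6`, `PCT_LT8` -- percentage of grid
#'     cells holding fewer than 2/4/6/8 maxima;
#'   \item `MPCM`, `MPCVAR`, `MPCSKEW` -- mean, variance and skewness of
#'     the maxima-per-cell counts, and `TOTMAX` -- total maxima in the ROI;
#'   \item `DISTM`, `DISTVAR`, `DISTSKEW` -- mean, variance and skewness
#'     across occupied cells of the centroid-to-mass-center distance;
#'   \item `KURTM`, `KURTVAR`, `KURTSKEW` and `SKEWM`, `SKEWVAR`,
#'     `SKEWSKEW` -- across-cell mean/variance/skewness of the within-cell
#'     kurtosis and skewness;
#'   \item `LOGNNVAR` -- natural log of the variance of the
#'     nearest-neighbor distances (normalized units).
#' }
#' Empty cells contribute to the occupancy percentages and to the
#' maxima-per-cell statistics (as zero counts) but are excluded from the
#' dist/skew/kurt aggregations. A degenerate nearest-neighbor variance of
#' exactly zero (perfect lattice) is floored at
#' `log(.Machine$double.eps)` and flagged via the `"lognnvarFloored"`
#' attribute. Across-cell variances use denominator `n - 1`; skewness and
#' kurtosis are population standardized moments (kurtosis non-excess).
#'
#' @param maxima a [MaximaSet] (already restricted to the ROI) with at
#'   least two points.
#' @param grid an [EyeGrid] over the same ROI.
#' @param pixelSize calibration override (um/pixel).
#' @return named numeric vector of length 18 with attribute
#'   `lognnvarFloored` (logical).
#' @export
extractFeatures <- function(maxima, grid, pixelSize = NULL) {
  stopifnot(methods::is(maxima, "MaximaSet"), methods::is(grid, "EyeGrid"))
  if (is.null(pixelSize)) pixelSize <- maxima@pixelSize
  if (nrow(maxima@points) < 2L)
    stop("feature extraction needs at least 2 maxima")
  cells <- cellStatistics(maxima, grid, pixelSize)
  n <- cells$n
  agg <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0L) return(c(NA_real_, NA_real_, NA_real_))
    c(mean(x), if (length(x) >= 2L) stats::var(x) else NA_real_, .pop_skew(x))
  }
  nn <- nearestNeighborDistances(maxima, pixelSize)
  nnvar <- stats::var(nn)
  floored <- nnvar == 0
  lognnvar <- if (floored) log(.Machine$double.eps) else log(nnvar)
  d <- agg(cells$dist); k <- agg(cells$kurt); s <- agg(cells$skew)
  fv <- c(
    PCT_LT2 = 100 * mean(n < 2), PCT_LT4 = 100 * mean(n < 4),
    PCT_LT6 = 100 * mean(n < 6), PCT_LT8 = 100 * mean(n < 8),
    MPCM = mean(n), MPCVAR = stats::var(n), MPCSKEW = .pop_skew(n),
    TOTMAX = nrow(maxima@points),
    DISTM = d[1], DISTVAR = d[2], DISTSKEW = d[3],
    KURTM = k[1], KURTVAR = k[2], KURTSKEW = k[3],
    SKEWM = s[1], SKEWVAR = s[2], SKEWSKEW = s[3],
    LOGNNVAR = lognnvar
  )
  names(fv) <- c("PCT_LT2", "PCT_LT4", "PCT_LT6", "PCT_LT8",
                 "MPCM", "MPCVAR", "MPCSKEW", "TOTMAX",
                 "DISTM", "DISTVAR", "DISTSKEW",
                 "KURTM", "KURTVAR", "KURTSKEW",
                 "SKEWM", "SKEWVAR", "SKEWSKEW", "LOGNNVAR")
  attr(fv, "lognnvarFloored") <- floored
  fv
}

#' Project the three model features out of the 18-vector
#'
#' The built-in classifier uses DISTM (mean centroid-to-mass-center
#' distance), DISTSKEW (its across-cell skewness) and LOGNNVAR (log
#' nearest-neighbor distance variance); the projection passes the values
#' through unchanged and propagates the floor flag.
#'
#' @param fv a feature vector from [extractFeatures()].
#' @return named numeric vector `distm`, `distskew`, `lognnvar` with
#'   attribute `lognnvarFloored`.
#' @export
modelFeatures <- function(fv) {
  stopifnot(all(c("DISTM", "DISTSKEW", "LOGNNVAR") %in% names(fv)))
  out <- c(distm = unname(fv["DISTM"]), distskew = unname(fv["DISTSKEW"]),
           lognnvar = unname(fv["LOGNNVAR"]))
  attr(out, "lognnvarFloored") <- isTRUE(attr(fv, "lognnvarFloored"))
  out
}
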