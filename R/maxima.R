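#' Detect ommatidial reflections as prominent intensity maxima
#'
#' Finds local maxima of the intensity surface whose prominence -- the
#' height of the summit above the highest saddle connecting it to any
#' higher summit -- strictly exceeds the noise `tolerance`. This is the
#' noise-tolerance semantics of the classic Find-Maxima plugin lineage.
#' Connectivity is 8-neighbour; an equal-valued summit plateau yields a
#' single point at the plateau centroid rounded to the nearest pixel; the
#' global summit is measured against the image minimum. Only maxima whose
#' pixel lies inside the ROI mask are returned (no edge-exclusion buffer:
#' the grid stage handles ROI edges). A flat image yields an empty set.
#'
#' Prominence is invariant to adding a constant to all intensities, and
#' raising the tolerance can only remove maxima, never add them.
#'
#' @param image an [EyeImage] (normally after [subtractBackground()] and
#'   [surfaceFilter()]).
#' @param roi an [EyeROI]; defaults to the full frame.
#' @param tolerance prominence threshold in intensity units (> 0).
#' @return a [MaximaSet]; the detected count estimates the number of
#'   ommatidia in the region.
#' @examples
#' syn <- generateEyeImage(syntheticEyeSpec(seed = 1))
#' m <- findMaxima(syn$image, tolerance = 30)
#' length(m)
#' @export
findMaxima <- function(image, roi = NULL, tolerance = 10) {
  stopifnot(methods::is(image, "EyeImage"))
  if (tolerance <= 0) stop("tolerance must be positive")
  pts <- .cpp_prominent_maxima(image@pixels, tolerance)
  if (is.null(roi)) {
    keep <- rep(TRUE, nrow(pts))
  } else {
    stopifnot(methods::is(roi, "EyeROI"))
    if (!identical(dim(roi@mask), dim(image@pixels)))
      stop("ROI mask dimensions do not match the image")
    keep <- roi@mask[cbind(pts[, 2] + 1L, pts[, 1] + 1L)]
  }
  pts <- pts[keep, , drop = FALSE]
  pts <- pts[!duplicated(pts), , drop = FALSE]  # rounding can merge plateaus
  methods::new("MaximaSet", points = pts, tolerance = tolerance,
               pixelSize = image@pixelSize)
}

#' Count detected maxima
#'
#' The size of a [MaximaSet]; over a full eye ROI this is the TOTMAX
#' variable, an estimate of the number of ommatidia.
#'
#' @param maxima a [MaximaSet].
#' @return integer count.
#' @export
countMaxima <- function(maxima) {
  stopifnot(methods::is(maxima, "MaximaSet"))
  nrow(maxima@points)
}

#' Calibrate detection parameters against a manual count
#'
#' Searches for a (tolerance, rolling-ball radius) pair whose detected
#' maxima count in a user-delimited region matches the user's manual
#' ommatidia count within a relative band (default +/- 5%). The search is
#' deterministic coordinate descent: for each radius on an 8-rung
#' logarithmic ladder (visited outward from the initial radius), the
#' tolerance coordinate is optimized by binary search on a 25-rung
#' logarithmic ladder, exploiting that the detected count is monotone
#' non-increasing in the tolerance; the first radius whose best count
#' falls inside the band wins. If the band is unreachable within the
#' bounds the best pair found is returned flagged as unconverged.
#'
#' @param image raw [EyeImage] (calibration re-runs preprocessing per
#'   candidate radius).
#' @param region an [EyeROI] delimiting the manually counted area.
#' @param userCount the user's manual count (> 0).
#' @param initial named list with `tolerance` and `rollingRadius` starting
#'   values.
#' @param displacement surface-filter displacement used during search.
#' @param band half-width of the relative acceptance band (0.05 = 5%).
#' @param toleranceRange,radiusRange numeric length-2 search bounds.
#' @return a list with `tolerance`, `rollingRadius`, `achievedCount`,
#'   `targetCount` and logical `converged`.
#' @export
calibrateDetection <- function(image, region, userCount,
                               initial = list(tolerance = 10,
                                              rollingRadius = 50),
                               displacement = 1, band = 0.05,
                               toleranceRange = c(1, 255),
                               radiusRange = c(5, 200)) {
  stopifnot(methods::is(image, "EyeImage"), methods::is(region, "EyeROI"))
  if (userCount <= 0) stop("userCount must be positive")
  radiusRange[2] <- min(radiusRange[2], max(dim(image@pixels)))

  tol_ladder <- exp(seq(log(toleranceRange[1]), log(toleranceRange[2]),
                        length.out = 25))
  rad_ladder <- unique(round(exp(seq(log(radiusRange[1]), log(radiusRange[2]),
                                     length.out = 8))))
  counts <- new.env(parent = emptyenv())
  count_at <- function(tol, rad) {
    key <- paste(signif(tol, 10), rad)
    if (!is.null(counts[[key]])) return(counts[[key]])
    pre <- surfaceFilter(subtractBackground(image, rad), displacement)
    n <- countMaxima(findMaxima(pre, region, tol))
    counts[[key]] <- n
    n
  }
  err <- function(n) abs(n - userCount)
  in_band <- function(n) err(n) <= band * userCount

  # honour an exactly matching initial pair without snapping to the ladder
  n0 <- count_at(initial$tolerance, initial$rollingRadius)
  if (n0 == userCount)
    return(list(tolerance = initial$tolerance,
                rollingRadius = initial$rollingRadius,
                achievedCount = n0, targetCount = userCount,
                converged = TRUE))

  # count is monotone non-increasing in tolerance: binary search the
  # ladder for the rung closest to the target at a fixed radius
  best_tol_at <- function(rad) {
    lo <- 1L; hi <- length(tol_ladder)
    probed <- integer(0)
    while (hi - lo > 1L) {
      mid <- (lo + hi) %/% 2L
      n <- count_at(tol_ladder[mid], rad)
      if (n > userCount) lo <- mid else hi <- mid
    }
    cand <- unique(c(lo, hi))
    ns <- vapply(cand, function(i) count_at(tol_ladder[i], rad), numeric(1))
    pick <- which.min(abs(ns - userCount))
    list(ti = cand[pick], n = ns[pick])
  }

  ri0 <- which.min(abs(log(rad_ladder) - log(initial$rollingRadius)))
  radius_order <- order(abs(seq_along(rad_ladder) - ri0),
                        seq_along(rad_ladder))
  best <- NULL
  for (ri in radius_order) {
    cand <- best_tol_at(rad_ladder[ri])
    if (is.null(best) || err(cand$n) < err(best$n))
      best <- list(ti = cand$ti, ri = ri, n = cand$n)
    if (in_band(best$n)) break
  }
  list(tolerance = tol_ladder[best$ti], rollingRadius = rad_ladder[best$ri],
       achievedCount = best$n, targetCount = userCount,
       converged = in_band(best$n))
}
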