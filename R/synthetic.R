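# Synthetic eye-surface images with ground truth: a hexagonal lattice of
# Gaussian reflection spots on an elliptical "in focus" footprint, with
# tunable positional jitter, spot dropout, spot broadening, a linear
# illumination gradient and pixel noise. Degeneration is emulated as
# jitter + dropout + spot broadening, which reproduces the loss of
# reflection regularity of the rough-eye phenotype without modelling any
# optics.

#' Specification of a synthetic eye image
#'
#' Defaults describe a healthy eye at the reference calibration of
#' 1.85 um/pixel: a 256 x 256 px frame, hexagonal pitch 10 px (= 18.5 um,
#' a realistic ommatidial spacing), sharp spots of sigma 2 px and amplitude
#' 180 on a dim background with a 30-intensity horizontal illumination
#' gradient and pixel noise of sd 4. Degeneration gradients are expressed
#' by raising `jitterSd`, `dropout` and `spotSigma`.
#'
#' @param width,height frame size in pixels.
#' @param latticeSpacing hexagonal pitch in pixels.
#' @param jitterSd isotropic Gaussian positional noise, px.
#' @param dropout independent spot deletion probability in `[0, 1]`.
#' @param spotSigma Gaussian spot width, px.
#' @param spotAmplitude spot peak intensity above background.
#' @param backgroundGradient intensity span of the linear horizontal
#'   illumination trend.
#' @param baseLevel constant background intensity.
#' @param noiseSd additive Gaussian pixel noise sd.
#' @param pixelSize calibration, um/pixel.
#' @param seed RNG seed making the image deterministic.
#' @return a named list of class `"syntheticEyeSpec"`.
#' @export
syntheticEyeSpec <- function(width = 256, height = 256, latticeSpacing = 10,
                             jitterSd = 0, dropout = 0, spotSigma = 2,
                             spotAmplitude = 180, backgroundGradient = 30,
                             baseLevel = 20, noiseSd = 4, pixelSize = 1.85,
                             seed = 1) {
  stopifnot(dropout >= 0, dropout <= 1, latticeSpacing > 0, spotSigma > 0,
            spotAmplitude > 0, noiseSd >= 0, jitterSd >= 0)
  structure(list(width = width, height = height,
                 latticeSpacing = latticeSpacing, jitterSd = jitterSd,
                 dropout = dropout, spotSigma = spotSigma,
                 spotAmplitude = spotAmplitude,
                 backgroundGradient = backgroundGradient,
                 baseLevel = baseLevel, noiseSd = noiseSd,
                 pixelSize = pixelSize, seed = seed),
            class = "syntheticEyeSpec")
}

#' Hexagonal lattice points inside an elliptical footprint
#'
#' Rows are spaced `spacing * sqrt(3) / 2` apart with alternate rows offset
#' by half a pitch; the lattice is centered on the frame center and clipped
#' to the ellipse with semi-axes `0.45 * width` and `0.45 * height`
#' (mimicking the in-focus region of the eye).
#'
#' @param width,height frame size, px.
#' @param spacing hexagonal pitch, px.
#' @return numeric matrix with columns `x`, `y` (0-based pixel coordinates).
#' @export
hexLatticePoints <- function(width, height, spacing) {
  cx <- width / 2; cy <- height / 2
  a <- 0.45 * width; b <- 0.45 * height
  dy <- spacing * sqrt(3) / 2
  rows <- seq(-ceiling(cy / dy), ceiling(cy / dy))
  pts <- do.call(rbind, lapply(rows, function(r) {
    y <- cy + r * dy
    offset <- if (r %% 2 == 0) 0 else spacing / 2
    ks <- seq(-ceiling(cx / spacing) - 1, ceiling(cx / spacing) + 1)
    cbind(x = cx + offset + ks * spacing, y = y)
  }))
  inside <- ((pts[, 1] - cx) / a)^2 + ((pts[, 2] - cy) / b)^2 <= 1
  pts[inside, , drop = FALSE]
}

#' Generate a synthetic eye-surface image with ground truth
#'
#' Lays down the hexagonal lattice inside the elliptical footprint, deletes
#' each spot independently with probability `dropout`, jitters the
#' survivors by `N(0, jitterSd^2)` per axis, renders each as a Gaussian
#' spot and adds the linear background gradient and pixel noise; the result
#' is clipped to `[0, 255]`. Deterministic given `spec$seed` (the caller's
#' RNG state is left untouched).
#'
#' @param spec a [syntheticEyeSpec()].
#' @return list with `image` (an [EyeImage]), `groundTruth` (list:
#'   `points`, the retained jittered centers; `nSpots`), and `roi` (an
#'   [EyeROI] polygon tracing the elliptical footprint, for batch runs).
#' @export
generateEyeImage <- function(spec) {
  stopifnot(inherits(spec, "syntheticEyeSpec"))
  if (spec$latticeSpacing < 2 * spec$spotSigma)
    warning("lattice spacing < 2 * spotSigma: spots merge and detection ",
            "is not guaranteed")
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(spec$seed)

  pts <- hexLatticePoints(spec$width, spec$height, spec$latticeSpacing)
  keep <- stats::runif(nrow(pts)) >= spec$dropout
  pts <- pts[keep, , drop = FALSE]
  if (nrow(pts) > 0L && spec$jitterSd > 0) {
    pts[, 1] <- pts[, 1] + stats::rnorm(nrow(pts), 0, spec$jitterSd)
    pts[, 2] <- pts[, 2] + stats::rnorm(nrow(pts), 0, spec$jitterSd)
    pts[, 1] <- pmin(pmax(pts[, 1], 0), spec$width - 1)
    pts[, 2] <- pmin(pmax(pts[, 2], 0), spec$height - 1)
  }

  img <- matrix(spec$baseLevel, spec$height, spec$width)
  img <- img + matrix(rep(seq(0, spec$backgroundGradient,
                              length.out = spec$width), each = spec$height),
                      spec$height, spec$width)
  half <- ceiling(4 * spec$spotSigma)
  for (i in seq_len(nrow(pts))) {
    x <- pts[i, 1]; y <- pts[i, 2]
    xs <- max(0, floor(x) - half):min(spec$width - 1, floor(x) + half)
    ys <- max(0, floor(y) - half):min(spec$height - 1, floor(y) + half)
    gx <- exp(-((xs - x)^2) / (2 * spec$spotSigma^2))
    gy <- exp(-((ys - y)^2) / (2 * spec$spotSigma^2))
    img[ys + 1, xs + 1] <- img[ys + 1, xs + 1] +
      spec$spotAmplitude * outer(gy, gx)
  }
  if (spec$noiseSd > 0)
    img <- img + matrix(stats::rnorm(length(img), 0, spec$noiseSd),
                        nrow(img), ncol(img))
  image <- .as_eye_image(img, spec$pixelSize)

  theta <- seq(0, 2 * pi, length.out = 65)[-65]
  poly <- cbind(x = spec$width / 2 + 0.98 * 0.45 * spec$width * cos(theta),
                y = spec$height / 2 + 0.98 * 0.45 * spec$height * sin(theta))
  list(image = image,
       groundTruth = list(points = pts, nSpots = nrow(pts)),
       roi = eyeROI(image, polygon = poly))
}

#' Generate a labelled feature table through the full pipeline
#'
#' Renders `nPerClass` images per class specification and runs each through
#' preprocessing, maxima detection, grid construction and feature
#' extraction, yielding a training table for exercising the model-building
#' path end to end. Rows carry the generating class as `group` and `class`
#' and a random 70/30 train/test split.
#'
#' @param nPerClass images per class.
#' @param classSpecs list of [syntheticEyeSpec()]s, ordered regular to
#'   degenerate.
#' @param seed split/derivation seed; image `i` of class `c` uses seed
#'   `seed + 1000 * c + i`.
#' @param tolerance,rollingRadius,displacement,cellSize detection and grid
#'   parameters; the default radius 15 px is matched to the synthetic spot
#'   width (well above 4 * spotSigma) and keeps batch generation fast.
#' @return data frame: `group`, `class`, `split`, the 18 feature columns.
#' @export
generateFeatureTable <- function(nPerClass, classSpecs, seed = 1,
                                 tolerance = 10, rollingRadius = 15,
                                 displacement = 1, cellSize = 50) {
  stopifnot(length(classSpecs) >= 2L)
  rows <- list()
  for (ci in seq_along(classSpecs)) {
    for (i in seq_len(nPerClass)) {
      spec <- classSpecs[[ci]]
      spec$seed <- seed + 1000L * ci + i
      syn <- generateEyeImage(spec)
      res <- analyzeEyeImage(syn$image, syn$roi, tolerance = tolerance,
                             rollingRadius = rollingRadius,
                             displacement = displacement,
                             cellSize = cellSize)
      rows[[length(rows) + 1L]] <-
        c(list(group = ci - 1L, class = ci - 1L), as.list(res$features))
    }
  }
  tab <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed)
  tab$split <- ifelse(stats::runif(nrow(tab)) < 0.7, "train", "test")
  tab
}

#' Simulate model features and class labels from a coefficient table
#'
#' Draws the three model features from a five-group Gaussian mixture laid
#' out along the degeneration gradient -- mirroring a study design of five
#' experimental groups spanning wild type to full degeneration -- and
#' samples class labels from the multinomial probabilities of the given
#' model. Group means (sd in parentheses): DISTM 3, 5.5, 6.8, 7.5, 9.5
#' (1.2); DISTSKEW 1.5, 0.9, 0.5, 0.1, -0.5 (0.8); LOGNNVAR -1.5, 0, 1, 2,
#' 3.5 (1.2). DISTSKEW starts positive for regular eyes (the right-tailed
#' within-cell distance distribution expected of a regular lattice) and
#' falls along the gradient; DISTM and LOGNNVAR rise.
#'
#' @param n number of samples.
#' @param model an [EyeModel] supplying the generating coefficients.
#' @param seed RNG seed.
#' @return data frame: `DISTM`, `DISTSKEW`, `LOGNNVAR`, sampled `class`
#'   (0..4), generating `group` (0..4), and a random 70/30 `split`.
#' @export
simulateModelFeatures <- function(n, model = builtinModel(), seed = 1) {
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed)
  g <- sample.int(5, n, replace = TRUE)
  distm <- c(3, 5.5, 6.8, 7.5, 9.5)[g] + stats::rnorm(n, 0, 1.2)
  distskew <- c(1.5, 0.9, 0.5, 0.1, -0.5)[g] + stats::rnorm(n, 0, 0.8)
  lognnvar <- c(-1.5, 0, 1, 2, 3.5)[g] + stats::rnorm(n, 0, 1.2)
  B <- modelCoefficients(model)
  A <- cbind(cbind(1, distm, distskew, lognnvar) %*% t(B), 0)
  A <- A - apply(A, 1, max)
  P <- exp(A) / rowSums(exp(A))
  cls <- vapply(seq_len(n), function(i) sample.int(5, 1, prob = P[i, ]) - 1L,
                integer(1))
  data.frame(DISTM = distm, DISTSKEW = distskew, LOGNNVAR = lognnvar,
             class = cls, group = g - 1L,
             split = ifelse(stats::runif(n) < 0.7, "train", "test"))
}
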