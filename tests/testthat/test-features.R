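manual_maxima <- function(pts, tolerance = 10, pixelSize = 1.85) {
  methods::new("MaximaSet", points = cbind(x = pts[, 1], y = pts[, 2]),
               tolerance = tolerance, pixelSize = pixelSize)
}

rect_roi <- function(w, h, frame = c(h, w)) {
  img <- as_eye_image(matrix(0, frame[1], frame[2]))
  eyeROI(img, polygon = rbind(c(0, 0), c(w, 0), c(w, h), c(0, h)))
}

test_that("grid construction keeps only fully contained cells", {
  expect_equal(nrow(gridCells(makeGrid(rect_roi(100, 100), 50))), 4L)
  expect_equal(nrow(gridCells(makeGrid(rect_roi(99, 99, c(99, 99)), 50))), 1L)
  expect_error(makeGrid(rect_roi(30, 30, c(40, 40)), 40), "fits")
})

test_that("grid over a disk ROI matches the exhaustive containment oracle", {
  img <- as_eye_image(matrix(0, 150, 150))
  mask <- outer(seq_len(150) - 0.5, seq_len(150) - 0.5,
                function(y, x) (x - 75)^2 + (y - 75)^2 <= 60^2)
  roi <- eyeROI(img, mask = mask)
  grid <- makeGrid(roi, 40)
  # brute force: every lattice square anchored at the mask bounding box
  rows <- range(which(rowSums(mask) > 0)); cols <- range(which(colSums(mask) > 0))
  expected <- 0L
  kept <- NULL
  for (x0 in seq(cols[1] - 1, cols[2] - 40, by = 40))
    for (y0 in seq(rows[1] - 1, rows[2] - 40, by = 40)) {
      sub <- mask[(y0 + 1):(y0 + 40), (x0 + 1):(x0 + 40)]
      if (all(sub)) { expected <- expected + 1L
        kept <- rbind(kept, c(x0, y0)) }
    }
  expect_equal(nrow(gridCells(grid)), expected)
  got <- gridCells(grid)
  expect_equal(unname(got[order(got[, 1], got[, 2]), , drop = FALSE]),
               unname(kept[order(kept[, 1], kept[, 2]), , drop = FALSE]))
})

test_that("nearest-neighbor distances match the all-pairs oracle", {
  # two points 10 px apart at 1.85 um/px: 18.5 um = 10 normalized units
  two <- manual_maxima(rbind(c(0, 0), c(10, 0)))
  expect_equal(nearestNeighborDistances(two), c(10, 10))
  # at a different calibration the physical distance changes accordingly
  expect_equal(nearestNeighborDistances(two, pixelSize = 3.7), c(20, 20))

  # perfect square lattice: every distance equals the spacing
  lat <- as.matrix(expand.grid(x = seq(0, 45, 5), y = seq(0, 45, 5)))
  expect_equal(unique(nearestNeighborDistances(manual_maxima(lat))), 5)

  # random cloud vs brute force
  set.seed(51)
  pts <- cbind(runif(50, 0, 200), runif(50, 0, 200))
  d2 <- as.matrix(dist(pts)); diag(d2) <- Inf
  oracle <- unname(apply(d2, 1, min))
  expect_equal(nearestNeighborDistances(manual_maxima(pts)), oracle)

  expect_error(nearestNeighborDistances(manual_maxima(rbind(c(1, 1)))),
               "at least 2")
})

test_that("per-cell statistics follow the documented moment formulas", {
  grid <- makeGrid(rect_roi(50, 50), 50)
  # a maximum at the cell centroid: the pixel center (24.5+0.5, 24.5+0.5)
  # does not matter -- place the point so its center hits (25, 25)
  one <- cellStatistics(manual_maxima(rbind(c(24.5, 24.5))), grid)
  expect_equal(one$n, 1L)
  expect_equal(one$dist, 0)
  expect_true(is.na(one$skew) && is.na(one$kurt))

  # four symmetric corners: center of mass = centroid
  corners <- manual_maxima(rbind(c(9.5, 9.5), c(39.5, 9.5), c(9.5, 39.5),
                                 c(39.5, 39.5)))
  four <- cellStatistics(corners, grid)
  expect_equal(four$n, 4L)
  expect_equal(four$dist, 0)
  expect_true(is.na(four$kurt))  # all point-to-centroid distances equal

  # five hand-placed points, frozen hand arithmetic
  five <- cellStatistics(manual_maxima(rbind(c(10, 10), c(20, 15), c(30, 30),
                                             c(40, 20), c(25, 40))), grid)
  expect_equal(five$n, 5L)
  expect_equal(five$dist, 1.58113883008, tolerance = 1e-10)
  expect_equal(five$skew, -0.04767587571, tolerance = 1e-9)
  expect_equal(five$kurt, 1.7329176043, tolerance = 1e-9)
})

test_that("the extractor emits the 18 variables with the documented values", {
  roi <- rect_roi(100, 50, c(60, 120))
  grid <- makeGrid(roi, 50)
  expect_equal(nrow(gridCells(grid)), 2L)
  pts <- rbind(c(10, 10), c(20, 15), c(30, 30), c(40, 20), c(25, 40),
               c(60, 10), c(75, 25), c(90, 40))
  fv <- extractFeatures(manual_maxima(pts), grid)
  expect_length(fv, 18L)
  expect_named(fv, c("PCT_LT2", "PCT_LT4", "PCT_LT6", "PCT_LT8",
                     "MPCM", "MPCVAR", "MPCSKEW", "TOTMAX",
                     "DISTM", "DISTVAR", "DISTSKEW",
                     "KURTM", "KURTVAR", "KURTSKEW",
                     "SKEWM", "SKEWVAR", "SKEWSKEW", "LOGNNVAR"))
  # frozen independent arithmetic for the full vector
  expect_equal(unname(fv[c("PCT_LT2", "PCT_LT4", "PCT_LT6", "PCT_LT8")]),
               c(0, 50, 100, 100))
  expect_equal(unname(fv[c("MPCM", "MPCVAR", "MPCSKEW", "TOTMAX")]),
               c(4, 2, 0, 8))
  expect_equal(unname(fv["DISTM"]), 1.14412280564, tolerance = 1e-10)
  expect_equal(unname(fv["DISTVAR"]), 0.38196601125, tolerance = 1e-9)
  expect_equal(unname(fv["DISTSKEW"]), 0, tolerance = 1e-12)
  expect_equal(unname(fv["KURTM"]), 1.7329176043, tolerance = 1e-9)
  expect_true(is.na(fv["KURTVAR"]))  # single defined within-cell kurtosis
  expect_equal(unname(fv["SKEWM"]), -0.371744532327, tolerance = 1e-9)
  expect_equal(unname(fv["SKEWVAR"]), 0.210040988402, tolerance = 1e-9)
  expect_equal(unname(fv["LOGNNVAR"]), 3.21385549237, tolerance = 1e-9)
  expect_false(attr(fv, "lognnvarFloored"))

  mf <- modelFeatures(fv)
  expect_equal(as.numeric(mf),
               unname(fv[c("DISTM", "DISTSKEW", "LOGNNVAR")]))
})

test_that("occupancy percentages are monotone on random configurations", {
  set.seed(61)
  roi <- rect_roi(150, 150)
  grid <- makeGrid(roi, 50)
  for (i in 1:10) {
    pts <- cbind(runif(sample(5:80, 1), 0, 149), runif(1, 0, 149))
    pts <- cbind(runif(nrow(pts), 0, 149), runif(nrow(pts), 0, 149))
    fv <- extractFeatures(manual_maxima(pts), grid)
    pct <- fv[c("PCT_LT2", "PCT_LT4", "PCT_LT6", "PCT_LT8")]
    expect_true(all(diff(pct) >= 0))
    expect_true(all(pct >= 0 & pct <= 100))
  }
})

test_that("a perfect lattice floors LOGNNVAR and zeroes MPCVAR", {
  # 50 px cells tiled exactly by a 10 px square lattice
  roi <- rect_roi(100, 100)
  grid <- makeGrid(roi, 50)
  lat <- as.matrix(expand.grid(x = seq(2, 92, 10), y = seq(2, 92, 10)))
  fv <- extractFeatures(manual_maxima(lat), grid)
  expect_equal(unname(fv["MPCVAR"]), 0)
  expect_true(attr(fv, "lognnvarFloored"))
  expect_equal(unname(fv["LOGNNVAR"]), log(.Machine$double.eps))
  expect_true(attr(modelFeatures(fv), "lognnvarFloored"))
})

test_that("features are invariant under joint integer translation", {
  set.seed(62)
  img <- as_eye_image(matrix(0, 200, 200))
  base_poly <- rbind(c(5, 5), c(115, 5), c(115, 115), c(5, 115))
  pts <- cbind(runif(60, 6, 114), runif(60, 6, 114))
  shift <- c(37, 21)
  roi1 <- eyeROI(img, polygon = base_poly)
  roi2 <- eyeROI(img, polygon = sweep(base_poly, 2, shift, "+"))
  fv1 <- extractFeatures(manual_maxima(pts), makeGrid(roi1, 50))
  fv2 <- extractFeatures(manual_maxima(sweep(pts, 2, shift, "+")),
                         makeGrid(roi2, 50))
  expect_equal(fv1, fv2)
})

test_that("feature statistics respond to lattice jitter as regularity decays", {
  # DISTM and LOGNNVAR grow with jitter; DISTSKEW is positive at low jitter
  set.seed(63)
  roi <- rect_roi(200, 200)
  grid <- makeGrid(roi, 50)
  mean_feats <- sapply(c(0, 2, 6), function(sd_j) {
    rowMeans(sapply(1:20, function(i) {
      lat <- as.matrix(expand.grid(x = seq(4, 194, 10), y = seq(4, 194, 10)))
      jit <- lat + matrix(rnorm(length(lat), 0, sd_j), ncol = 2)
      jit <- pmin(pmax(jit, 0), 199)
      jit <- jit[!duplicated(round(jit, 6)), ]
      fv <- extractFeatures(manual_maxima(jit), grid)
      fv[c("DISTM", "DISTSKEW", "LOGNNVAR")]
    }))
  })
  expect_true(all(diff(mean_feats["DISTM", ]) > 0))
  expect_true(all(diff(mean_feats["LOGNNVAR", ]) > 0))
  expect_gt(mean_feats["DISTSKEW", 2], 0)  # low-jitter right tail
})
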