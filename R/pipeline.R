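#' Analyze one eye image end to end
#'
#' The per-image pipeline: rolling-ball background subtraction,
#' inverted-shift averaging filter, prominence-filtered maxima detection
#' inside the ROI, grid construction, extraction of the 18 regularity
#' variables and conversion through the classifier into the five class
#' probabilities and IREG.
#'
#' The grid cell size is expressed at the reference calibration of
#' 1.85 um/pixel and rescaled by `1.85 / pixelSize(image)` for images at
#' other calibrations, so a cell always covers the same physical area. An
#' image yielding fewer than two maxima, or too few to occupy any grid
#' cell, cannot support the spatial statistics and is assigned complete
#' degeneration (`PP4 = 1`, `IREG = 0`, features `NA`) with
#' `degenerate = TRUE`.
#'
#' @param image an [EyeImage].
#' @param roi an [EyeROI]; defaults to the full frame.
#' @param tolerance prominence threshold for maxima detection.
#' @param rollingRadius rolling-ball radius, px.
#' @param displacement surface-filter shift, px.
#' @param cellSize grid cell size in pixels at the reference calibration
#'   (default 50).
#' @param model an [EyeModel] (built-in classifier by default).
#' @return list: `features` (18-vector), `pp` (`PP0..PP4`), `ireg`,
#'   `nMaxima`, `nCells`, `degenerate`.
#' @export
analyzeEyeImage <- function(image, roi = NULL, tolerance = 10,
                            rollingRadius = 50, displacement = 1,
                            cellSize = 50, model = builtinModel()) {
  stopifnot(methods::is(image, "EyeImage"))
  if (is.null(roi))
    roi <- eyeROI(image, mask = matrix(TRUE, nrow(image@pixels),
                                       ncol(image@pixels)))
  pre <- surfaceFilter(subtractBackground(image, rollingRadius), displacement)
  maxima <- findMaxima(pre, roi, tolerance)
  cell_px <- max(2L, round(cellSize * .REFERENCE_PITCH_UM / image@pixelSize))

  empty <- rep(NA_real_, 18)
  names(empty) <- .FEATURE_ORDER
  degenerate_out <- function(n_max) {
    pp <- c(PP0 = 0, PP1 = 0, PP2 = 0, PP3 = 0, PP4 = 1)
    list(features = empty, pp = pp, ireg = 0, nMaxima = n_max, nCells = 0L,
         degenerate = TRUE)
  }
  if (countMaxima(maxima) < 2L) return(degenerate_out(countMaxima(maxima)))
  grid <- tryCatch(makeGrid(roi, cell_px), error = function(e) NULL)
  if (is.null(grid)) return(degenerate_out(countMaxima(maxima)))
  fv <- extractFeatures(maxima, grid, image@pixelSize)
  mf <- modelFeatures(fv)
  if (anyNA(mf)) return(degenerate_out(countMaxima(maxima)))
  pp <- classProbabilities(mf, model)
  list(features = fv, pp = pp, ireg = iregScore(pp),
       nMaxima = countMaxima(maxima), nCells = nrow(gridCells(grid)),
       degenerate = FALSE)
}

#' Batch analysis of an image folder
#'
#' Mirrors the batch workflow: every image in `imageDir` is paired with the
#' ROI file of the same base name in `roiDir`, analyzed with
#' [analyzeEyeImage()], and the per-image results, per-group summaries,
#' group-comparison statistics, plots and a full configuration echo are
#' written to `outputDir`. Images without a ROI (or unreadable) are listed
#' and skipped, never silently dropped. Deterministic given the
#' configuration.
#'
#' @param config named list (or path to a JSON file holding one) with
#'   `imageDir`, `roiDir`, `outputDir`, and optionally `pixelSize` (1.85),
#'   `tolerance` (10), `rollingRadius` (50), `displacement` (1), `cellSize`
#'   (50), `groups` (named list/vector: image base name -> group label;
#'   default one group `"all"`), `modelFile` (replacement coefficient
#'   JSON) and `adjust` (Dunn adjustment, default `"none"`).
#' @return invisibly, a list with `perImage` (data frame), `perGroup`,
#'   `comparison` (or `NULL`), and `skipped` (data frame of skipped images
#'   with reasons).
#' @export
runBatch <- function(config) {
  if (is.character(config)) config <- jsonlite::fromJSON(config)
  defaults <- list(pixelSize = 1.85, tolerance = 10, rollingRadius = 50,
                   displacement = 1, cellSize = 50, groups = NULL,
                   modelFile = NULL, adjust = "none")
  config <- utils::modifyList(defaults, config)
  for (key in c("imageDir", "roiDir", "outputDir")) {
    if (is.null(config[[key]])) stop("config is missing '", key, "'")
  }
  if (!dir.exists(config$imageDir)) stop("imageDir does not exist: ",
                                         config$imageDir)
  if (!dir.exists(config$roiDir)) stop("roiDir does not exist: ",
                                       config$roiDir)
  dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
  model <- if (!is.null(config$modelFile))
    readModelCoefficients(config$modelFile) else builtinModel()

  images <- sort(list.files(config$imageDir,
                            pattern = "\\.(tif|tiff|png)$",
                            ignore.case = TRUE))
  if (!length(images)) stop("no images found in ", config$imageDir)

  rows <- list(); skipped <- list()
  for (img_name in images) {
    base <- tools::file_path_sans_ext(img_name)
    roi_candidates <- file.path(config$roiDir, paste0(base, c(".json",
                                                              ".roi")))
    roi_path <- roi_candidates[file.exists(roi_candidates)][1]
    if (is.na(roi_path)) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(image = img_name,
                   reason = paste0("missing ROI file '", base,
                                   ".json' / '", base, ".roi'"))
      next
    }
    res <- tryCatch({
      image <- readEyeImage(file.path(config$imageDir, img_name),
                            pixelSize = config$pixelSize)
      roi <- readROI(roi_path, image)
      analyzeEyeImage(image, roi, tolerance = config$tolerance,
                      rollingRadius = config$rollingRadius,
                      displacement = config$displacement,
                      cellSize = config$cellSize, model = model)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(image = img_name, reason = conditionMessage(res))
      next
    }
    group <- if (!is.null(config$groups) && !is.null(config$groups[[base]]))
      as.character(config$groups[[base]]) else "all"
    message(sprintf("analyzed %s: %d maxima, %d cells, IREG %.3f",
                    img_name, res$nMaxima, res$nCells, res$ireg))
    rows[[length(rows) + 1L]] <- data.frame(
      image = img_name, group = group, n_maxima = res$nMaxima,
      n_cells = res$nCells, degenerate = res$degenerate,
      t(res$features), t(res$pp), IREG = res$ireg,
      check.names = FALSE)
  }
  if (!length(rows)) stop("no image could be analyzed")
  per_image <- do.call(rbind, rows)
  skipped <- if (length(skipped)) do.call(rbind, skipped)
             else data.frame(image = character(0), reason = character(0))

  groups <- factor(per_image$group)
  per_group <- data.frame(
    group = levels(groups),
    n = as.integer(table(groups)),
    mean_ireg = as.numeric(tapply(per_image$IREG, groups, mean)),
    median_ireg = as.numeric(tapply(per_image$IREG, groups, median)),
    sd_ireg = as.numeric(tapply(per_image$IREG, groups, stats::sd)))

  comparison <- NULL
  if (nlevels(groups) >= 2L && all(table(groups) >= 2L))
    comparison <- compareGroups(per_image$IREG, groups,
                                adjust = config$adjust)

  out <- function(f) file.path(config$outputDir, f)
  utils::write.csv(per_image, out("per_image.csv"), row.names = FALSE)
  utils::write.csv(per_group, out("per_group.csv"), row.names = FALSE)
  utils::write.csv(skipped, out("skipped.csv"), row.names = FALSE)
  jsonlite::write_json(config[!vapply(config, is.null, logical(1))],
                       out("config_echo.json"), auto_unbox = TRUE,
                       digits = NA)
  if (!is.null(comparison)) {
    utils::write.csv(data.frame(H = comparison$kruskal$H,
                                df = comparison$kruskal$df,
                                p = comparison$kruskal$p),
                     out("kruskal_wallis.csv"), row.names = FALSE)
    utils::write.csv(comparison$pairwise, out("dunn_pairwise.csv"),
                     row.names = FALSE)
  }

  grDevices::png(out("ireg_by_group.png"), width = 700, height = 500)
  graphics::boxplot(IREG ~ group, data = per_image, ylim = c(0, 1),
                    ylab = "IREG", col = "grey90")
  graphics::stripchart(IREG ~ group, data = per_image, vertical = TRUE,
                       add = TRUE, pch = 19, method = "jitter",
                       col = grDevices::adjustcolor("steelblue", 0.7))
  grDevices::dev.off()
  for (g in levels(groups)) {
    grDevices::png(out(sprintf("ireg_hist_%s.png", g)),
                   width = 600, height = 400)
    graphics::hist(per_image$IREG[per_image$group == g],
                   breaks = seq(0, 1, by = 0.05), main = g, xlab = "IREG",
                   col = "grey80")
    grDevices::dev.off()
  }

  invisible(list(perImage = per_image, perGroup = per_group,
                 comparison = comparison, skipped = skipped))
}
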