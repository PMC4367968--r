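# Scoring side of the statistical model: linear predictors, class
# probabilities and the regularity index IREG.

.model_colnames <- c("independent", "distm", "distskew", "lognnvar")

#' Construct an EyeModel from a coefficient matrix
#'
#' @param coefficients numeric 4x4 matrix: rows are degeneration classes
#'   0--3, columns intercept (`independent`) and the slopes on `distm`,
#'   `distskew`, `lognnvar`. Class 4 (fully degenerate) is the reference
#'   with an implied all-zero row.
#' @param description provenance note.
#' @return an [EyeModel].
#' @export
eyeModel <- function(coefficients, description = "user-supplied") {
  coefficients <- as.matrix(coefficients)
  dimnames(coefficients) <- list(paste0("class", 0:3), .model_colnames)
  methods::new("EyeModel", coefficients = coefficients,
               description = description)
}

#' The built-in regularity classifier
#'
#' Loads the packaged coefficient table of the five-class multinomial
#' logistic model on DISTM, DISTSKEW and LOGNNVAR (16 free parameters;
#' class 4 reference), shipped as a versioned JSON asset. Users may load a
#' replacement coefficient file with [readModelCoefficients()], e.g. one
#' produced by [fitMultinomial()] on their own training images.
#'
#' @return an [EyeModel].
#' @examples
#' modelCoefficients(builtinModel())
#' @export
builtinModel <- function() {
  path <- system.file("extdata", "builtin_model.json", package = "eyereg",
                      mustWork = TRUE)
  readModelCoefficients(path)
}

#' Read / write model coefficient files
#'
#' JSON with fields `columns` (the four coefficient names) and
#' `coefficients` (four rows, classes 0--3); the layout of the built-in
#' asset.
#'
#' @param path JSON file path.
#' @return `readModelCoefficients()`: an [EyeModel].
#' @export
readModelCoefficients <- function(path) {
  obj <- jsonlite::fromJSON(path)
  b <- as.matrix(obj$coefficients)
  if (any(dim(b) != c(4L, 4L)))
    stop("coefficient file must hold a 4x4 matrix (16 free parameters): ",
         path)
  eyeModel(b, description = if (!is.null(obj$description)) obj$description
                            else path)
}

#' @rdname readModelCoefficients
#' @param model an [EyeModel].
#' @export
writeModelCoefficients <- function(model, path) {
  stopifnot(methods::is(model, "EyeModel"))
  jsonlite::write_json(
    list(description = model@description, classes = 0:3, reference_class = 4,
         columns = .model_colnames,
         coefficients = unname(model@coefficients)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Linear predictors of the degeneration classes
#'
#' `a_i = independent_i + distm_i * DISTM + distskew_i * DISTSKEW +
#' lognnvar_i * LOGNNVAR` for classes `i = 0..3`; the reference class 4 has
#' `a_4 = 0` implicitly.
#'
#' @param features named vector from [modelFeatures()] (or any numeric
#'   vector `distm`, `distskew`, `lognnvar`).
#' @param model an [EyeModel]; the built-in classifier by default.
#' @return numeric vector `a0..a3`.
#' @export
linearPredictors <- function(features, model = builtinModel()) {
  stopifnot(methods::is(model, "EyeModel"))
  f <- as.numeric(features[c("distm", "distskew", "lognnvar")])
  if (anyNA(f) || any(!is.finite(f)))
    stop("model features must be finite (got ",
         paste(signif(f, 4), collapse = ", "), ")")
  a <- as.numeric(model@coefficients %*% c(1, f))
  names(a) <- paste0("a", 0:3)
  a
}

#' Degeneration-class probabilities
#'
#' The five class membership probabilities of the multinomial logistic
#' model: `PP_i = exp(a_i) / (sum_j exp(a_j) + 1)` for `i = 0..3` and
#' `PP_4 = 1 / (sum_j exp(a_j) + 1)`. Computed with max-subtraction so
#' extreme linear predictors cannot overflow; the five values always sum
#' to one.
#'
#' @inheritParams linearPredictors
#' @return numeric vector `PP0..PP4` on the unit simplex.
#' @examples
#' classProbabilities(c(distm = 1, distskew = 0.5, lognnvar = -1))
#' @export
classProbabilities <- function(features, model = builtinModel()) {
  a <- c(linearPredictors(features, model), 0)  # reference class appended
  e <- exp(a - max(a))
  pp <- e / sum(e)
  names(pp) <- paste0("PP", 0:4)
  pp
}

#' The regularity index IREG
#'
#' Probability-weighted degeneration score
#' `IREG = (4 PP_0 + 3 PP_1 + 2 PP_2 + PP_3) / 4`: 1 for certain wild-type
#' regularity, 0 for certain full degeneration, intermediate values for
#' partial degeneration or rescue. Monotone in the sense that moving
#' probability mass from a more degenerate class to a less degenerate one
#' never lowers the score.
#'
#' @param pp five class probabilities (order `PP0..PP4`; must be a
#'   probability simplex).
#' @return IREG in `[0, 1]`.
#' @examples
#' iregScore(c(1, 0, 0, 0, 0))  # 1: fully regular
#' iregScore(c(0, 0, 0, 0, 1))  # 0: fully degenerate
#' @export
iregScore <- function(pp) {
  pp <- as.numeric(pp)
  if (length(pp) != 5L || any(pp < -1e-9) || abs(sum(pp) - 1) > 1e-6)
    stop("pp must be five probabilities summing to 1")
  sum(c(4, 3, 2, 1, 0) * pp) / 4
}
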