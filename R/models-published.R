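## Reference CARS-MLR calibration equations for loquat quality,
## transcribed from the original study's printed model formulae. The
## same coefficients are shipped a second time as a JSON fixture
## (inst/extdata/reference_mlr_models.json) transcribed independently;
## a unit test asserts the two transcriptions agree.

.REF_MLR <- list(
  colour_e = list(
    intercept = 22.89,
    wavelengths = c(397, 401, 404, 413, 418, 422, 432, 443, 498, 526,
                    541, 553, 621, 623, 641, 717, 750, 972, 974, 993),
    coefficients = c(-8.82, 12.37, -22.02, 28.37, 2.09, 20.83, -11.90,
                     -24.50, 23.75, -17.75, 20.45, -16.34, -0.04, 21.10,
                     -8.06, -15.07, 14.64, 23.98, -0.96, -18.62)),
  firmness = list(
    intercept = 13.36,
    wavelengths = c(394, 399, 406, 408, 411, 413, 415, 555, 616, 619,
                    626, 641, 643, 678, 690, 693, 705, 707, 727, 730,
                    733, 743, 783, 785, 796, 974, 987, 1022, 1024),
    coefficients = c(-11.57, 19.69, -14.56, -21.74, 11.40, 21.95, -1.14,
                     5.08, -72.32, 98.67, -48.77, 8.86, 5.32, -1.30,
                     -31.62, 53.08, 22.26, -61.38, 100.76, -95.06, 48.17,
                     -11.88, -9.22, -23.11, 10.39, -15.85, 1.51, 12.89,
                     7.36)),
  ssc = list(
    intercept = 36.33,
    wavelengths = c(418, 425, 439, 488, 505, 695, 705, 720, 824, 883,
                    885, 888, 914, 919, 940, 961, 990, 1019),
    coefficients = c(-76.42, 84.97, 26.85, -48.79, 30.30, -21.61, 77.22,
                     -67.04, -29.14, -31.90, 222.32, 61.35, -176.46,
                     -122.60, 72.51, 68.45, -134.16, 81.12)))

#' Reference CARS-MLR model for a quality target
#'
#' Returns the fixed linear calibration equation from the original
#' loquat study: intercept, feature wavelengths (nm) and coefficients.
#' The colour e / firmness / SSC models use 20 / 29 / 18 bands.
#'
#' @param target `"colour_e"`, `"firmness"` or `"ssc"`.
#' @return List with `intercept`, `wavelengths`, `coefficients`.
#' @export
referenceModel <- function(target = c("colour_e", "firmness", "ssc")) {
  target <- match.arg(target)
  .REF_MLR[[target]]
}

#' Predict with a reference CARS-MLR model
#'
#' Evaluates the fixed linear form intercept + sum(coef_i * lambda_i)
#' exactly as printed, where lambda_i is the reflectance at the model's
#' i-th feature wavelength.
#'
#' @param target `"colour_e"`, `"firmness"` or `"ssc"`.
#' @param reflectance numeric vector (or matrix, rows = samples) of
#'   reflectances at the model's wavelengths, in model order.
#' @return Predicted value(s) in target units.
#' @export
predictReference <- function(target = c("colour_e", "firmness", "ssc"),
                             reflectance) {
  target <- match.arg(target)
  m <- .REF_MLR[[target]]
  k <- length(m$coefficients)
  if (is.matrix(reflectance)) {
    if (ncol(reflectance) != k)
      stop("reference model '", target, "' needs ", k,
           " reflectances, got ", ncol(reflectance))
    drop(m$intercept + reflectance %*% m$coefficients)
  } else {
    if (length(reflectance) != k)
      stop("reference model '", target, "' needs ", k,
           " reflectances, got ", length(reflectance))
    m$intercept + sum(m$coefficients * reflectance)
  }
}

#' Reference model as a RegressionModel bound to a grid
#'
#' Resolves the reference wavelengths onto a measurement grid (nearest
#' band, erroring if off by more than half the band spacing) and wraps
#' the linear form as a [RegressionModel-class], usable for pixel-wise
#' prediction maps.
#'
#' @param target `"colour_e"`, `"firmness"` or `"ssc"`.
#' @param grid wavelength grid (nm) of the cube/spectra to predict on.
#' @param preprocessing tag the model should expect (default `"raw"`).
#' @return A [RegressionModel-class] of family `"MLR"`.
#' @export
referenceRegressionModel <- function(target = c("colour_e", "firmness",
                                                "ssc"),
                                     grid, preprocessing = "raw") {
  target <- match.arg(target)
  m <- .REF_MLR[[target]]
  idx <- wavelengthToIndex(grid, m$wavelengths)
  ord <- order(idx)
  methods::new("RegressionModel", family = "MLR",
               bandIndices = idx[ord], wavelength = grid[idx[ord]],
               preprocessing = preprocessing,
               parameters = list(intercept = m$intercept,
                                 coefficients = m$coefficients[ord]),
               seed = NA_integer_)
}
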