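## Model evaluation: R2, RMSE, RPD and the performance tier.

.r2 <- function(act, pred) {
  sst <- sum((act - mean(act))^2)
  if (sst <= 0) stop("undefined R-squared: zero variance in measured values")
  1 - sum((act - pred)^2) / sst
}

.rmse <- function(act, pred) sqrt(mean((act - pred)^2))

#' RPD performance tier
#' @param rpd residual predictive deviation.
#' @return `"poor"` (< 1.5), `"moderate"` ([1.5, 2)), `"good"`
#'   ([2, 2.5]) or `"excellent"` (> 2.5).
#' @export
rpdTierOf <- function(rpd) {
  if (rpd < 1.5) "poor"
  else if (rpd < 2) "moderate"
  else if (rpd <= 2.5) "good"
  else "excellent"
}

#' Evaluate a calibration model on both sets
#'
#' Computes the determination coefficients (1 - SSE/SST about each
#' set's own measured mean), the root mean square errors, and
#' RPD = SD / RMSEP with SD the (n-1) standard deviation of the
#' measured prediction-set values.
#'
#' @param yActCal,yCalHat measured and predicted calibration values.
#' @param yActPred,yPredHat measured and predicted prediction-set
#'   values.
#' @return An [EvaluationReport-class].
#' @export
evaluateRegression <- function(yActCal, yCalHat, yActPred, yPredHat) {
  stopifnot(length(yActCal) == length(yCalHat),
            length(yActPred) == length(yPredHat),
            length(yActCal) >= 2L, length(yActPred) >= 2L)
  if (stats::sd(yActPred) <= 0)
    stop("prediction-set measured values have zero variance")
  rmsep <- .rmse(yActPred, yPredHat)
  if (rmsep == 0)
    stop("RPD undefined: perfect predictions give RMSEP = 0")
  sdP <- stats::sd(yActPred)
  rpd <- sdP / rmsep
  methods::new("EvaluationReport",
               r2C = .r2(yActCal, yCalHat), rmsec = .rmse(yActCal, yCalHat),
               r2P = .r2(yActPred, yPredHat), rmsep = rmsep, rpd = rpd,
               nC = length(yActCal), nP = length(yActPred), sdPred = sdP,
               tier = rpdTierOf(rpd))
}

#' Write an evaluation report as a CSV row
#'
#' Column order follows the conventional performance tables:
#' R2_C, RMSEC, R2_P, RMSEP, RPD (plus n_c, n_p, tier).
#'
#' @param report an [EvaluationReport-class].
#' @param path CSV path.
#' @param label optional row label (e.g. "CARS-MLR colour_e").
#' @export
writeEvaluationCSV <- function(report, path, label = "") {
  utils::write.csv(data.frame(
    model = label, R2_C = report@r2C, RMSEC = report@rmsec,
    R2_P = report@r2P, RMSEP = report@rmsep, RPD = report@rpd,
    n_c = report@nC, n_p = report@nP, tier = report@tier), path,
    row.names = FALSE)
  invisible(path)
}
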