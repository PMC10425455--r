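#' Wavelength grid accessor
#'
#' Returns the wavelength grid (nm) attached to a spectral object.
#'
#' @param x a [SpectrumMatrix-class], [SpectralCube-class] or
#'   [SelectionResult-class] object.
#' @return Numeric vector of wavelengths in nm.
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' Sample identifier accessor
#' @param x a [SpectrumMatrix-class] object.
#' @return Character vector of sample ids.
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' Preprocessing tag accessor
#' @param x a [SpectrumMatrix-class] or [RegressionModel-class] object.
#' @return `"raw"` or `"snv"`.
#' @export
setGeneric("preprocessingTag", function(x) standardGeneric("preprocessingTag"))

#' Selected band indices accessor
#' @param x a [SelectionResult-class] or [RegressionModel-class] object.
#' @return Integer vector of 1-based band indices.
#' @export
setGeneric("bandIndices", function(x) standardGeneric("bandIndices"))

#' Number of fruit pixels in a mask
#' @param x a [FruitMask-class] object.
#' @return Integer count of TRUE pixels.
#' @export
setGeneric("pixelCount", function(x) standardGeneric("pixelCount"))

#' RPD performance tier accessor
#' @param x an [EvaluationReport-class] object.
#' @return One of `"poor"`, `"moderate"`, `"good"`, `"excellent"`.
#' @export
setGeneric("rpdTier", function(x) standardGeneric("rpdTier"))
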