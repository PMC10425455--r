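## Central S4 containers for the hyperspectral quality pipeline.

#' @include AllGenerics.R
NULL

#' SpectrumMatrix: n samples x p bands of reflectance
#'
#' The central currency of the pipeline: a numeric matrix of reflectance
#' spectra (rows = samples, columns = bands) bound to a shared wavelength
#' grid in nm and a preprocessing tag. Row names carry the sample ids.
#'
#' @slot values numeric matrix, n x p; rownames are sample ids.
#' @slot wavelength numeric, length p, strictly increasing, nm.
#' @slot preprocessing `"raw"` or `"snv"`.
#' @exportClass SpectrumMatrix
setClass("SpectrumMatrix",
  representation(values = "matrix", wavelength = "numeric",
                 preprocessing = "character"),
  validity = function(object) {
    v <- object@values
    if (!is.numeric(v) || nrow(v) < 1L)
      return("values must be a numeric matrix with at least one row")
    if (ncol(v) != length(object@wavelength))
      return("column count must equal wavelength grid length")
    if (length(object@wavelength) >= 2 && any(diff(object@wavelength) <= 0))
      return("wavelength grid must be strictly increasing")
    if (any(object@wavelength < 300) || any(object@wavelength > 1200))
      return("wavelengths outside [300, 1200] nm sanity bounds")
    if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
      return("sample ids (rownames) must be present and unique")
    if (!object@preprocessing %in% c("raw", "snv"))
      return("preprocessing must be 'raw' or 'snv'")
    TRUE
  })

#' Construct a SpectrumMatrix
#'
#' @param values numeric matrix (n samples x p bands) of reflectance.
#' @param wavelength numeric vector of band-centre wavelengths (nm).
#' @param sampleIds optional character vector of unique ids; defaults to
#'   existing rownames or `s1..sn`.
#' @param preprocessing `"raw"` (default) or `"snv"`.
#' @return A [SpectrumMatrix-class] object.
#' @export
SpectrumMatrix <- function(values, wavelength, sampleIds = NULL,
                           preprocessing = "raw") {
  values <- as.matrix(values)
  if (!is.null(sampleIds)) rownames(values) <- as.character(sampleIds)
  if (is.null(rownames(values)))
    rownames(values) <- paste0("s", seq_len(nrow(values)))
  methods::new("SpectrumMatrix", values = values,
               wavelength = as.numeric(wavelength),
               preprocessing = preprocessing)
}

#' SpectralCube: a rows x cols x bands hyperspectral image
#'
#' Holds raw counts or reflectance with its wavelength grid and a kind tag
#' distinguishing the roles in black/white correction: the original image,
#' the white and dark references, and the corrected reflectance.
#'
#' @slot values numeric array, rows x cols x bands.
#' @slot wavelength numeric, length = band count, strictly increasing, nm.
#' @slot kind one of `"raw"`, `"white_ref"`, `"dark_ref"`, `"reflectance"`.
#' @exportClass SpectralCube
setClass("SpectralCube",
  representation(values = "array", wavelength = "numeric", kind = "character"),
  validity = function(object) {
    d <- dim(object@values)
    if (length(d) != 3L) return("values must be a 3-d array")
    if (d[3] != length(object@wavelength))
      return("band count must equal wavelength grid length")
    if (length(object@wavelength) >= 2 && any(diff(object@wavelength) <= 0))
      return("wavelength grid must be strictly increasing")
    if (!object@kind %in% c("raw", "white_ref", "dark_ref", "reflectance"))
      return("invalid kind")
    if (object@kind == "reflectance" && any(object@values < 0))
      return("reflectance cube must be non-negative")
    TRUE
  })

#' Construct a SpectralCube
#' @param values rows x cols x bands numeric array.
#' @param wavelength numeric vector of wavelengths (nm).
#' @param kind `"raw"`, `"white_ref"`, `"dark_ref"` or `"reflectance"`.
#' @return A [SpectralCube-class] object.
#' @export
SpectralCube <- function(values, wavelength, kind = "raw") {
  methods::new("SpectralCube", values = values,
               wavelength = as.numeric(wavelength), kind = kind)
}

#' FruitMask: a boolean fruit/background segmentation
#'
#' @slot mask logical matrix (rows x cols); TRUE marks fruit pixels.
#' @exportClass FruitMask
setClass("FruitMask",
  representation(mask = "matrix"),
  validity = function(object) {
    if (!is.logical(object@mask)) return("mask must be logical")
    if (sum(object@mask) < 1L) return("mask must contain at least one pixel")
    TRUE
  })

#' Construct a FruitMask
#' @param mask logical matrix marking fruit pixels.
#' @return A [FruitMask-class] object.
#' @export
FruitMask <- function(mask) methods::new("FruitMask", mask = mask)

#' SelectionResult: the outcome of a wavelength-selection run
#'
#' @slot method `"CARS"`, `"GA"` or `"SPA"`.
#' @slot indices integer, 1-based indices into the wavelength grid,
#'   unique and sorted.
#' @slot wavelength numeric, full grid the indices refer to (nm).
#' @slot rmsecvTrace numeric, per-iteration cross-validated RMSE.
#' @slot winningIteration integer, index into the trace achieving its
#'   minimum.
#' @slot nRetained integer, per-iteration retained-band counts (CARS
#'   only; empty otherwise).
#' @slot seed integer seed used (NA for deterministic SPA).
#' @exportClass SelectionResult
setClass("SelectionResult",
  representation(method = "character", indices = "integer",
                 wavelength = "numeric", rmsecvTrace = "numeric",
                 winningIteration = "integer", nRetained = "integer",
                 seed = "integer"),
  validity = function(object) {
    if (!object@method %in% c("CARS", "GA", "SPA")) return("invalid method")
    i <- object@indices
    if (anyDuplicated(i) || is.unsorted(i)) return("indices must be unique and sorted")
    if (any(i < 1L) || any(i > length(object@wavelength)))
      return("indices out of grid range")
    w <- object@winningIteration
    tr <- object@rmsecvTrace
    if (length(tr) && (w < 1L || w > length(tr)))
      return("winningIteration outside trace")
    if (length(tr) && is.finite(tr[w]) &&
        tr[w] > min(tr, na.rm = TRUE) + 1e-12)
      return("winningIteration must achieve the trace minimum")
    TRUE
  })

#' RegressionModel: a fitted quality-calibration model
#'
#' A fitted predictor bound to a band subset and a preprocessing recipe.
#' The `parameters` list is family-specific: regression coefficients and
#' intercept for the linear families (PLSR/PCR/MLR, after reduction to a
#' single linear form), hidden and output weights plus input scaling for
#' ELM and BP.
#'
#' @slot family `"PLSR"`, `"PCR"`, `"MLR"`, `"ELM"` or `"BP"`.
#' @slot bandIndices integer, 1-based indices of the bands the model uses.
#' @slot wavelength numeric, wavelengths (nm) of those bands.
#' @slot preprocessing preprocessing tag the model expects (`"raw"`/`"snv"`).
#' @slot parameters list of family-specific fitted parameters.
#' @slot seed integer seed (NA for deterministic families).
#' @exportClass RegressionModel
setClass("RegressionModel",
  representation(family = "character", bandIndices = "integer",
                 wavelength = "numeric", preprocessing = "character",
                 parameters = "list", seed = "integer"),
  validity = function(object) {
    if (!object@family %in% c("PLSR", "PCR", "MLR", "ELM", "BP"))
      return("invalid family")
    if (length(object@bandIndices) != length(object@wavelength))
      return("bandIndices and wavelength lengths differ")
    TRUE
  })

#' ClassifierModel: a fitted maturity-stage discriminator
#'
#' @slot family `"PLSDA"`, `"SKNN"` or `"SVM"`.
#' @slot parameters family-specific fitted parameters.
#' @slot classes ordered stage labels, `c("I","II","III")` in full use.
#' @slot seed integer seed (NA where deterministic).
#' @exportClass ClassifierModel
setClass("ClassifierModel",
  representation(family = "character", parameters = "list",
                 classes = "character", seed = "integer"),
  validity = function(object) {
    if (!object@family %in% c("PLSDA", "SKNN", "SVM"))
      return("invalid family")
    if (length(object@classes) < 2L) return("need at least two classes")
    TRUE
  })

#' EvaluationReport: calibration/prediction performance of a model
#'
#' Determination coefficients and root mean square errors for the
#' calibration and prediction sets, plus the residual predictive
#' deviation RPD = SD / RMSEP, where SD is the (n-1) standard deviation
#' of the measured prediction-set values. Tier thresholds: RPD < 1.5
#' poor, 1.5-2 moderate, 2-2.5 good, > 2.5 excellent.
#'
#' @slot r2C,rmsec calibration-set R-squared and RMSE.
#' @slot r2P,rmsep prediction-set R-squared and RMSE.
#' @slot rpd residual predictive deviation.
#' @slot nC,nP set sizes.
#' @slot sdPred SD of measured prediction-set values.
#' @slot tier `"poor"`, `"moderate"`, `"good"` or `"excellent"`.
#' @exportClass EvaluationReport
setClass("EvaluationReport",
  representation(r2C = "numeric", rmsec = "numeric", r2P = "numeric",
                 rmsep = "numeric", rpd = "numeric", nC = "integer",
                 nP = "integer", sdPred = "numeric", tier = "character"),
  validity = function(object) {
    if (object@r2C > 1 + 1e-12 || object@r2P > 1 + 1e-12)
      return("R-squared cannot exceed 1")
    if (object@rmsec < 0 || object@rmsep < 0) return("RMSE must be >= 0")
    if (abs(object@rpd - object@sdPred / object@rmsep) > 1e-8 * max(1, object@rpd))
      return("rpd must equal sdPred / rmsep")
    TRUE
  })

#' PredictionMap: per-pixel predicted quality over a fruit mask
#'
#' @slot values numeric matrix of predictions (target units); NA outside
#'   the mask.
#' @slot mask the [FruitMask-class] the map is defined on.
#' @slot target `"colour_e"`, `"firmness"` or `"ssc"`.
#' @slot colourScale numeric length-2 (min, max) used for rendering.
#' @slot compression deviation-compression factor c in [0, 1] applied
#'   before pixel-wise prediction.
#' @exportClass PredictionMap
setClass("PredictionMap",
  representation(values = "matrix", mask = "FruitMask", target = "character",
                 colourScale = "numeric", compression = "numeric"),
  validity = function(object) {
    if (!all(dim(object@values) == dim(object@mask@mask)))
      return("values and mask dimensions differ")
    if (any(!is.finite(object@values[object@mask@mask])))
      return("map must be finite inside the mask")
    if (!object@target %in% c("colour_e", "firmness", "ssc"))
      return("invalid target")
    cs <- object@colourScale
    if (length(cs) != 2L || !(cs[1] < cs[2]))
      return("colourScale must be (min, max) with min < max")
    TRUE
  })

## ---- accessors ----

#' @rdname wavelengths
#' @export
setMethod("wavelengths", "SpectrumMatrix", function(x) x@wavelength)
#' @rdname wavelengths
#' @export
setMethod("wavelengths", "SpectralCube", function(x) x@wavelength)
#' @rdname wavelengths
#' @export
setMethod("wavelengths", "SelectionResult",
          function(x) x@wavelength[x@indices])

#' @rdname sampleIds
#' @export
setMethod("sampleIds", "SpectrumMatrix", function(x) rownames(x@values))

#' @rdname preprocessingTag
#' @export
setMethod("preprocessingTag", "SpectrumMatrix", function(x) x@preprocessing)
#' @rdname preprocessingTag
#' @export
setMethod("preprocessingTag", "RegressionModel", function(x) x@preprocessing)

#' @rdname bandIndices
#' @export
setMethod("bandIndices", "SelectionResult", function(x) x@indices)
#' @rdname bandIndices
#' @export
setMethod("bandIndices", "RegressionModel", function(x) x@bandIndices)

#' @rdname pixelCount
#' @export
setMethod("pixelCount", "FruitMask", function(x) sum(x@mask))

#' @rdname rpdTier
#' @export
setMethod("rpdTier", "EvaluationReport", function(x) x@tier)

#' Extract the spectra matrix
#' @param x a [SpectrumMatrix-class].
#' @return The underlying numeric matrix (samples x bands).
#' @export
spectraValues <- function(x) x@values

## ---- show methods ----

setMethod("show", "SpectrumMatrix", function(object) {
  cat(sprintf("SpectrumMatrix: %d spectra x %d bands (%.0f-%.0f nm), %s\n",
              nrow(object@values), ncol(object@values),
              min(object@wavelength), max(object@wavelength),
              object@preprocessing))
})

setMethod("show", "SpectralCube", function(object) {
  d <- dim(object@values)
  cat(sprintf("SpectralCube [%s]: %d x %d pixels x %d bands (%.0f-%.0f nm)\n",
              object@kind, d[1], d[2], d[3],
              min(object@wavelength), max(object@wavelength)))
})

setMethod("show", "FruitMask", function(object) {
  d <- dim(object@mask)
  cat(sprintf("FruitMask: %d x %d, %d fruit pixels\n",
              d[1], d[2], sum(object@mask)))
})

setMethod("show", "SelectionResult", function(object) {
  cat(sprintf("SelectionResult [%s]: %d bands selected (iteration %d, RMSECV %.4g)\n",
              object@method, length(object@indices), object@winningIteration,
              object@rmsecvTrace[object@winningIteration]))
  cat("  wavelengths (nm):",
      paste(round(object@wavelength[object@indices]), collapse = ", "), "\n")
})

setMethod("show", "RegressionModel", function(object) {
  cat(sprintf("RegressionModel [%s]: %d bands, preprocessing '%s'\n",
              object@family, length(object@bandIndices),
              object@preprocessing))
})

setMethod("show", "ClassifierModel", function(object) {
  cat(sprintf("ClassifierModel [%s]: classes %s\n", object@family,
              paste(object@classes, collapse = " < ")))
})

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf(
    "EvaluationReport: R2C %.3f RMSEC %.3f | R2P %.3f RMSEP %.3f | RPD %.2f (%s)\n",
    object@r2C, object@rmsec, object@r2P, object@rmsep, object@rpd,
    object@tier))
})

setMethod("show", "PredictionMap", function(object) {
  cat(sprintf("PredictionMap [%s]: %d x %d, %d fruit pixels, scale [%.3g, %.3g], c = %.2f\n",
              object@target, nrow(object@values), ncol(object@values),
              pixelCount(object@mask), object@colourScale[1],
              object@colourScale[2], object@compression))
})
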