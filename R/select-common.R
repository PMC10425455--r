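## Shared infrastructure for the wavelength-selection algorithms.

#' CARS configuration
#'
#' Defaults follow the study settings: 50 Monte-Carlo sampling runs and
#' 5 cross-validation folds.
#'
#' @param nRuns Monte-Carlo sampling runs (>= 2).
#' @param cvFolds cross-validation folds.
#' @param mcSampleFraction fraction of calibration samples drawn per run.
#' @param maxComp latent-variable cap for the inner PLS models.
#' @param seed integer RNG seed.
#' @return A list of class `CarsConfig`.
#' @export
carsConfig <- function(nRuns = 50L, cvFolds = 5L, mcSampleFraction = 0.8,
                       maxComp = 10L, seed = 1L) {
  stopifnot(nRuns >= 2L, cvFolds >= 2L,
            mcSampleFraction > 0, mcSampleFraction <= 1)
  structure(list(nRuns = as.integer(nRuns), cvFolds = as.integer(cvFolds),
                 mcSampleFraction = mcSampleFraction,
                 maxComp = as.integer(maxComp), seed = as.integer(seed)),
            class = "CarsConfig")
}

#' Genetic-algorithm configuration
#'
#' Defaults follow the study settings: population 30, crossover
#' probability 0.5, mutation probability 0.01, 100 generations.
#'
#' @param population even population size >= 4.
#' @param crossoverP,mutationP operator probabilities in [0, 1].
#' @param generations number of generations.
#' @param cvFolds folds of the RMSECV fitness.
#' @param initP inclusion probability per band in the initial population.
#' @param maxComp latent-variable cap for the inner PLS models.
#' @param seed integer RNG seed.
#' @return A list of class `GaConfig`.
#' @export
gaConfig <- function(population = 30L, crossoverP = 0.5, mutationP = 0.01,
                     generations = 100L, cvFolds = 5L, initP = 0.1,
                     maxComp = 10L, seed = 1L) {
  stopifnot(population >= 4L, population %% 2L == 0L,
            crossoverP >= 0, crossoverP <= 1, mutationP >= 0, mutationP <= 1,
            generations >= 1L)
  structure(list(population = as.integer(population),
                 crossoverP = crossoverP, mutationP = mutationP,
                 generations = as.integer(generations),
                 cvFolds = as.integer(cvFolds), initP = initP,
                 maxComp = as.integer(maxComp), seed = as.integer(seed)),
            class = "GaConfig")
}

#' Successive-projections-algorithm configuration
#'
#' @param minVars,maxVars chain-length bounds (1 <= min <= max <= p).
#' @param validationFraction fraction held out (by an internal SPXY
#'   split) for the RMSE used to pick the chain.
#' @return A list of class `SpaConfig`.
#' @export
spaConfig <- function(minVars = 1L, maxVars = 30L,
                      validationFraction = 0.25) {
  stopifnot(minVars >= 1L, minVars <= maxVars,
            validationFraction > 0, validationFraction < 1)
  structure(list(minVars = as.integer(minVars),
                 maxVars = as.integer(maxVars),
                 validationFraction = validationFraction),
            class = "SpaConfig")
}

## canonical sample ordering so seeded selection is invariant to
## permutations of the input rows
.canonicalOrder <- function(X, y) order(y, rowSums(X))

## extract (matrix, grid) from a SpectrumMatrix or matrix + wavelength
.asXw <- function(X, wavelength) {
  if (methods::is(X, "SpectrumMatrix")) {
    list(X = X@values, w = X@wavelength)
  } else {
    X <- as.matrix(X)
    if (is.null(wavelength)) wavelength <- seq_len(ncol(X))
    stopifnot(length(wavelength) == ncol(X))
    list(X = X, w = as.numeric(wavelength))
  }
}

#' Map wavelengths (nm) to band indices on a grid
#'
#' Nearest-neighbour mapping; errors if any requested wavelength is
#' farther from its nearest grid point than half the local band spacing
#' (so typos cannot silently land on the wrong band).
#'
#' @param grid strictly increasing wavelength grid (nm).
#' @param wl wavelengths to map (nm).
#' @return Integer vector of 1-based band indices.
#' @export
wavelengthToIndex <- function(grid, wl) {
  spacing <- stats::median(diff(grid))
  idx <- vapply(wl, function(w) which.min(abs(grid - w)), integer(1))
  off <- abs(grid[idx] - wl)
  bad <- off > spacing / 2
  if (any(bad))
    stop("wavelengths off-grid by more than half the band spacing: ",
         paste(wl[bad], collapse = ", "))
  idx
}

#' Band sets reported by the original loquat study
#'
#' Returns the reference CARS/GA/SPA wavelength subsets (nm) for each
#' quality target, shipped as a JSON fixture. These are fixed reference
#' values, useful for evaluating the accompanying reference MLR models
#' on new cubes.
#'
#' @param target `"colour_e"`, `"firmness"` or `"ssc"`.
#' @param method `"CARS"`, `"GA"` or `"SPA"`.
#' @return Numeric vector of wavelengths (nm).
#' @export
referenceSelectedWavelengths <- function(target = c("colour_e", "firmness",
                                                    "ssc"),
                                         method = c("CARS", "GA", "SPA")) {
  target <- match.arg(target)
  method <- match.arg(method)
  path <- system.file("extdata", "reference_selected_wavelengths.json",
                      package = "loquatHSI", mustWork = TRUE)
  as.numeric(jsonlite::fromJSON(path)[[target]][[method]])
}

## build a SelectionResult
.selectionResult <- function(method, indices, wavelength, trace, winning,
                             seed = NA_integer_, nRetained = integer(0)) {
  methods::new("SelectionResult", method = method,
               indices = sort(as.integer(indices)),
               wavelength = as.numeric(wavelength),
               rmsecvTrace = as.numeric(trace),
               winningIteration = as.integer(winning),
               nRetained = as.integer(nRetained),
               seed = as.integer(seed))
}

#' Serialise / load a SelectionResult as JSON
#'
#' @param x a [SelectionResult-class].
#' @param path JSON file path.
#' @return `readSelectionJSON` returns a [SelectionResult-class].
#' @export
writeSelectionJSON <- function(x, path) {
  jsonlite::write_json(
    list(method = x@method, indices = x@indices,
         selected_wavelengths = x@wavelength[x@indices],
         grid = x@wavelength, rmsecv_trace = x@rmsecvTrace,
         winning_iteration = x@winningIteration,
         n_retained = x@nRetained, seed = x@seed),
    path, auto_unbox = TRUE, digits = I(17), na = "null")
  invisible(path)
}

#' @rdname writeSelectionJSON
#' @export
readSelectionJSON <- function(path) {
  j <- jsonlite::fromJSON(path)
  .selectionResult(j$method, j$indices, j$grid, j$rmsecv_trace,
                   j$winning_iteration,
                   if (is.null(j$seed)) NA_integer_ else j$seed,
                   nRetained = if (is.null(j$n_retained)) integer(0)
                               else j$n_retained)
}
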