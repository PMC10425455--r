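## Competitive adaptive reweighted sampling (CARS).

#' CARS wavelength selection
#'
#' Monte-Carlo selection competing bands by the magnitude of their PLS
#' regression coefficients. Each run fits a PLS model on a random
#' calibration subset, force-retains the top bands under an
#' exponentially decreasing retention ratio (from 1 down to 2/p across
#' runs), then applies adaptive reweighted sampling (draws with
#' replacement proportional to |coefficient|) to the survivors. The
#' subset of the run with minimal cross-validated RMSE wins.
#'
#' Sample order is canonicalised before the seeded Monte-Carlo stream
#' starts, so permuting input rows does not change the selection.
#'
#' @param X [SpectrumMatrix-class] or numeric matrix (n x p).
#' @param y numeric response, length n, finite.
#' @param config a [carsConfig()] list.
#' @param wavelength grid (nm) when `X` is a plain matrix.
#' @return A [SelectionResult-class] with an `nRuns`-long RMSECV trace.
#' @export
carsSelect <- function(X, y, config = carsConfig(), wavelength = NULL) {
  xw <- .asXw(X, wavelength)
  X <- xw$X
  y <- as.numeric(y)
  if (any(!is.finite(y))) stop("carsSelect: y must be finite")
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n, n >= config$cvFolds + 2L)
  ord <- .canonicalOrder(X, y)
  X <- X[ord, , drop = FALSE]; y <- y[ord]
  set.seed(config$seed)
  N <- config$nRuns
  ## retention ratio r_i = a e^(-k i) with r_1 = 1, r_N = 2/p
  k <- log(p / 2) / (N - 1)
  aconst <- exp(k)
  retained <- seq_len(p)
  trace <- rep(NA_real_, N)
  subsets <- vector("list", N)
  nmc <- max(config$cvFolds + 2L, round(config$mcSampleFraction * n))
  nmc <- min(nmc, n)
  for (i in seq_len(N)) {
    if (length(retained) < 2L) break
    mc <- sort(sample(n, nmc))
    ncomp <- min(config$maxComp, nmc - 1L, length(retained))
    fit <- .plsFit(X[mc, retained, drop = FALSE], y[mc], ncomp)
    w <- abs(fit$B[, 1, fit$ncomp])
    ## forced retention by the decay schedule
    keep <- min(round(aconst * exp(-k * i) * p), length(retained))
    keep <- max(keep, 2L)
    topIdx <- order(w, decreasing = TRUE)[seq_len(keep)]
    forced <- retained[topIdx]
    wForced <- w[topIdx]
    ## adaptive reweighted sampling among the forced set
    if (sum(wForced) <= 0) {
      surv <- forced
    } else {
      draws <- sample(length(forced), keep, replace = TRUE,
                      prob = wForced / sum(wForced))
      surv <- forced[sort(unique(draws))]
    }
    if (length(surv) < 2L) surv <- forced[order(wForced,
                                                decreasing = TRUE)[1:2]]
    retained <- sort(surv)
    subsets[[i]] <- retained
    folds <- .makeFolds(n, config$cvFolds)
    rm <- .plsRMSECV(X[, retained, drop = FALSE], y,
                     min(config$maxComp, length(retained)), folds)
    trace[i] <- min(rm, na.rm = TRUE)
  }
  done <- which(is.finite(trace))
  if (!length(done)) stop("carsSelect: no run completed")
  win <- done[which.min(trace[done])]
  .selectionResult("CARS", subsets[[win]], xw$w, trace, win, config$seed,
                   nRetained = lengths(subsets[done]))
}
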