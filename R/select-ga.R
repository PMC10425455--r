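## Genetic-algorithm wavelength selection.

#' GA wavelength selection
#'
#' Binary chromosomes over the p bands; fitness is the negative 5-fold
#' cross-validated RMSE of a PLS model on the encoded subset (folds are
#' drawn once so all chromosomes are compared on the same partition).
#' Tournament selection (size 2), single-point crossover, bitwise
#' mutation, elitism of one. The best chromosome ever seen is returned,
#' so best-ever fitness is non-decreasing over generations.
#'
#' @inheritParams carsSelect
#' @param config a [gaConfig()] list.
#' @return A [SelectionResult-class]; the trace holds the best-ever
#'   RMSECV per generation, `winningIteration` the first generation
#'   achieving the optimum.
#' @export
gaSelect <- function(X, y, config = gaConfig(), wavelength = NULL) {
  xw <- .asXw(X, wavelength)
  X <- xw$X
  y <- as.numeric(y)
  if (any(!is.finite(y))) stop("gaSelect: y must be finite")
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n, n >= config$cvFolds + 2L)
  ord <- .canonicalOrder(X, y)
  X <- X[ord, , drop = FALSE]; y <- y[ord]
  set.seed(config$seed)
  folds <- .makeFolds(n, config$cvFolds)
  cache <- new.env(hash = TRUE, parent = emptyenv())
  evalChr <- function(chr) {
    if (!any(chr)) return(Inf)          # all-zero: worst, never fitted
    key <- paste(which(chr), collapse = ",")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    rm <- .plsRMSECV(X[, chr, drop = FALSE], y,
                     min(config$maxComp, sum(chr)), folds)
    val <- min(rm, na.rm = TRUE)
    cache[[key]] <- val
    val
  }
  np <- config$population
  pop <- matrix(stats::runif(np * p) < config$initP, np, p)
  empty <- which(!rowSums(pop))
  for (i in empty) pop[i, sample(p, 2L)] <- TRUE
  rmse <- apply(pop, 1, evalChr)
  bestChr <- pop[which.min(rmse), ]
  bestVal <- min(rmse)
  trace <- numeric(config$generations)
  for (g in seq_len(config$generations)) {
    newPop <- matrix(FALSE, np, p)
    newPop[1, ] <- bestChr                        # elitism of 1
    i <- 2L
    while (i <= np) {
      pick <- function() {
        cand <- sample(np, 2L)
        cand[which.min(rmse[cand])]
      }
      pa <- pop[pick(), ]; pb <- pop[pick(), ]
      if (stats::runif(1) < config$crossoverP) {
        cut <- sample(p - 1L, 1L)
        c1 <- c(pa[1:cut], pb[(cut + 1):p])
        c2 <- c(pb[1:cut], pa[(cut + 1):p])
      } else {
        c1 <- pa; c2 <- pb
      }
      mut <- function(chr) xor(chr, stats::runif(p) < config$mutationP)
      newPop[i, ] <- mut(c1)
      if (i + 1L <= np) newPop[i + 1L, ] <- mut(c2)
      i <- i + 2L
    }
    pop <- newPop
    rmse <- apply(pop, 1, evalChr)
    gBest <- which.min(rmse)
    if (rmse[gBest] < bestVal) {
      bestVal <- rmse[gBest]
      bestChr <- pop[gBest, ]
    }
    trace[g] <- bestVal
  }
  win <- which.min(trace)  # first generation reaching the optimum
  .selectionResult("GA", which(bestChr), xw$w, trace, win, config$seed)
}
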