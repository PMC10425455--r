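## Successive projections algorithm (SPA).

## one projection chain: starting at column j, repeatedly append the
## column with maximal norm orthogonal to the span of the chain.
## Returns the chain (possibly shorter than maxVars on collinear
## exhaustion). Ties break toward the lowest index (which.max).
.spaChain <- function(X, start, maxVars, tol = 1e-10) {
  p <- ncol(X)
  Z <- X
  chain <- integer(0)
  cur <- start
  ref <- sqrt(sum(X[, start]^2))
  for (step in seq_len(min(maxVars, p))) {
    chain <- c(chain, cur)
    if (length(chain) == maxVars) break
    zc <- Z[, cur]
    nz <- sum(zc^2)
    if (nz < (tol * max(ref, 1))^2) break
    ## deflate every column against the newly selected one
    proj <- crossprod(Z, zc) / nz
    Z <- Z - tcrossprod(zc, proj)
    Z[, chain] <- 0
    norms <- sqrt(colSums(Z^2))
    if (max(norms) < tol * max(ref, 1)) {
      message("spaSelect: chain truncated at length ", length(chain),
              " (collinear exhaustion)")
      break
    }
    cur <- which.max(norms)
  }
  chain
}

#' SPA wavelength selection
#'
#' Forward selection minimising collinearity: from every candidate
#' start band, a chain is grown by repeatedly picking the band with the
#' largest component orthogonal to the span of the bands already chosen.
#' Every (start, length) prefix with length in `[minVars, maxVars]` is
#' scored by the RMSE of an ordinary least-squares model on an internal
#' SPXY validation split; the global minimiser is returned. Fully
#' deterministic.
#'
#' @inheritParams carsSelect
#' @param config a [spaConfig()] list.
#' @return A [SelectionResult-class]; the trace holds, for each chain
#'   length, the best validation RMSE over all start bands.
#' @export
spaSelect <- function(X, y, config = spaConfig(), wavelength = NULL) {
  xw <- .asXw(X, wavelength)
  X <- xw$X
  y <- as.numeric(y)
  if (any(!is.finite(y))) stop("spaSelect: y must be finite")
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n, n >= 8L)
  maxVars <- min(config$maxVars, p, n - 2L)
  split <- spxySplit(X, y, 1 - config$validationFraction)
  Xc <- X[split@calIndices, , drop = FALSE]
  yc <- y[split@calIndices]
  Xv <- X[split@predIndices, , drop = FALSE]
  yv <- y[split@predIndices]
  valRmse <- function(bands) {
    fit <- stats::lm.fit(cbind(1, Xc[, bands, drop = FALSE]), yc)
    pred <- drop(cbind(1, Xv[, bands, drop = FALSE]) %*% fit$coefficients)
    if (any(!is.finite(pred))) return(Inf)
    sqrt(mean((yv - pred)^2))
  }
  lenBest <- rep(Inf, maxVars)          # best RMSE per chain length
  bestRmse <- Inf
  bestBands <- integer(0)
  for (start in seq_len(p)) {
    chain <- .spaChain(Xc, start, maxVars)
    if (length(chain) < config$minVars) next
    for (L in seq(config$minVars, length(chain))) {
      r <- valRmse(chain[seq_len(L)])
      if (r < lenBest[L]) lenBest[L] <- r
      if (r < bestRmse) {
        bestRmse <- r
        bestBands <- chain[seq_len(L)]
      }
    }
  }
  if (!length(bestBands)) stop("spaSelect: no valid chain found")
  win <- which.min(lenBest)
  .selectionResult("SPA", bestBands, xw$w,
                   ifelse(is.finite(lenBest), lenBest, NA_real_), win)
}
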