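## Internal partial-least-squares engine (SIMPLS). Returns the whole
## coefficient path (1..ncomp latent variables) from a single
## decomposition, which keeps the CARS / GA inner loops cheap. Supports
## multivariate Y for PLS-DA.

## X: n x p, Y: n x m. Returns list(B: p x m x A, intercept: m x A,
## ncomp: A actually extracted).
.plsFit <- function(X, Y, ncomp) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X); p <- ncol(X); m <- ncol(Y)
  A <- min(ncomp, n - 1L, p)
  xm <- colMeans(X); ym <- colMeans(Y)
  Xc <- sweep(X, 2, xm); Yc <- sweep(Y, 2, ym)
  S <- crossprod(Xc, Yc)
  R <- matrix(0, p, A); Q <- matrix(0, m, A); V <- matrix(0, p, A)
  a <- 0L
  for (i in seq_len(A)) {
    StS <- crossprod(S)
    q <- if (m == 1L) matrix(1, 1, 1) else {
      eg <- eigen(StS, symmetric = TRUE)
      eg$vectors[, 1, drop = FALSE]
    }
    r <- S %*% q
    t <- Xc %*% r
    normt <- sqrt(sum(t^2))
    if (normt < 1e-12) break
    t <- t / normt; r <- r / normt
    pA <- crossprod(Xc, t)
    qA <- crossprod(Yc, t)
    v <- pA
    if (a > 0L) v <- v - V[, seq_len(a), drop = FALSE] %*%
        crossprod(V[, seq_len(a), drop = FALSE], pA)
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) break
    v <- v / nv
    S <- S - v %*% crossprod(v, S)
    a <- a + 1L
    R[, a] <- r; Q[, a] <- qA; V[, a] <- v
  }
  if (a == 0L) stop("PLS: no latent variable could be extracted")
  B <- array(0, dim = c(p, m, a))
  intercept <- matrix(0, m, a)
  for (i in seq_len(a)) {
    Bi <- R[, seq_len(i), drop = FALSE] %*% t(Q[, seq_len(i), drop = FALSE])
    B[, , i] <- Bi
    intercept[, i] <- ym - drop(crossprod(Bi, xm))
  }
  list(B = B, intercept = intercept, ncomp = a, xMeans = xm, yMeans = ym)
}

## predictions for every component count: n x m x A
.plsPredictAll <- function(fit, X) {
  X <- as.matrix(X)
  A <- fit$ncomp; m <- ncol(fit$B[, , 1, drop = FALSE])
  out <- array(0, dim = c(nrow(X), dim(fit$B)[2], A))
  for (i in seq_len(A))
    out[, , i] <- sweep(X %*% fit$B[, , i], 2, fit$intercept[, i], "+")
  out
}

## k-fold RMSECV for y (univariate) at every component count.
## folds: integer vector of fold labels (caller controls randomness).
## Returns numeric vector length ncompMax (NA past extractable comps).
.plsRMSECV <- function(X, y, ncompMax, folds) {
  X <- as.matrix(X)
  nf <- max(folds)
  press <- matrix(NA_real_, nf, ncompMax)
  for (f in seq_len(nf)) {
    tr <- folds != f
    fit <- .plsFit(X[tr, , drop = FALSE], y[tr], ncompMax)
    pr <- .plsPredictAll(fit, X[!tr, , drop = FALSE])
    for (i in seq_len(fit$ncomp))
      press[f, i] <- sum((y[!tr] - pr[, 1, i])^2)
  }
  sse <- colSums(press)
  rmsecv <- sqrt(sse / length(y))
  ## per-fold RMSE spread, for the one-standard-error rule
  cnt <- vapply(seq_len(nf), function(f) sum(folds == f), numeric(1))
  foldRmse <- sqrt(press / cnt)
  se <- apply(foldRmse, 2, stats::sd) / sqrt(nf)
  structure(rmsecv, se = se)
}

## random fold assignment consuming the current RNG stream
.makeFolds <- function(n, k) {
  k <- min(k, n)
  sample(rep(seq_len(k), length.out = n))
}

## choose a component count from an RMSECV curve with a one-standard-
## error preference for fewer components
.chooseNcomp <- function(rmsecv, se = NULL) {
  ok <- which(is.finite(rmsecv))
  best <- ok[which.min(rmsecv[ok])]
  if (is.null(se)) return(best)
  thr <- rmsecv[best] + se[best]
  min(ok[rmsecv[ok] <= thr])
}
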