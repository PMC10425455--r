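## The five calibration families: PLSR, PCR, MLR, ELM, BP.

.sigmoid <- function(x) 1 / (1 + exp(-x))

## per-band [-1, 1] scaling used by the neural families
.rangeScaleFit <- function(X) {
  lo <- apply(X, 2, min); hi <- apply(X, 2, max)
  hi[hi == lo] <- lo[hi == lo] + 1
  list(lo = lo, hi = hi)
}
.rangeScaleApply <- function(X, sc)
  sweep(sweep(X, 2, sc$lo), 2, (sc$hi - sc$lo) / 2, "/") - 1

#' Fit a quality-calibration regression model
#'
#' Fits one of five families on the selected bands of a calibration
#' set:
#' \describe{
#'   \item{PLSR}{partial least squares; latent-variable count chosen by
#'     5-fold RMSECV (cap `maxComp`, default 20) with a one-standard-
#'     error preference for fewer components.}
#'   \item{PCR}{principal-component regression; component count chosen
#'     the same way (cap 30).}
#'   \item{MLR}{ordinary least squares on the selected bands; requires
#'     more calibration samples than coefficients and full rank.}
#'   \item{ELM}{extreme learning machine: fixed uniform random hidden
#'     weights (default 40 sigmoid nodes), output weights by least
#'     squares; inputs scaled to [-1, 1] per band.}
#'   \item{BP}{one-hidden-layer back-propagation network (default 10
#'     sigmoid nodes, linear output) trained by full-batch gradient
#'     descent with early stopping on an internal validation split.}
#' }
#' Stochastic families (ELM, BP and the CV fold draws) are
#' deterministic under `seed`.
#'
#' @param family `"PLSR"`, `"PCR"`, `"MLR"`, `"ELM"` or `"BP"`.
#' @param X calibration spectra, [SpectrumMatrix-class] or matrix.
#' @param y numeric response.
#' @param bands integer band indices the model uses (default: all).
#' @param hyper named list overriding family defaults (`maxComp`,
#'   `hiddenNodes`, `learningRate`, `maxEpochs`, `patience`).
#' @param seed integer RNG seed.
#' @param wavelength grid (nm) when `X` is a plain matrix.
#' @return A [RegressionModel-class].
#' @export
fitRegression <- function(family = c("PLSR", "PCR", "MLR", "ELM", "BP"),
                          X, y, bands = NULL, hyper = list(), seed = 1L,
                          wavelength = NULL) {
  family <- match.arg(family)
  tag <- if (methods::is(X, "SpectrumMatrix")) X@preprocessing else "raw"
  xw <- .asXw(X, wavelength)
  Xf <- xw$X
  y <- as.numeric(y)
  n <- nrow(Xf)
  stopifnot(length(y) == n)
  if (any(!is.finite(Xf)) || any(!is.finite(y)))
    stop("fitRegression: inputs must be finite")
  if (is.null(bands)) bands <- seq_len(ncol(Xf))
  bands <- sort(as.integer(bands))
  Xb <- Xf[, bands, drop = FALSE]
  p <- ncol(Xb)
  set.seed(seed)
  params <- switch(family,
    MLR = {
      if (n <= p + 1L)
        stop("MLR needs more calibration samples than bands + 1; ",
             "use fewer bands")
      fit <- stats::lm.fit(cbind(1, Xb), y)
      if (fit$rank < p + 1L)
        stop("MLR design is rank deficient; use fewer bands")
      cf <- fit$coefficients
      list(intercept = cf[1], coefficients = unname(cf[-1]))
    },
    PLSR = {
      maxComp <- min(if (!is.null(hyper$maxComp)) hyper$maxComp else 20L,
                     n - 2L, p)
      folds <- .makeFolds(n, 5L)
      rm <- .plsRMSECV(Xb, y, maxComp, folds)
      nc <- .chooseNcomp(rm, attr(rm, "se"))
      fit <- .plsFit(Xb, y, nc)
      list(ncomp = fit$ncomp,
           intercept = fit$intercept[1, fit$ncomp],
           coefficients = fit$B[, 1, fit$ncomp],
           rmsecv = as.numeric(rm))
    },
    PCR = {
      maxComp <- min(if (!is.null(hyper$maxComp)) hyper$maxComp else 30L,
                     n - 2L, p)
      folds <- .makeFolds(n, 5L)
      ## CV over component counts
      press <- matrix(NA_real_, max(folds), maxComp)
      for (f in seq_len(max(folds))) {
        tr <- folds != f
        pc <- stats::prcomp(Xb[tr, , drop = FALSE], center = TRUE,
                            scale. = FALSE)
        kmax <- min(maxComp, ncol(pc$rotation))
        Ztr <- pc$x[, seq_len(kmax), drop = FALSE]
        Zte <- scale(Xb[!tr, , drop = FALSE], pc$center, FALSE) %*%
          pc$rotation[, seq_len(kmax), drop = FALSE]
        for (k in seq_len(kmax)) {
          cf <- stats::lm.fit(cbind(1, Ztr[, 1:k, drop = FALSE]),
                              y[tr])$coefficients
          pr <- drop(cbind(1, Zte[, 1:k, drop = FALSE]) %*% cf)
          press[f, k] <- sum((y[!tr] - pr)^2)
        }
      }
      rm <- sqrt(colSums(press) / n)
      nc <- which.min(rm)
      pc <- stats::prcomp(Xb, center = TRUE, scale. = FALSE)
      nc <- min(nc, ncol(pc$rotation))
      cf <- stats::lm.fit(cbind(1, pc$x[, 1:nc, drop = FALSE]),
                          y)$coefficients
      beta <- pc$rotation[, 1:nc, drop = FALSE] %*% cf[-1]
      list(ncomp = nc,
           intercept = unname(cf[1] - drop(pc$center %*% beta)),
           coefficients = drop(beta), rmsecv = as.numeric(rm))
    },
    ELM = {
      h <- if (!is.null(hyper$hiddenNodes)) hyper$hiddenNodes else 40L
      act <- if (!is.null(hyper$activation)) hyper$activation else "sigmoid"
      sc <- .rangeScaleFit(Xb)
      Z <- .rangeScaleApply(Xb, sc)
      W <- if (!is.null(hyper$hiddenWeights)) hyper$hiddenWeights
           else matrix(stats::runif(h * (p + 1L), -1, 1), p + 1L, h)
      A <- cbind(1, Z) %*% W
      H <- if (act == "sigmoid") .sigmoid(A) else A
      beta <- qr.solve(cbind(1, H), y, tol = 1e-12)
      list(hidden = W, output = beta, scale = sc, activation = act)
    },
    BP = {
      h <- if (!is.null(hyper$hiddenNodes)) hyper$hiddenNodes else 10L
      lr <- if (!is.null(hyper$learningRate)) hyper$learningRate else 0.05
      maxEpochs <- if (!is.null(hyper$maxEpochs)) hyper$maxEpochs else 2000L
      patience <- if (!is.null(hyper$patience)) hyper$patience else 100L
      sc <- .rangeScaleFit(Xb)
      Z <- .rangeScaleApply(Xb, sc)
      ym <- mean(y); ys <- stats::sd(y); if (ys == 0) ys <- 1
      yz <- (y - ym) / ys
      val <- sample(n, max(2L, round(0.25 * n)))
      tr <- setdiff(seq_len(n), val)
      W1 <- matrix(stats::rnorm(h * (p + 1L), 0, 0.5), p + 1L, h)
      W2 <- stats::rnorm(h + 1L, 0, 0.5)
      fwd <- function(Zm) {
        H <- .sigmoid(cbind(1, Zm) %*% W1)
        list(H = H, yhat = drop(cbind(1, H) %*% W2))
      }
      best <- list(err = Inf, W1 = W1, W2 = W2)
      wait <- 0L
      Ztr <- Z[tr, , drop = FALSE]; ytr <- yz[tr]
      Zval <- Z[val, , drop = FALSE]; yval <- yz[val]
      ntr <- length(tr)
      for (ep in seq_len(maxEpochs)) {
        f <- fwd(Ztr)
        err <- f$yhat - ytr
        gW2 <- crossprod(cbind(1, f$H), err) / ntr
        dH <- tcrossprod(err, W2[-1]) * f$H * (1 - f$H)
        gW1 <- crossprod(cbind(1, Ztr), dH) / ntr
        W2 <- W2 - lr * drop(gW2)
        W1 <- W1 - lr * gW1
        vErr <- mean((fwd(Zval)$yhat - yval)^2)
        if (vErr < best$err - 1e-9) {
          best <- list(err = vErr, W1 = W1, W2 = W2)
          wait <- 0L
        } else {
          wait <- wait + 1L
          if (wait >= patience) break
        }
      }
      list(hidden = best$W1, output = best$W2, scale = sc,
           yCenter = ym, yScale = ys, activation = "sigmoid")
    })
  methods::new("RegressionModel", family = family, bandIndices = bands,
               wavelength = xw$w[bands], preprocessing = tag,
               parameters = params,
               seed = if (family %in% c("ELM", "BP")) as.integer(seed)
                      else NA_integer_)
}

#' Predict from a fitted regression model
#'
#' @param object a [RegressionModel-class].
#' @param newdata [SpectrumMatrix-class] or numeric matrix. Either the
#'   full grid the model was fitted on (columns are subset by the
#'   model's band indices) or exactly the model's bands.
#' @return Numeric vector of predictions.
#' @export
setMethod("predict", "RegressionModel", function(object, newdata) {
  X <- if (methods::is(newdata, "SpectrumMatrix")) {
    if (newdata@preprocessing != object@preprocessing)
      stop("preprocessing mismatch: model expects '", object@preprocessing,
           "', data is '", newdata@preprocessing, "'")
    newdata@values
  } else as.matrix(newdata)
  k <- length(object@bandIndices)
  Xb <- if (ncol(X) == k) X
  else if (ncol(X) >= max(object@bandIndices))
    X[, object@bandIndices, drop = FALSE]
  else stop("newdata has ", ncol(X), " bands; model needs ", k,
            " (or the full grid)")
  par <- object@parameters
  switch(object@family,
    MLR = , PLSR = , PCR =
      drop(Xb %*% par$coefficients) + par$intercept,
    ELM = {
      Z <- .rangeScaleApply(Xb, par$scale)
      A <- cbind(1, Z) %*% par$hidden
      H <- if (identical(par$activation, "linear")) A else .sigmoid(A)
      drop(cbind(1, H) %*% par$output)
    },
    BP = {
      Z <- .rangeScaleApply(Xb, par$scale)
      H <- .sigmoid(cbind(1, Z) %*% par$hidden)
      drop(cbind(1, H) %*% par$output) * par$yScale + par$yCenter
    })
})

#' Serialise / load a regression model as JSON
#'
#' Linear families round-trip predictions bit-exactly; the neural
#' families round-trip to numerical JSON precision.
#'
#' @param model a [RegressionModel-class].
#' @param path JSON file path.
#' @return `readModelJSON` returns a [RegressionModel-class].
#' @export
writeModelJSON <- function(model, path) {
  par <- lapply(model@parameters, function(x)
    if (is.matrix(x)) list(mat = as.vector(x), dim = dim(x)) else x)
  jsonlite::write_json(
    list(family = model@family, band_indices = model@bandIndices,
         wavelengths = model@wavelength,
         preprocessing = model@preprocessing, parameters = par,
         seed = model@seed),
    path, auto_unbox = TRUE, digits = I(17), na = "null")
  invisible(path)
}

#' @rdname writeModelJSON
#' @export
readModelJSON <- function(path) {
  j <- jsonlite::fromJSON(path)
  par <- lapply(j$parameters, function(x)
    if (is.list(x) && !is.null(x$dim)) matrix(x$mat, x$dim[1], x$dim[2])
    else unlist(x))
  ## scale sublist survives as list of two vectors
  if (!is.null(par$scale)) par$scale <- as.list(j$parameters$scale)
  methods::new("RegressionModel", family = j$family,
               bandIndices = as.integer(j$band_indices),
               wavelength = as.numeric(j$wavelengths),
               preprocessing = j$preprocessing, parameters = par,
               seed = if (is.null(j$seed) || is.na(j$seed)) NA_integer_
                      else as.integer(j$seed))
}
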