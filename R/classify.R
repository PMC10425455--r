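## Maturity-stage discrimination: PLS-DA, simplified KNN (nearest class
## centroid) and SVM, plus confusion/accuracy arithmetic.

#' Fit a maturity-stage classifier
#'
#' \describe{
#'   \item{PLSDA}{PLS regression of the one-hot class indicator matrix
#'     on the spectra (latent variables chosen by 5-fold CV on the
#'     misclassification rate); class = argmax of the predicted
#'     scores.}
#'   \item{SKNN}{simplified K nearest neighbour, read here as nearest
#'     class centroid: each class is represented by its mean spectrum
#'     and a sample takes the class of the nearest centroid
#'     (Euclidean).}
#'   \item{SVM}{RBF-kernel SVM, one-vs-one, with (cost, gamma) chosen
#'     by 5-fold grid search over 2^(-5..10) x 2^(-10..3).}
#' }
#' Ties (equal scores or distances) break toward the earlier stage.
#'
#' @param family `"PLSDA"`, `"SKNN"` or `"SVM"`.
#' @param X calibration spectra, [SpectrumMatrix-class] or matrix.
#' @param labels factor/character stage labels; >= 2 classes, each with
#'   >= 2 members.
#' @param hyper named list of overrides (`maxComp` for PLSDA;
#'   `costGrid`, `gammaGrid`, `cvFolds` for SVM).
#' @param seed integer RNG seed (fold draws, SVM internals).
#' @return A [ClassifierModel-class].
#' @export
fitClassifier <- function(family = c("PLSDA", "SKNN", "SVM"), X, labels,
                          hyper = list(), seed = 1L) {
  family <- match.arg(family)
  if (methods::is(X, "SpectrumMatrix")) X <- X@values
  X <- as.matrix(X)
  labels <- factor(as.character(labels),
                   levels = intersect(c("I", "II", "III"),
                                      unique(as.character(labels))))
  n <- nrow(X)
  stopifnot(length(labels) == n)
  if (nlevels(labels) < 2L)
    stop("fitClassifier: need at least 2 classes present")
  if (any(table(labels) < 2L))
    stop("fitClassifier: every class needs at least 2 members")
  classes <- levels(labels)
  set.seed(seed)
  params <- switch(family,
    SKNN = {
      cent <- t(vapply(classes, function(cl)
        colMeans(X[labels == cl, , drop = FALSE]), numeric(ncol(X))))
      list(centroids = cent)
    },
    PLSDA = {
      maxComp <- min(if (!is.null(hyper$maxComp)) hyper$maxComp else 10L,
                     n - 2L, ncol(X))
      Y <- stats::model.matrix(~ labels - 1)
      colnames(Y) <- classes
      folds <- .makeFolds(n, 5L)
      err <- rep(NA_real_, maxComp)
      predAll <- array(NA_real_, c(n, nlevels(labels), maxComp))
      for (f in seq_len(max(folds))) {
        tr <- folds != f
        fit <- .plsFit(X[tr, , drop = FALSE], Y[tr, , drop = FALSE],
                       maxComp)
        pr <- .plsPredictAll(fit, X[!tr, , drop = FALSE])
        predAll[!tr, , seq_len(fit$ncomp)] <- pr
      }
      for (k in seq_len(maxComp)) {
        if (any(!is.finite(predAll[, , k]))) next
        cl <- classes[apply(predAll[, , k], 1, which.max)]
        err[k] <- mean(cl != as.character(labels))
      }
      nc <- which.min(err)   # ties: fewer latent variables
      fit <- .plsFit(X, Y, nc)
      list(ncomp = fit$ncomp, B = fit$B[, , fit$ncomp],
           intercept = fit$intercept[, fit$ncomp], cvError = err)
    },
    SVM = {
      costGrid <- if (!is.null(hyper$costGrid)) hyper$costGrid
                  else 2^(-5:10)
      gammaGrid <- if (!is.null(hyper$gammaGrid)) hyper$gammaGrid
                   else 2^(-10:3)
      nf <- if (!is.null(hyper$cvFolds)) hyper$cvFolds else 5L
      folds <- .makeFolds(n, nf)
      best <- list(err = Inf, cost = costGrid[1], gamma = gammaGrid[1])
      for (g in gammaGrid) for (C in costGrid) {
        nerr <- 0L
        for (f in seq_len(max(folds))) {
          tr <- folds != f
          m <- e1071::svm(X[tr, , drop = FALSE], labels[tr],
                          kernel = "radial", cost = C, gamma = g,
                          scale = FALSE)
          pr <- stats::predict(m, X[!tr, , drop = FALSE])
          nerr <- nerr + sum(pr != labels[!tr])
        }
        e <- nerr / n
        if (e < best$err) best <- list(err = e, cost = C, gamma = g)
      }
      m <- e1071::svm(X, labels, kernel = "radial", cost = best$cost,
                      gamma = best$gamma, scale = FALSE)
      list(svm = m, cost = best$cost, gamma = best$gamma,
           cvError = best$err)
    })
  methods::new("ClassifierModel", family = family, parameters = params,
               classes = classes, seed = as.integer(seed))
}

#' Classify spectra with a fitted model
#'
#' @param object a [ClassifierModel-class].
#' @param newdata [SpectrumMatrix-class] or matrix with the bands the
#'   model was trained on.
#' @return Factor of predicted stages.
#' @export
setMethod("predict", "ClassifierModel", function(object, newdata) {
  X <- if (methods::is(newdata, "SpectrumMatrix")) newdata@values
       else as.matrix(newdata)
  par <- object@parameters
  lab <- switch(object@family,
    SKNN = {
      d2 <- outer(rowSums(X^2), rowSums(par$centroids^2), "+") -
        2 * X %*% t(par$centroids)
      object@classes[apply(d2, 1, which.min)]
    },
    PLSDA = {
      sc <- sweep(X %*% par$B, 2, par$intercept, "+")
      object@classes[apply(sc, 1, which.max)]
    },
    SVM = as.character(stats::predict(par$svm, X)))
  factor(lab, levels = object@classes)
})

#' Confusion matrix of true vs predicted stages
#'
#' @param true,predicted factors/characters of matching length.
#' @param classes label universe (default stages I/II/III).
#' @return Integer matrix, rows = true, columns = predicted.
#' @export
confusionCounts <- function(true, predicted, classes = c("I", "II", "III")) {
  true <- as.character(true); predicted <- as.character(predicted)
  stopifnot(length(true) == length(predicted))
  bad <- setdiff(unique(c(true, predicted)), classes)
  if (length(bad))
    stop("unknown label value(s): ", paste(bad, collapse = ", "))
  cm <- table(factor(true, classes), factor(predicted, classes))
  m <- matrix(as.integer(cm), length(classes), length(classes),
              dimnames = list(true = classes, predicted = classes))
  m
}

#' Calibration/prediction accuracy report
#'
#' Computes, per set, the sample count, error count and accuracy
#' 100 (n - err) / n, plus the pooled total accuracy
#' 100 (n_cal + n_pred - err_cal - err_pred) / (n_cal + n_pred).
#' Accuracies are reported to 2 decimals.
#'
#' @param cmCal,cmPred confusion matrices from [confusionCounts()].
#' @return One-row data frame with columns `n_cal`, `err_cal`,
#'   `acc_cal`, `n_pred`, `err_pred`, `acc_pred`, `acc_total`.
#' @export
accuracyReport <- function(cmCal, cmPred) {
  one <- function(cm) {
    n <- sum(cm)
    if (n < 1L) stop("empty set in accuracy report")
    err <- n - sum(diag(cm))
    c(n = n, err = err)
  }
  a <- one(cmCal); b <- one(cmPred)
  acc <- function(n, err) round(100 * (n - err) / n, 2)
  data.frame(n_cal = a["n"], err_cal = a["err"],
             acc_cal = acc(a["n"], a["err"]),
             n_pred = b["n"], err_pred = b["err"],
             acc_pred = acc(b["n"], b["err"]),
             acc_total = acc(a["n"] + b["n"], a["err"] + b["err"]),
             row.names = NULL)
}
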