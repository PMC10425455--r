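## Deterministic calibration/prediction splitting: Kennard-Stone
## farthest-point sampling and its SPXY variant driven by joint
## spectrum-response distances.

#' SplitResult: a calibration/prediction partition
#'
#' @slot calIndices,predIndices disjoint 1-based sample indices whose
#'   union covers all samples.
#' @slot method `"SPXY"` or `"KS"`.
#' @slot calFraction requested calibration fraction.
#' @exportClass SplitResult
setClass("SplitResult",
  representation(calIndices = "integer", predIndices = "integer",
                 method = "character", calFraction = "numeric"),
  validity = function(object) {
    if (length(intersect(object@calIndices, object@predIndices)))
      return("calibration and prediction sets overlap")
    if (!length(object@calIndices) || !length(object@predIndices))
      return("both sets must be non-empty")
    if (!object@method %in% c("SPXY", "KS")) return("invalid method")
    TRUE
  })

setMethod("show", "SplitResult", function(object) {
  cat(sprintf("SplitResult [%s]: %d calibration / %d prediction\n",
              object@method, length(object@calIndices),
              length(object@predIndices)))
})

## round half away from zero
.rhalf <- function(x) sign(x) * floor(abs(x) + 0.5)

## farthest-point (Kennard-Stone) selection on a distance matrix;
## ties broken toward the lowest index
.ksCore <- function(D, k) {
  n <- nrow(D)
  stopifnot(k >= 1L, k < n)
  if (k == 1L) return(1L)  # degenerate: deterministic lowest index
  sel <- integer(k)
  best <- arrayInd(which.max(D), dim(D))  # first (lowest) linear index wins
  sel[1:2] <- sort(c(best[1], best[2]))
  dmin <- pmin(D[, sel[1]], D[, sel[2]])
  dmin[sel[1:2]] <- -Inf
  for (i in seq_len(k - 2L) + 2L) {
    nxt <- which.max(dmin)
    sel[i] <- nxt
    dmin <- pmin(dmin, D[, nxt])
    dmin[nxt] <- -Inf
  }
  sort(sel)
}

.distMat <- function(M) as.matrix(stats::dist(M))

#' SPXY calibration/prediction split
#'
#' Kennard-Stone-style farthest-point selection on joint spectrum and
#' response distances: the X and y Euclidean distance matrices are each
#' normalised by their maximum and summed, so the calibration set covers
#' both spectral and response space. The calibration size is
#' `round(calFraction * n)` (half away from zero). Deterministic; ties
#' go to the lowest sample index.
#'
#' @param X numeric matrix or [SpectrumMatrix-class] (n x p).
#' @param y numeric response vector (standardised internally).
#' @param calFraction calibration fraction in (0, 1); default 0.75 for
#'   the 3:1 split.
#' @return A [SplitResult-class].
#' @export
spxySplit <- function(X, y, calFraction = 0.75) {
  if (methods::is(X, "SpectrumMatrix")) X <- X@values
  if (!(calFraction > 0 && calFraction < 1))
    stop("calFraction must be in (0, 1)")
  n <- nrow(X)
  stopifnot(n >= 4L, length(y) == n)
  if (any(!is.finite(y))) stop("y must be finite")
  Dx <- .distMat(X)
  ys <- (y - mean(y)) / stats::sd(y)
  Dy <- .distMat(matrix(ys, ncol = 1))
  D <- Dx / max(Dx) + Dy / max(Dy)
  k <- as.integer(.rhalf(calFraction * n))
  sel <- .ksCore(D, k)
  methods::new("SplitResult", calIndices = sel,
               predIndices = setdiff(seq_len(n), sel),
               method = "SPXY", calFraction = calFraction)
}

#' Kennard-Stone calibration/prediction split
#'
#' Farthest-point selection on spectral Euclidean distances; with
#' `labels` given, selection runs within each class and per-class
#' calibration sizes are `round(calFraction * classSize)` adjusted by
#' largest remainder so the total matches `round(calFraction * n)`.
#'
#' @param X numeric matrix or [SpectrumMatrix-class].
#' @param calFraction calibration fraction in (0, 1); default 2/3 for
#'   the 2:1 split.
#' @param labels optional class labels (factor/character) for a
#'   stratified split; every class needs at least 2 members.
#' @return A [SplitResult-class].
#' @export
kennardStoneSplit <- function(X, calFraction = 2 / 3, labels = NULL) {
  if (methods::is(X, "SpectrumMatrix")) X <- X@values
  if (!(calFraction > 0 && calFraction < 1))
    stop("calFraction must be in (0, 1)")
  n <- nrow(X)
  stopifnot(n >= 3L)
  if (is.null(labels)) {
    k <- as.integer(.rhalf(calFraction * n))
    sel <- .ksCore(.distMat(X), k)
    return(methods::new("SplitResult", calIndices = sel,
                        predIndices = setdiff(seq_len(n), sel),
                        method = "KS", calFraction = calFraction))
  }
  labels <- as.factor(labels)
  stopifnot(length(labels) == n)
  sizes <- table(labels)
  if (any(sizes < 2L))
    stop("stratified split needs >= 2 members per class; offending: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  perClass <- as.integer(.rhalf(calFraction * as.numeric(sizes)))
  total <- as.integer(.rhalf(calFraction * n))
  ## largest-remainder repair toward the exact total
  rem <- calFraction * as.numeric(sizes) - perClass
  while (sum(perClass) < total) {
    cand <- which(perClass < as.numeric(sizes) - 1L)
    i <- cand[which.max(rem[cand])]
    perClass[i] <- perClass[i] + 1L
    rem[i] <- rem[i] - 1
  }
  while (sum(perClass) > total) {
    cand <- which(perClass > 1L)
    i <- cand[which.min(rem[cand])]
    perClass[i] <- perClass[i] - 1L
    rem[i] <- rem[i] + 1
  }
  sel <- integer(0)
  for (ci in seq_along(levels(labels))) {
    idx <- which(labels == levels(labels)[ci])
    selLocal <- .ksCore(.distMat(X[idx, , drop = FALSE]), perClass[ci])
    sel <- c(sel, idx[selLocal])
  }
  sel <- sort(sel)
  methods::new("SplitResult", calIndices = sel,
               predIndices = setdiff(seq_len(n), sel),
               method = "KS", calFraction = calFraction)
}

#' Serialise a split as CSV
#'
#' Writes rows `sample_id,set` with `set` in `{cal, pred}`.
#'
#' @param split a [SplitResult-class].
#' @param sampleIds character ids, one per sample.
#' @param path output CSV path.
#' @export
writeSplitCSV <- function(split, sampleIds, path) {
  n <- length(split@calIndices) + length(split@predIndices)
  stopifnot(length(sampleIds) == n)
  set <- rep("pred", n)
  set[split@calIndices] <- "cal"
  utils::write.csv(data.frame(sample_id = sampleIds, set = set), path,
                   row.names = FALSE)
  invisible(path)
}
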