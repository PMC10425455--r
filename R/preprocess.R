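## Standard normal variate preprocessing.

#' Standard normal variate (SNV) transform
#'
#' Centres each spectrum to mean 0 and scales it to standard deviation 1
#' (n-1 denominator), row by row. SNV removes per-sample multiplicative
#' gain and additive offset — the scatter artefacts of diffuse
#' reflectance off curved fruit surfaces — and is idempotent.
#'
#' @param x a [SpectrumMatrix-class] or plain numeric matrix (rows =
#'   spectra).
#' @return Same type as the input; a `SpectrumMatrix` is retagged
#'   `"snv"`.
#' @export
snv <- function(x) {
  mat <- if (methods::is(x, "SpectrumMatrix")) x@values else as.matrix(x)
  mu <- rowMeans(mat)
  sdv <- apply(mat, 1, stats::sd)
  zero <- which(sdv == 0)
  if (length(zero)) {
    ids <- if (!is.null(rownames(mat))) rownames(mat)[zero]
           else as.character(zero)
    stop("snv: constant spectrum (zero sd) for sample(s): ",
         paste(ids, collapse = ", "))
  }
  out <- (mat - mu) / sdv
  if (methods::is(x, "SpectrumMatrix"))
    SpectrumMatrix(out, x@wavelength, preprocessing = "snv")
  else out
}
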