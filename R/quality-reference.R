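## Reference-chemistry formulas: colour e value, maturity staging,
## summary statistics, and the QualityTable data frame contract.

.STAGE_LO <- 8.33
.STAGE_HI <- 15.41

#' Colour e value from CIELAB coordinates
#'
#' The colour statistic e = 1000 a* / (L* x b*), which emphasises the
#' contrast between the red-green (a*) and yellow-blue (b*) directions
#' and tracks loquat ripening: green fruit have negative a* and small e,
#' deep-orange fruit large positive e.
#'
#' @param L CIELAB lightness L* (nonzero).
#' @param a CIELAB a* (red-green).
#' @param b CIELAB b* (yellow-blue, nonzero).
#' @return Numeric colour e value(s); vectorised over its arguments.
#' @examples
#' colourEValue(50, 10, 20)  # 10
#' @export
colourEValue <- function(L, a, b) {
  if (any(!is.finite(L)) || any(!is.finite(a)) || any(!is.finite(b)))
    stop("colourEValue: inputs must be finite")
  if (any(L == 0)) stop("colourEValue: L* must be nonzero")
  if (any(b == 0)) stop("colourEValue: b* must be nonzero")
  1000 * a / (L * b)
}

#' Assign a loquat maturity stage from colour a*
#'
#' Stage I: a* < 8.33; stage II: 8.33 <= a* <= 15.41 (both boundaries
#' closed, so the three predicates partition the line); stage III:
#' a* > 15.41.
#'
#' @param a numeric vector of CIELAB a* values.
#' @return Factor with levels `I`, `II`, `III`.
#' @export
assignMaturityStage <- function(a) {
  if (any(!is.finite(a))) stop("assignMaturityStage: a* must be finite")
  stage <- ifelse(a < .STAGE_LO, "I", ifelse(a <= .STAGE_HI, "II", "III"))
  factor(stage, levels = c("I", "II", "III"))
}

#' Summary statistics of a quality parameter
#'
#' Count, range, mean and standard deviation (n-1 denominator), the
#' columns of a calibration/prediction statistics table.
#'
#' @param values numeric vector, at least one finite value.
#' @return A one-row data frame with columns `num`, `min`, `max`, `mean`,
#'   `sd` (`sd` is NA for a single value).
#' @export
summarizeQuality <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 1L || any(!is.finite(values)))
    stop("summarizeQuality: need at least one finite value")
  data.frame(num = length(values), min = min(values), max = max(values),
             mean = mean(values),
             sd = if (length(values) > 1L) stats::sd(values) else NA_real_)
}

## internal: validate the QualityTable data frame contract
.checkQualityTable <- function(tab) {
  need <- c("sample_id", "L", "a", "b", "colour_e", "firmness", "ssc", "stage")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("QualityTable missing columns: ", paste(miss, collapse = ", "))
  if (nrow(tab) < 1L) stop("QualityTable must be non-empty")
  if (anyDuplicated(tab$sample_id)) stop("sample_ids must be unique")
  if (any(tab$firmness <= 0)) stop("firmness must be > 0")
  if (any(tab$ssc < 0)) stop("ssc must be >= 0")
  ce <- colourEValue(tab$L, tab$a, tab$b)
  if (any(abs(ce - tab$colour_e) > 1e-6 * pmax(1, abs(ce))))
    stop("colour_e inconsistent with 1000*a/(L*b)")
  st <- assignMaturityStage(tab$a)
  if (any(as.character(st) != as.character(tab$stage)))
    stop("stage inconsistent with a* thresholds 8.33/15.41")
  invisible(tab)
}

#' Read / write a quality table as CSV
#'
#' The CSV carries one row per fruit with columns
#' `sample_id,L,a,b,colour_e,firmness,ssc,stage`. On read the table is
#' validated: colour_e must equal 1000 a*/(L* b*) and stage must agree
#' with the a* thresholds 8.33 / 15.41.
#'
#' @param path file path.
#' @return `readQualityTable` returns the validated data frame.
#' @export
readQualityTable <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab$stage <- factor(tab$stage, levels = c("I", "II", "III"))
  .checkQualityTable(tab)
  tab
}

#' @rdname readQualityTable
#' @param tab a quality table data frame.
#' @export
writeQualityTable <- function(tab, path) {
  .checkQualityTable(tab)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
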