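## Synthetic loquat data: quality tables, reflectance spectra and small
## labelled scenes with the statistical structure the pipeline assumes.
##
## The spectral model is continuum - chlorophyll dip (depth decreasing
## with a*, i.e. ripening) - water dip, plus sparse per-quality band
## loadings so that colour e, firmness and SSC are each linearly
## recoverable from a known 5-band set after SNV; then per-sample
## multiplicative/additive scatter (what SNV removes) and noise.

## fixed per-stage generating distributions (I, II, III)
.GEN <- list(
  a_mean = c(3.5, 11.8, 19.0), a_sd = c(2.0, 1.7, 2.0),
  L_mean = c(58, 52, 47), L_sd = 3, L_min = 20,
  b_mean = 30, b_sd = 3, b_min = 5,
  firm_mean = c(3.3, 2.4, 1.3), firm_sd = 0.4, firm_min = 0.3,
  ssc_mean = c(6.6, 7.9, 9.4), ssc_sd = 0.8, ssc_min = 3,
  ## standardisation constants for the spectral loadings (mixture-level
  ## moments of the generating distributions, fixed, not data-derived)
  z_mu = c(colour_e = 7.4, firmness = 2.4, ssc = 7.9),
  z_sd = c(colour_e = 4.2, firmness = 0.8, ssc = 1.2),
  ## informative bands (nm) and loading amplitudes per quality target
  bands = list(colour_e = c(420, 500, 560, 640, 720),
               firmness = c(450, 620, 760, 800, 860),
               ssc      = c(740, 840, 900, 940, 1010)),
  amps  = list(colour_e = c(0.045, -0.035, 0.050, -0.040, 0.045),
               firmness = c(0.050, -0.040, 0.045, -0.050, 0.040),
               ssc      = c(0.045, -0.050, 0.040, 0.050, -0.040)))

#' Parameters of the synthetic spectrum generator
#'
#' Defaults emulate the instrument grid (256 bands, 390-1030 nm), the
#' chlorophyll absorption feature near 675 nm and the water feature near
#' 980 nm, moderate multiplicative/additive scatter (the artefact SNV is
#' applied to remove) and additive sensor noise.
#'
#' @param nBands number of bands (>= 2).
#' @param wlMin,wlMax wavelength range in nm.
#' @param chlorophyllCenter,waterCenter absorption-dip centres (nm).
#' @param scatterGainSd sd of the per-sample log multiplicative gain.
#' @param scatterOffsetSd sd of the per-sample additive offset
#'   (reflectance units).
#' @param noiseSd sd of per-band additive noise (reflectance units).
#' @param stageProportions length-3 proportions of stages I/II/III,
#'   summing to 1; defaults follow the observed stage frequencies
#'   177/331/141 in a 649-fruit harvest.
#' @return A list of class `SynthSpectraParams`.
#' @export
synthSpectraParams <- function(nBands = 256L, wlMin = 390, wlMax = 1030,
                               chlorophyllCenter = 675, waterCenter = 980,
                               scatterGainSd = 0.08, scatterOffsetSd = 0.04,
                               noiseSd = 0.005,
                               stageProportions = c(0.27, 0.51, 0.22)) {
  stopifnot(nBands >= 2L, wlMin < wlMax, scatterGainSd >= 0,
            scatterOffsetSd >= 0, noiseSd >= 0,
            length(stageProportions) == 3L, all(stageProportions >= 0),
            abs(sum(stageProportions) - 1) < 1e-8)
  structure(list(nBands = as.integer(nBands), wlMin = wlMin, wlMax = wlMax,
                 chlorophyllCenter = chlorophyllCenter,
                 waterCenter = waterCenter, scatterGainSd = scatterGainSd,
                 scatterOffsetSd = scatterOffsetSd, noiseSd = noiseSd,
                 stageProportions = stageProportions),
            class = "SynthSpectraParams")
}

#' Wavelength grid of a parameter set
#' @param params a `SynthSpectraParams` list.
#' @return Numeric vector of `nBands` evenly spaced wavelengths (nm).
#' @export
paramsGrid <- function(params)
  seq(params$wlMin, params$wlMax, length.out = params$nBands)

#' True informative bands of the generator
#'
#' Returns the 1-based grid indices of the 5 bands through which the
#' generator couples a quality target to the spectra; the ground truth
#' that wavelength-selection algorithms are expected to recover.
#'
#' @param params a `SynthSpectraParams` list.
#' @param target `"colour_e"`, `"firmness"` or `"ssc"`.
#' @return Sorted integer vector of 5 band indices.
#' @export
generatorBands <- function(params, target = c("colour_e", "firmness", "ssc")) {
  target <- match.arg(target)
  grid <- paramsGrid(params)
  sort(vapply(.GEN$bands[[target]],
              function(w) which.min(abs(grid - w)), integer(1)))
}

## truncated-normal sampler by rejection (vectorised, deterministic
## under the current RNG state)
.rtrunc <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    x <- stats::rnorm(length(todo), mean, sd)
    ok <- x >= lo & x <= hi
    out[todo[ok]] <- x[ok]
    todo <- todo[!ok]
  }
  out
}

#' Simulate a loquat quality table
#'
#' Draws per-stage truncated Gaussians for CIELAB a* (truncated to the
#' stage interval so labels and thresholds agree by construction), L*,
#' b*, firmness and SSC; stage means are ordered so that colour e and
#' SSC increase and firmness decreases with maturity. Colour e is
#' computed as 1000 a*/(L* b*).
#'
#' @param n number of fruit (>= 3).
#' @param stageProportions length-3 proportions for stages I/II/III.
#' @param seed integer RNG seed; the same seed reproduces the table.
#' @return A validated quality table data frame (see
#'   [readQualityTable()]).
#' @export
simulateQualityTable <- function(n, stageProportions = c(0.27, 0.51, 0.22),
                                 seed = 1L) {
  stopifnot(n >= 3L, length(stageProportions) == 3L,
            abs(sum(stageProportions) - 1) < 1e-8)
  counts <- .apportion(n, stageProportions)
  if (any(counts == 0L & stageProportions > 0))
    stop("degenerate proportions: a requested stage would receive 0 samples")
  set.seed(seed)
  g <- .GEN
  lims <- list(c(-Inf, .STAGE_LO - 1e-9), c(.STAGE_LO, .STAGE_HI),
               c(.STAGE_HI + 1e-9, Inf))
  rows <- lapply(1:3, function(s) {
    ns <- counts[s]
    if (ns == 0L) return(NULL)
    a <- .rtrunc(ns, g$a_mean[s], g$a_sd[s], lims[[s]][1], lims[[s]][2])
    L <- .rtrunc(ns, g$L_mean[s], g$L_sd, g$L_min)
    b <- .rtrunc(ns, g$b_mean, g$b_sd, g$b_min)
    firm <- .rtrunc(ns, g$firm_mean[s], g$firm_sd, g$firm_min)
    ssc <- .rtrunc(ns, g$ssc_mean[s], g$ssc_sd, g$ssc_min)
    data.frame(L = L, a = a, b = b, firmness = firm, ssc = ssc)
  })
  tab <- do.call(rbind, rows)
  tab$colour_e <- colourEValue(tab$L, tab$a, tab$b)
  tab$stage <- assignMaturityStage(tab$a)
  tab$sample_id <- sprintf("loquat_%03d", seq_len(nrow(tab)))
  tab <- tab[c("sample_id", "L", "a", "b", "colour_e", "firmness", "ssc",
               "stage")]
  rownames(tab) <- NULL
  .checkQualityTable(tab)
}

## largest-remainder apportionment of n into parts proportional to p
.apportion <- function(n, p) {
  raw <- n * p / sum(p)
  k <- floor(raw)
  rem <- n - sum(k)
  if (rem > 0) {
    ord <- order(raw - k, decreasing = TRUE)
    k[ord[seq_len(rem)]] <- k[ord[seq_len(rem)]] + 1
  }
  as.integer(k)
}

## deterministic (noise-free, scatter-free) spectrum for one quality row
.cleanSpectrum <- function(grid, L, a, b, firmness, ssc, params) {
  g <- .GEN
  continuum <- 0.28 + 0.42 * stats::plogis((grid - 680) / 55)
  chl <- 0.26 * stats::plogis((12 - a) / 3.5) *
    exp(-(grid - params$chlorophyllCenter)^2 / (2 * 18^2))
  wat <- 0.12 * exp(-(grid - params$waterCenter)^2 / (2 * 26^2))
  s <- continuum - chl - wat
  q <- c(colour_e = colourEValue(L, a, b), firmness = firmness, ssc = ssc)
  for (tgt in names(g$bands)) {
    z <- (q[[tgt]] - g$z_mu[[tgt]]) / g$z_sd[[tgt]]
    idx <- vapply(g$bands[[tgt]], function(w) which.min(abs(grid - w)),
                  integer(1))
    s[idx] <- s[idx] + z * g$amps[[tgt]]
  }
  s
}

#' Simulate reflectance spectra for a quality table
#'
#' One spectrum per fruit on the parameter grid: a smooth continuum
#' minus a chlorophyll Gaussian dip near 675 nm (depth decreasing with
#' a*) and a water dip near 980 nm, plus sparse band loadings carrying
#' each quality target, then per-sample multiplicative gain and additive
#' offset scatter and band-wise noise. Reflectance is clipped to
#' [0, 1.2].
#'
#' @param table a quality table (see [simulateQualityTable()]).
#' @param params a `SynthSpectraParams` list.
#' @param seed integer RNG seed.
#' @return A [SpectrumMatrix-class] tagged `"raw"`.
#' @export
simulateSpectra <- function(table, params = synthSpectraParams(), seed = 1L) {
  .checkQualityTable(table)
  grid <- paramsGrid(params)
  set.seed(seed)
  n <- nrow(table)
  clean <- t(vapply(seq_len(n), function(i)
    .cleanSpectrum(grid, table$L[i], table$a[i], table$b[i],
                   table$firmness[i], table$ssc[i], params),
    numeric(params$nBands)))
  gain <- exp(stats::rnorm(n, 0, params$scatterGainSd))
  offset <- stats::rnorm(n, 0, params$scatterOffsetSd)
  noise <- matrix(stats::rnorm(n * params$nBands, 0, params$noiseSd),
                  n, params$nBands)
  vals <- clean * gain + offset + noise
  vals <- pmin(pmax(vals, 0), 1.2)
  SpectrumMatrix(vals, grid, sampleIds = table$sample_id,
                 preprocessing = "raw")
}

#' Simulate a small labelled hyperspectral scene
#'
#' Renders one fruit as an ellipse on a dark background: fruit pixels
#' carry the record's (noise-free) generating spectrum under mild radial
#' shading normalised to mean 1, so the mask-mean corrected spectrum
#' matches the generating spectrum up to noise. Returns raw, white and
#' dark cubes such that black/white correction recovers the reflectance,
#' plus the ground-truth mask.
#'
#' @param record one row of a quality table.
#' @param height,width scene size in pixels (>= 8).
#' @param seed integer RNG seed.
#' @param params a `SynthSpectraParams` list.
#' @return List with elements `raw`, `white`, `dark` ([SpectralCube-class]),
#'   `mask` ([FruitMask-class]) and `spectrum` (the generating spectrum).
#' @export
simulateScene <- function(record, height = 48L, width = 48L, seed = 1L,
                          params = synthSpectraParams()) {
  stopifnot(height >= 8L, width >= 8L, nrow(record) == 1L)
  grid <- paramsGrid(params)
  p <- params$nBands
  spec <- .cleanSpectrum(grid, record$L, record$a, record$b,
                         record$firmness, record$ssc, params)
  set.seed(seed)
  rr <- (row(matrix(0, height, width)) - (height + 1) / 2) / (0.38 * height)
  cc <- (col(matrix(0, height, width)) - (width + 1) / 2) / (0.34 * width)
  r2 <- rr^2 + cc^2
  mask <- r2 <= 1
  shade <- 1 + 0.06 * (1 - 2 * r2)
  shade[!mask] <- 0
  shade[mask] <- shade[mask] / mean(shade[mask])
  refl <- array(0.03, dim = c(height, width, p))
  for (k in seq_len(p)) {
    plane <- refl[, , k]
    plane[mask] <- spec[k] * shade[mask]
    refl[, , k] <- plane
  }
  Wlev <- 3200 + 800 * (grid - params$wlMin) / (params$wlMax - params$wlMin)
  Blev <- 96
  white <- array(rep(Wlev, each = height * width), dim = c(height, width, p))
  dark <- array(Blev, dim = c(height, width, p))
  noise <- array(stats::rnorm(height * width * p, 0, params$noiseSd),
                 dim = c(height, width, p))
  raw <- dark + (refl + noise) * (white - dark)
  list(raw = SpectralCube(raw, grid, "raw"),
       white = SpectralCube(white, grid, "white_ref"),
       dark = SpectralCube(dark, grid, "dark_ref"),
       mask = FruitMask(mask),
       spectrum = spec)
}
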