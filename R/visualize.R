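## Pixel-wise quality maps: deviation compression, per-pixel
## prediction, pseudo-colour rendering.

#' Compress pixel spectra toward the fruit mean
#'
#' For each fruit pixel spectrum p and the mask-mean spectrum m,
#' replaces p by m + c (p - m). Curvature of the fruit surface makes
#' pixel spectra within one fruit vary strongly; shrinking the
#' deviations (c < 1) suppresses that variation so pixel-wise maps
#' reflect overall fruit quality. c = 1 is the identity, c = 0 maps
#' every fruit pixel to the mean spectrum; the mask-mean spectrum is
#' preserved for every c. Background pixels are untouched.
#'
#' @param cube a reflectance [SpectralCube-class].
#' @param mask a [FruitMask-class].
#' @param c compression factor in [0, 1].
#' @return A [SpectralCube-class] of kind `"reflectance"`.
#' @export
compressPixels <- function(cube, mask, c = 0.5) {
  stopifnot(methods::is(cube, "SpectralCube"), methods::is(mask, "FruitMask"))
  if (cube@kind != "reflectance")
    stop("compressPixels expects a reflectance cube")
  if (!(c >= 0 && c <= 1)) stop("compression factor must be in [0, 1]")
  m <- mask@mask
  vals <- cube@values
  for (k in seq_len(dim(vals)[3])) {
    plane <- vals[, , k]
    mu <- mean(plane[m])
    plane[m] <- mu + c * (plane[m] - mu)
    vals[, , k] <- plane
  }
  SpectralCube(vals, cube@wavelength, "reflectance")
}

#' Pixel-wise quality prediction map
#'
#' Applies deviation compression, then evaluates a fitted linear model
#' at its bands for every fruit pixel. If the model carries an `"snv"`
#' preprocessing tag, SNV is applied to each (compressed) pixel
#' spectrum before prediction. Model wavelengths are resolved onto the
#' cube grid by nearest band (erroring when off by more than half the
#' band spacing).
#'
#' @param cube a reflectance [SpectralCube-class].
#' @param mask a [FruitMask-class].
#' @param model a [RegressionModel-class].
#' @param c compression factor in [0, 1].
#' @param target map label; defaults from the model when resolvable.
#' @param colourScale length-2 (min, max) rendering scale; defaults to
#'   the observed prediction range padded by 5%.
#' @return A [PredictionMap-class].
#' @export
predictMap <- function(cube, mask, model, c = 0.5,
                       target = c("colour_e", "firmness", "ssc"),
                       colourScale = NULL) {
  target <- match.arg(target)
  stopifnot(methods::is(model, "RegressionModel"))
  comp <- compressPixels(cube, mask, c)
  px <- pixelSpectra(comp, mask)
  idx <- wavelengthToIndex(cube@wavelength, model@wavelength)
  X <- px@values
  if (model@preprocessing == "snv") X <- snv(X)
  preds <- predict(model, X[, idx, drop = FALSE])
  vals <- matrix(NA_real_, nrow(mask@mask), ncol(mask@mask))
  vals[mask@mask] <- preds
  if (is.null(colourScale)) {
    rng <- range(preds)
    pad <- max(diff(rng), 1e-6) * 0.05
    colourScale <- c(rng[1] - pad, rng[2] + pad)
  }
  methods::new("PredictionMap", values = vals, mask = mask,
               target = target, colourScale = as.numeric(colourScale),
               compression = c)
}

#' Render a prediction map as a pseudo-colour PNG
#'
#' Fruit pixels are mapped linearly from the colour scale onto the
#' palette; background is rendered neutral grey. A sidecar JSON
#' (`<path>.json`) records the target, colour scale and compression
#' factor, standing in for a colour bar.
#'
#' @param map a [PredictionMap-class].
#' @param path output PNG path.
#' @param palette vector of colours (default: 256-step viridis).
#' @param background background RGB in [0, 1].
#' @return Invisibly, `path`.
#' @export
renderPseudocolour <- function(map, path,
                               palette = grDevices::hcl.colors(256,
                                                               "viridis"),
                               background = c(0.85, 0.85, 0.85)) {
  cs <- map@colourScale
  if (!(cs[1] < cs[2])) stop("degenerate colour scale")
  d <- dim(map@values)
  img <- array(rep(background, each = prod(d)), dim = c(d, 3))
  m <- map@mask@mask
  frac <- (map@values[m] - cs[1]) / (cs[2] - cs[1])
  frac <- pmin(pmax(frac, 0), 1)
  ci <- pmin(1L + as.integer(frac * (length(palette) - 1) + 0.5),
             length(palette))
  rgb <- grDevices::col2rgb(palette[ci]) / 255
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[m] <- rgb[ch, ]
    img[, , ch] <- plane
  }
  png::writePNG(img, path)
  jsonlite::write_json(list(target = map@target,
                            colour_scale = map@colourScale,
                            compression = map@compression),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
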