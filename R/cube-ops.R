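## Cube-level operations: black/white reflectance correction, fruit
## segmentation and spectrum extraction.

#' Black/white reflectance correction
#'
#' Corrects a raw cube against white and dark reference cubes,
#' I = (I0 - B) / (W - B) elementwise, removing sensor dark current and
#' illumination non-uniformity. Negative corrected values (raw below
#' dark, sensor noise) are clipped to 0; the clipped-voxel count is
#' reported via a message.
#'
#' @param raw,white,dark [SpectralCube-class] objects sharing shape and
#'   wavelength grid.
#' @return A [SpectralCube-class] of kind `"reflectance"`.
#' @export
correctReflectance <- function(raw, white, dark) {
  stopifnot(methods::is(raw, "SpectralCube"),
            methods::is(white, "SpectralCube"),
            methods::is(dark, "SpectralCube"))
  if (!all(dim(raw@values) == dim(white@values)) ||
      !all(dim(raw@values) == dim(dark@values)))
    stop("correctReflectance: cubes must share dimensions")
  if (max(abs(raw@wavelength - white@wavelength)) > 1e-6 ||
      max(abs(raw@wavelength - dark@wavelength)) > 1e-6)
    stop("correctReflectance: cubes must share the wavelength grid")
  denom <- white@values - dark@values
  bad <- which(denom <= 0)
  if (length(bad)) {
    loc <- arrayInd(bad[1], dim(denom))
    stop(sprintf(
      "degenerate reference: white <= dark at (row %d, col %d, band %d)%s",
      loc[1], loc[2], loc[3],
      if (length(bad) > 1) sprintf(" and %d more voxels", length(bad) - 1)
      else ""))
  }
  vals <- (raw@values - dark@values) / denom
  nneg <- sum(vals < 0)
  if (nneg > 0) {
    message("correctReflectance: clipped ", nneg, " negative voxels to 0")
    vals[vals < 0] <- 0
  }
  SpectralCube(vals, raw@wavelength, "reflectance")
}

#' Segment the fruit from the background
#'
#' Thresholds the mean reflectance over a high-contrast near-infrared
#' window (default 750-850 nm, where fruit is bright and background
#' dark) by Otsu's criterion, fills holes and retains connected
#' components of at least `minArea` pixels. Deterministic.
#'
#' @param cube a reflectance [SpectralCube-class].
#' @param window length-2 wavelength window (nm) averaged for contrast.
#' @param minArea smallest component (pixels) kept.
#' @return A [FruitMask-class].
#' @export
segmentFruit <- function(cube, window = c(750, 850), minArea = 16L) {
  stopifnot(methods::is(cube, "SpectralCube"))
  if (cube@kind != "reflectance")
    stop("segmentFruit expects a reflectance cube")
  inWin <- cube@wavelength >= window[1] & cube@wavelength <= window[2]
  if (!any(inWin)) stop("no bands inside the contrast window")
  img <- apply(cube@values[, , inWin, drop = FALSE], c(1, 2), mean)
  rng <- range(img)
  if (diff(rng) < 1e-9)
    stop("segmentation failed: image has no contrast")
  thr <- EBImage::otsu(img, range = rng)
  fg <- img > thr
  if (!any(fg)) stop("segmentation failed: empty foreground")
  fg <- EBImage::fillHull(fg) > 0
  lab <- EBImage::bwlabel(fg)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= minArea)
  mask <- matrix(lab %in% keep & lab > 0, nrow(img), ncol(img))
  if (!any(mask))
    stop("segmentation failed: no component of at least ", minArea,
         " pixels")
  FruitMask(mask)
}

#' Mean spectrum over a fruit mask
#'
#' @param cube a [SpectralCube-class].
#' @param mask a [FruitMask-class] matching the cube's spatial shape.
#' @return Numeric vector, one value per band.
#' @export
meanSpectrum <- function(cube, mask) {
  stopifnot(methods::is(cube, "SpectralCube"), methods::is(mask, "FruitMask"))
  m <- mask@mask
  if (!all(dim(m) == dim(cube@values)[1:2]))
    stop("mask shape does not match cube")
  if (!any(m)) stop("empty mask")
  apply(cube@values, 3, function(plane) mean(plane[m]))
}

#' Extract per-pixel spectra under a mask
#'
#' @inheritParams meanSpectrum
#' @return A [SpectrumMatrix-class] with one row per fruit pixel, ids
#'   `px_<row>_<col>`.
#' @export
pixelSpectra <- function(cube, mask) {
  stopifnot(methods::is(cube, "SpectralCube"), methods::is(mask, "FruitMask"))
  m <- mask@mask
  if (!all(dim(m) == dim(cube@values)[1:2]))
    stop("mask shape does not match cube")
  idx <- which(m, arr.ind = TRUE)
  p <- dim(cube@values)[3]
  mat <- matrix(NA_real_, nrow(idx), p)
  for (k in seq_len(p)) mat[, k] <- cube@values[, , k][m]
  SpectrumMatrix(mat, cube@wavelength,
                 sampleIds = sprintf("px_%d_%d", idx[, 1], idx[, 2]),
                 preprocessing = "raw")
}

#' Write / read a fruit mask as PNG
#'
#' Masks are stored as 8-bit grayscale PNG with fruit = 255 and
#' background = 0, and reload losslessly.
#'
#' @param mask a [FruitMask-class].
#' @param path PNG file path.
#' @return `readMaskPNG` returns a [FruitMask-class].
#' @export
writeMaskPNG <- function(mask, path) {
  png::writePNG(mask@mask * 1, path)
  invisible(path)
}

#' @rdname writeMaskPNG
#' @export
readMaskPNG <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  FruitMask(img > 0.5)
}
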