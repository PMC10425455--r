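makeCube <- function(seed = 1, d = c(4, 5, 6), quantised = TRUE) {
  set.seed(seed)
  v <- array(runif(prod(d)), d)
  # float32-representable values so float32 round trips are bit-exact
  if (quantised) v <- round(v * 1024) / 1024
  SpectralCube(v, seq(400, 900, length.out = d[3]))
}

test_that("ENVI cubes round-trip bit-exactly in all interleaves", {
  cube <- makeCube()
  for (il in c("BSQ", "BIL", "BIP")) {
    p <- tempfile()
    writeENVI(cube, p, interleave = il)
    back <- readENVI(paste0(p, ".hdr"))
    expect_identical(back@values, cube@values)
    expect_equal(back@wavelength, cube@wavelength, tolerance = 1e-6)
  }
})

test_that("ENVI uint16 dialect round-trips integer counts", {
  cube <- SpectralCube(array(sample(0:65535, 60), c(4, 5, 3)),
                       c(400, 500, 600))
  p <- tempfile()
  writeENVI(cube, p, interleave = "BIL", dataType = 12L)
  back <- readENVI(paste0(p, ".hdr"))
  expect_identical(back@values, cube@values)
})

test_that("ENVI format errors are explicit", {
  cube <- makeCube()
  p <- tempfile()
  hdr <- writeENVI(cube, p)
  # header bands inconsistent with binary size
  txt <- readLines(hdr)
  txt[grepl("^bands", txt)] <- "bands = 10"
  txt[grepl("^wavelength", txt)] <- paste0(
    "wavelength = {", paste(1:10 * 100, collapse = ", "), "}")
  writeLines(txt, hdr)
  expect_error(readENVI(hdr), "size")
  # missing binary
  hdr2 <- paste0(tempfile(), ".hdr")
  file.copy(paste0(p, ".hdr"), hdr2)
  expect_error(readENVI(hdr2), "binary not found")
  # unsupported data type
  writeENVI(cube, p)
  txt <- readLines(hdr)
  txt[grepl("^data type", txt)] <- "data type = 5"
  writeLines(txt, hdr)
  expect_error(readENVI(hdr), "data type")
})

test_that("reflectance correction handles the canonical reference cases", {
  w <- makeCube(2); d <- makeCube(3)
  d@values <- d@values * 0.1
  w@values <- w@values + 1          # ensure white > dark everywhere
  half <- SpectralCube((w@values + d@values) / 2, w@wavelength)
  expect_equal(max(abs(correctReflectance(w, w, d)@values - 1)), 0)
  expect_equal(max(abs(correctReflectance(d, w, d)@values)), 0)
  expect_equal(max(abs(correctReflectance(half, w, d)@values - 0.5)), 0,
               tolerance = 1e-12)
  # gain invariance: scaling all three cubes leaves the result unchanged
  g <- 3.7
  scaled <- function(cb) SpectralCube(cb@values * g, cb@wavelength, cb@kind)
  expect_equal(correctReflectance(scaled(half), scaled(w), scaled(d))@values,
               correctReflectance(half, w, d)@values, tolerance = 1e-12)
  # degenerate reference reports a location
  wbad <- w; wbad@values[2, 3, 1] <- d@values[2, 3, 1]
  expect_error(correctReflectance(half, wbad, d), "row 2, col 3, band 1")
})

test_that("fruit segmentation recovers the true mask on synthetic scenes", {
  sc <- sceneFixture()
  refl <- correctReflectance(sc$raw, sc$white, sc$dark)
  seg <- segmentFruit(refl)
  jac <- sum(seg@mask & sc$mask@mask) / sum(seg@mask | sc$mask@mask)
  expect_gte(jac, 0.95)
  expect_equal(pixelCount(seg), sum(seg@mask))
  # idempotence: zeroing the background does not change the mask
  zeroed <- refl
  for (k in seq_len(dim(zeroed@values)[3])) {
    plane <- zeroed@values[, , k]
    plane[!seg@mask] <- 0
    zeroed@values[, , k] <- plane
  }
  expect_identical(segmentFruit(zeroed)@mask, seg@mask)
})

test_that("uniform cubes cannot be segmented", {
  flat <- SpectralCube(array(0.5, c(16, 16, 4)),
                       c(700, 780, 820, 900), kind = "reflectance")
  expect_error(segmentFruit(flat), "segmentation failed")
})

test_that("mean spectrum averages masked pixels per band", {
  cube <- makeCube(5, d = c(6, 6, 4))
  cube@kind <- "reflectance"
  m <- matrix(FALSE, 6, 6); m[2, 3] <- TRUE
  expect_equal(meanSpectrum(cube, FruitMask(m)), cube@values[2, 3, ])
  # two pixels with spectra s and -s + 2c average to c
  ctr <- c(0.4, 0.5, 0.6, 0.7)
  cube2 <- cube
  s <- cube2@values[1, 1, ]
  cube2@values[1, 2, ] <- -s + 2 * ctr
  m2 <- matrix(FALSE, 6, 6); m2[1, 1:2] <- TRUE
  expect_equal(meanSpectrum(cube2, FruitMask(m2)), ctr, tolerance = 1e-12)
  expect_error(meanSpectrum(cube, FruitMask(matrix(TRUE, 2, 2))), "shape")
})

test_that("masks round-trip through PNG", {
  sc <- sceneFixture()
  p <- tempfile(fileext = ".png")
  writeMaskPNG(sc$mask, p)
  expect_identical(readMaskPNG(p)@mask, sc$mask@mask)
})
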