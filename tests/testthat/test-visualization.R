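test_that("deviation compression interpolates between pixel and mean spectra", {
  sc <- sceneFixture()
  refl <- correctReflectance(sc$raw, sc$white, sc$dark)
  m <- sc$mask
  ident <- compressPixels(refl, m, 1)
  expect_equal(ident@values, refl@values, tolerance = 1e-12)
  flat <- compressPixels(refl, m, 0)
  mu <- meanSpectrum(refl, m)
  px <- spectraValues(pixelSpectra(flat, m))
  expect_equal(px, matrix(rep(mu, each = nrow(px)), nrow(px)),
               tolerance = 1e-12, ignore_attr = TRUE)
  # the mask-mean spectrum is preserved for every c
  for (cc in c(0.25, 0.5, 0.8))
    expect_equal(meanSpectrum(compressPixels(refl, m, cc), m), mu,
                 tolerance = 1e-12)
  expect_error(compressPixels(refl, m, 1.5), "\\[0, 1\\]")
})

test_that("pixel-wise maps obey the linearity identity for linear models", {
  sc <- sceneFixture()
  refl <- correctReflectance(sc$raw, sc$white, sc$dark)
  model <- referenceRegressionModel("ssc", wavelengths(refl))
  map1 <- predictMap(refl, sc$mask, model, c = 1, target = "ssc")
  mu <- meanSpectrum(refl, sc$mask)
  idx <- wavelengthToIndex(wavelengths(refl), model@wavelength)
  muPred <- unname(predict(model, matrix(mu[idx], 1)))
  expect_equal(mean(map1@values[sc$mask@mask]), muPred, tolerance = 1e-8)
  # c = 0 collapses the map to the mean-spectrum prediction
  map0 <- predictMap(refl, sc$mask, model, c = 0, target = "ssc")
  expect_equal(max(abs(map0@values[sc$mask@mask] - muPred)), 0,
               tolerance = 1e-9)
  # compression shrinks the prediction variance monotonically
  vr <- vapply(c(0.2, 0.5, 1), function(cc)
    var(predictMap(refl, sc$mask, model, cc,
                   target = "ssc")@values[sc$mask@mask]), numeric(1))
  expect_true(all(diff(vr) >= 0))
})

test_that("a generator-truth model recovers the record's quality per pixel", {
  # calibrate an MLR on scatter-free synthetic reflectance at the true
  # SSC bands, then predict a scene of a known record pixel by pixel.
  # A touch of noise keeps the sparse-band design full rank.
  params <- synthSpectraParams(scatterGainSd = 0, scatterOffsetSd = 0,
                               noiseSd = 0.002)
  tab <- simulateQualityTable(80, seed = 21)
  spec <- simulateSpectra(tab, params, seed = 22)
  b <- generatorBands(params, "ssc")
  truthModel <- fitRegression("MLR", spectraValues(spec), tab$ssc,
                              bands = b, wavelength = wavelengths(spec))
  sc <- sceneFixture()
  refl <- correctReflectance(sc$raw, sc$white, sc$dark)
  map <- predictMap(refl, sc$mask, truthModel, c = 0, target = "ssc")
  expect_lt(max(abs(map@values[sc$mask@mask] - sc$record$ssc)), 0.15)
})

test_that("maps of riper stages order as the quality trends dictate", {
  params <- synthSpectraParams()
  tab <- simulateQualityTable(60, c(1, 1, 1) / 3, seed = 31)
  spec <- simulateSpectra(tab, params, seed = 32)
  ms <- list()
  for (st in c("I", "II", "III")) {
    # representative fruit: the stage's median-firmness record
    sub <- tab[tab$stage == st, ]
    rec <- sub[which.min(abs(sub$firmness - median(sub$firmness))), ]
    sc <- simulateScene(rec, 32, 32, seed = 33, params = params)
    refl <- correctReflectance(sc$raw, sc$white, sc$dark)
    ms[[st]] <- refl
    attr(ms[[st]], "mask") <- sc$mask
    attr(ms[[st]], "rec") <- rec
  }
  b <- generatorBands(params, "firmness")
  quiet <- synthSpectraParams(scatterGainSd = 0, scatterOffsetSd = 0,
                              noiseSd = 0.002)
  calTab <- simulateQualityTable(80, seed = 34)
  calSpec <- simulateSpectra(calTab, quiet, seed = 35)
  firmModel <- fitRegression("MLR", spectraValues(calSpec),
                             calTab$firmness, bands = b,
                             wavelength = wavelengths(calSpec))
  means <- vapply(ms, function(r)
    mean(predictMap(r, attr(r, "mask"), firmModel, 0.5,
                    target = "firmness")@values[attr(r, "mask")@mask]),
    numeric(1))
  expect_true(means[["I"]] > means[["II"]] && means[["II"]] > means[["III"]])
})

test_that("pseudo-colour rendering respects the palette and silhouette", {
  sc <- sceneFixture()
  refl <- correctReflectance(sc$raw, sc$white, sc$dark)
  model <- referenceRegressionModel("ssc", wavelengths(refl))
  map <- predictMap(refl, sc$mask, model, 0.5, target = "ssc")
  pal <- grDevices::hcl.colors(11, "viridis")
  p <- tempfile(fileext = ".png")
  renderPseudocolour(map, p, palette = pal)
  img <- png::readPNG(p)
  # silhouette preserved: background grey exactly where the mask is FALSE
  grey <- img[, , 1] == img[, , 2] & img[, , 2] == img[, , 3]
  bgOnly <- !sc$mask@mask
  expect_true(all(grey[bgOnly]))
  expect_true(file.exists(paste0(p, ".json")))
  # uniform map renders a single fruit colour, the palette midpoint
  uni <- map
  uni@values[sc$mask@mask] <- mean(map@colourScale)
  renderPseudocolour(uni, p, palette = pal)
  img2 <- png::readPNG(p)
  mid <- grDevices::col2rgb(pal[6]) / 255
  fruitCols <- cbind(img2[, , 1][sc$mask@mask], img2[, , 2][sc$mask@mask],
                     img2[, , 3][sc$mask@mask])
  expect_lt(max(abs(sweep(fruitCols, 2, c(mid)))), 0.01)
  # degenerate colour scale rejected
  bad <- map
  bad@colourScale <- c(1, 1)
  expect_error(renderPseudocolour(bad, p), "degenerate")
})
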