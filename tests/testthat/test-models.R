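test_that("MLR recovers exact linear relations and flags deficiencies", {
  set.seed(1)
  X <- matrix(rnorm(30 * 6), 30)
  y <- 2 * X[, 3] + 1
  m <- fitRegression("MLR", X, y, bands = 3L)
  expect_equal(m@parameters$coefficients, 2, tolerance = 1e-8)
  expect_equal(m@parameters$intercept, 1, tolerance = 1e-8,
               ignore_attr = TRUE)
  # too many bands for the sample count
  expect_error(fitRegression("MLR", X[1:5, ], y[1:5], bands = 1:5),
               "fewer bands")
  # exact duplicate band makes the design rank deficient
  Xd <- cbind(X, X[, 1])
  expect_error(fitRegression("MLR", Xd, y, bands = c(1L, 7L)),
               "rank deficient")
})

test_that("PLSR achieves exact recovery on rank-1 noiseless data", {
  set.seed(2)
  t1 <- rnorm(25)
  X <- outer(t1, rnorm(8))
  y <- 3 * t1 + 2
  m <- fitRegression("PLSR", X, y, hyper = list(maxComp = 3), seed = 1)
  expect_lt(sqrt(mean((predict(m, X) - y)^2)), 1e-6)
})

test_that("PLSR and PCR with full components equal MLR at full rank", {
  set.seed(3)
  X <- matrix(rnorm(20 * 5), 20)
  y <- drop(X %*% c(1, -2, 0.5, 3, -1)) + 0.3 + rnorm(20, 0, 0.05)
  mlr <- fitRegression("MLR", X, y)
  fit <- loquatHSI:::.plsFit(X, y, 5L)
  plsPred <- drop(X %*% fit$B[, 1, 5] + fit$intercept[1, 5])
  expect_equal(plsPred, predict(mlr, X), tolerance = 1e-6)
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  cf <- lm.fit(cbind(1, pc$x), y)$coefficients
  beta <- pc$rotation %*% cf[-1]
  pcrPred <- drop(X %*% beta) + cf[1] - drop(pc$center %*% beta)
  expect_equal(pcrPred, predict(mlr, X), tolerance = 1e-6)
})

test_that("the internal PLS engine matches an independent implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(4)
  X <- matrix(rnorm(40 * 10), 40,
              dimnames = list(NULL, paste0("b", 1:10)))
  y <- drop(X %*% rnorm(10)) + rnorm(40, 0, 0.1)
  fit <- loquatHSI:::.plsFit(X, y, 4L)
  ours <- drop(X %*% fit$B[, 1, 4] + fit$intercept[1, 4])
  ref <- mixOmics::pls(X, y, ncomp = 4, scale = FALSE, mode = "regression")
  theirs <- unname(drop(predict(ref, X)$predict[, 1, 4]))
  expect_equal(ours, theirs, tolerance = 1e-6)
})

test_that("ELM with linear activation and identity hidden weights is least squares", {
  set.seed(5)
  X <- matrix(rnorm(40 * 4), 40)
  y <- drop(X %*% c(2, -1, 0.5, 1)) + 1 + rnorm(40, 0, 0.01)
  W <- rbind(0, diag(4))       # bias row 0, identity on inputs
  elm <- fitRegression("ELM", X, y,
                       hyper = list(activation = "linear",
                                    hiddenWeights = W), seed = 1)
  mlr <- fitRegression("MLR", X, y)
  expect_equal(predict(elm, X), predict(mlr, X), tolerance = 1e-6)
})

test_that("stochastic families are deterministic under a seed and fit the signal", {
  fx <- synthFixture()
  params <- fx$params
  b <- generatorBands(params, "ssc")
  X <- spectraValues(fx$snv)
  y <- fx$table$ssc
  e1 <- fitRegression("ELM", X, y, bands = b, seed = 7)
  e2 <- fitRegression("ELM", X, y, bands = b, seed = 7)
  expect_identical(predict(e1, X), predict(e2, X))
  expect_gt(cor(predict(e1, X), y)^2, 0.9)
  b1 <- fitRegression("BP", X, y, bands = b, seed = 7)
  b2 <- fitRegression("BP", X, y, bands = b, seed = 7)
  expect_identical(predict(b1, X), predict(b2, X))
  expect_gt(cor(predict(b1, X), y)^2, 0.9)
})

test_that("prediction enforces the band and preprocessing contracts", {
  set.seed(6)
  X <- matrix(rnorm(30 * 6), 30)
  y <- rnorm(30)
  m <- fitRegression("MLR", X, y, bands = c(2L, 4L))
  expect_equal(predict(m, X), predict(m, X[, c(2, 4)]))
  expect_error(predict(m, X[, 1, drop = FALSE]), "bands")
  sm <- SpectrumMatrix(X[, c(2, 4)], c(500, 600), preprocessing = "snv")
  expect_error(predict(m, sm), "preprocessing mismatch")
  # affine in the inputs (linear family)
  p1 <- predict(m, X)
  p2 <- predict(m, 2 * X)
  p3 <- predict(m, 3 * X)
  expect_equal(p3 - p2, p2 - p1, tolerance = 1e-10)
})

test_that("models serialise to JSON and reproduce predictions", {
  set.seed(7)
  X <- matrix(rnorm(30 * 5), 30)
  y <- rnorm(30)
  m <- fitRegression("MLR", X, y, bands = c(1L, 3L, 5L))
  p <- tempfile(fileext = ".json")
  writeModelJSON(m, p)
  back <- readModelJSON(p)
  expect_identical(predict(back, X), predict(m, X))
  expect_identical(back@bandIndices, m@bandIndices)
})

test_that("evaluation reproduces the defined metrics and tiers", {
  set.seed(8)
  yc <- rnorm(20); yp <- rnorm(10)
  # constant offset on predictions: RMSEP equals |d|
  rep1 <- evaluateRegression(yc, yc + 0.3, yp, yp + 0.5)
  expect_equal(rep1@rmsec, 0.3, tolerance = 1e-12)
  expect_equal(rep1@rmsep, 0.5, tolerance = 1e-12)
  expect_equal(rep1@rpd, sd(yp) / 0.5, tolerance = 1e-12)
  # translation invariance
  rep2 <- evaluateRegression(yc + 10, yc + 10.3, yp + 10, yp + 10.5)
  expect_equal(rep2@r2P, rep1@r2P, tolerance = 1e-12)
  expect_equal(rep2@rmsep, rep1@rmsep, tolerance = 1e-12)
  expect_equal(rep2@rpd, rep1@rpd, tolerance = 1e-12)
  # perfect predictions leave RPD undefined
  expect_error(evaluateRegression(yc, yc, yp, yp), "RPD undefined")
  # tier thresholds
  expect_equal(rpdTierOf(1.2), "poor")
  expect_equal(rpdTierOf(1.7), "moderate")
  expect_equal(rpdTierOf(2.5), "good")
  expect_equal(rpdTierOf(2.81), "excellent")
})

test_that("reference CARS-MLR equations match their independent transcription", {
  path <- system.file("extdata", "reference_mlr_models.json",
                      package = "loquatHSI")
  j <- jsonlite::fromJSON(path)
  for (tgt in c("colour_e", "firmness", "ssc")) {
    m <- referenceModel(tgt)
    expect_equal(m$intercept, j[[tgt]]$intercept)
    expect_equal(m$wavelengths, as.numeric(names(j[[tgt]]$terms)))
    expect_equal(m$coefficients, unname(unlist(j[[tgt]]$terms)))
    # linear-form agreement on random reflectances
    set.seed(9)
    r <- runif(length(m$coefficients))
    expect_equal(predictReference(tgt, r),
                 j[[tgt]]$intercept + sum(unlist(j[[tgt]]$terms) * r),
                 tolerance = 1e-12)
  }
  expect_error(predictReference("ssc", rep(0, 5)), "18")
})

test_that("reference models bind onto a measurement grid", {
  grid <- seq(390, 1030, length.out = 256)
  m <- referenceRegressionModel("colour_e", grid)
  expect_s4_class(m, "RegressionModel")
  expect_length(bandIndices(m), 20)
  # zero reflectance at the model bands returns the intercept
  X <- matrix(0, 1, 20)
  expect_equal(unname(predict(m, X)), 22.89)
})
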