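test_that("SNV centres and scales each spectrum and is idempotent", {
  expect_equal(drop(snv(matrix(c(1, 2, 3), 1))), c(-1, 0, 1))
  x <- matrix(rnorm(5 * 20), 5)
  z <- snv(x)
  expect_equal(rowMeans(z), rep(0, 5), tolerance = 1e-12)
  expect_equal(apply(z, 1, sd), rep(1, 5), tolerance = 1e-12)
  expect_equal(snv(z), z, tolerance = 1e-12)
  # scatter invariance: snv(a x + b) == snv(x) for a > 0
  expect_equal(snv(2.5 * x + 0.7), z, tolerance = 1e-12)
  bad <- matrix(c(1, 1, 1, 1, 2, 3), 2, byrow = TRUE,
                dimnames = list(c("flat", "ok"), NULL))
  expect_error(snv(bad), "flat")
})

test_that("SNV on a SpectrumMatrix retags the preprocessing", {
  fx <- synthFixture()
  expect_equal(preprocessingTag(fx$raw), "raw")
  expect_equal(preprocessingTag(fx$snv), "snv")
  expect_identical(sampleIds(fx$snv), sampleIds(fx$raw))
})

test_that("SPXY reproduces the 3:1 calibration/prediction sizes", {
  set.seed(1)
  X <- matrix(rnorm(140 * 12), 140); y <- rnorm(140)
  s <- spxySplit(X, y, 0.75)
  expect_equal(length(s@calIndices), 105)
  expect_equal(length(s@predIndices), 35)
  X2 <- matrix(rnorm(120 * 12), 120); y2 <- rnorm(120)
  s2 <- spxySplit(X2, y2, 0.75)
  expect_equal(length(s2@calIndices), 90)
  expect_equal(length(s2@predIndices), 30)
  expect_error(spxySplit(X, y, 1.2), "calFraction")
})

test_that("SPXY seeds from the pair at maximal joint distance", {
  set.seed(4)
  X <- matrix(rnorm(30 * 6), 30); y <- rnorm(30)
  Dx <- as.matrix(dist(X))
  Dy <- as.matrix(dist(scale(y)))
  D <- Dx / max(Dx) + Dy / max(Dy)
  pair <- arrayInd(which.max(D), dim(D))
  s <- spxySplit(X, y, 0.6)
  expect_true(all(c(pair) %in% s@calIndices))
})

test_that("SPXY calibration covers the response range", {
  fx <- synthFixture()
  y <- fx$table$ssc
  s <- spxySplit(fx$snv, y, 0.75)
  expect_true(which.min(y) %in% s@calIndices)
  expect_true(which.max(y) %in% s@calIndices)
})

test_that("stratified Kennard-Stone reproduces the 2:1 stage split sizes", {
  set.seed(2)
  lab <- rep(c("I", "II", "III"), c(60, 150, 39))
  X <- matrix(rnorm(249 * 8), 249)
  s <- kennardStoneSplit(X, 2 / 3, labels = lab)
  expect_equal(length(s@calIndices), 166)
  expect_equal(length(s@predIndices), 83)
  # per-class sizes are round(2/3 class size)
  expect_equal(unname(table(lab[s@calIndices])), c(40, 100, 26),
               ignore_attr = TRUE)
  # n = 3 unstratified
  s3 <- kennardStoneSplit(matrix(rnorm(9), 3), 2 / 3)
  expect_equal(length(s3@calIndices), 2)
  expect_error(kennardStoneSplit(X, 2 / 3,
                                 labels = c("solo", lab[-1])),
               "solo")
})

test_that("splits are deterministic and calibration spans the data", {
  set.seed(3)
  X <- matrix(rnorm(40 * 5), 40); y <- rnorm(40)
  expect_identical(spxySplit(X, y, 0.7)@calIndices,
                   spxySplit(X, y, 0.7)@calIndices)
  expect_identical(kennardStoneSplit(X, 0.7)@calIndices,
                   kennardStoneSplit(X, 0.7)@calIndices)
  # 1-D exhaustive: calibration convex hull contains the prediction hull
  x1 <- matrix(seq(0, 1, length.out = 10)^2, ncol = 1)
  ks <- kennardStoneSplit(x1, 0.6)
  expect_gte(diff(range(x1[ks@calIndices])), diff(range(x1[ks@predIndices])))
  expect_true(min(x1) >= min(x1[ks@calIndices]) &&
              max(x1) <= max(x1[ks@calIndices]))
})

test_that("splits serialise as sample/set CSV", {
  set.seed(5)
  X <- matrix(rnorm(20 * 3), 20)
  s <- kennardStoneSplit(X, 0.5)
  p <- tempfile(fileext = ".csv")
  writeSplitCSV(s, sprintf("s%02d", 1:20), p)
  back <- utils::read.csv(p)
  expect_equal(sum(back$set == "cal"), length(s@calIndices))
  expect_equal(which(back$set == "cal"), s@calIndices)
})
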