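# Fixture task: 200 SNV spectra whose SSC signal lives in 5 known bands.

test_that("CARS runs the configured number of Monte-Carlo iterations", {
  fx <- synthFixture()
  sel <- carsSelect(spectraValues(fx$snv), fx$table$ssc,
                    carsConfig(seed = 5), wavelength = wavelengths(fx$snv))
  expect_equal(length(sel@rmsecvTrace), 50)
  expect_equal(sel@method, "CARS")
  # retained-band counts decay monotonically
  expect_true(all(diff(sel@nRetained) <= 0))
  # winning iteration sits at the trace minimum
  expect_equal(sel@rmsecvTrace[sel@winningIteration],
               min(sel@rmsecvTrace, na.rm = TRUE))
  # subsets are strict subsets of the full grid
  expect_lt(length(bandIndices(sel)), ncol(spectraValues(fx$snv)))
})

test_that("CARS recovers the generator's informative bands", {
  fx <- synthFixture()
  truth <- generatorBands(fx$params, "ssc")
  sel <- carsSelect(spectraValues(fx$snv), fx$table$ssc,
                    carsConfig(seed = 11), wavelength = wavelengths(fx$snv))
  expect_gte(sum(truth %in% bandIndices(sel)), 4)
})

test_that("CARS is invariant to permuting the sample order", {
  fx <- synthFixture()
  X <- spectraValues(fx$snv); y <- fx$table$ssc
  set.seed(99); perm <- sample(nrow(X))
  s1 <- carsSelect(X, y, carsConfig(seed = 3), wavelength = wavelengths(fx$snv))
  s2 <- carsSelect(X[perm, ], y[perm], carsConfig(seed = 3),
                   wavelength = wavelengths(fx$snv))
  expect_identical(bandIndices(s1), bandIndices(s2))
})

test_that("GA is reproducible, monotone in best-ever fitness, and beats the full spectrum", {
  fx <- synthFixture()
  X <- spectraValues(fx$snv); y <- fx$table$ssc
  w <- wavelengths(fx$snv)
  cfg <- gaConfig(generations = 10L, seed = 4)
  g1 <- gaSelect(X, y, cfg, wavelength = w)
  g2 <- gaSelect(X, y, cfg, wavelength = w)
  expect_identical(bandIndices(g1), bandIndices(g2))
  expect_identical(g1@rmsecvTrace, g2@rmsecvTrace)
  # best-ever RMSECV can only improve
  expect_true(all(diff(g1@rmsecvTrace) <= 1e-12))
  # selected subset predicts at least as well as the full spectrum
  folds <- rep_len(1:5, length(y))
  cvr <- function(bands) {
    pr <- numeric(length(y))
    for (f in 1:5) {
      tr <- folds != f
      m <- fitRegression("PLSR", X[tr, bands, drop = FALSE], y[tr],
                         hyper = list(maxComp = 10), seed = 1)
      pr[!tr] <- predict(m, X[!tr, bands, drop = FALSE])
    }
    sqrt(mean((y - pr)^2))
  }
  expect_lte(cvr(bandIndices(g1)), cvr(seq_len(ncol(X))))
})

test_that("SPA chains follow the maximal-orthogonal-projection rule", {
  # orthogonal columns with distinct norms: picks descend by norm
  Q <- qr.Q(qr(matrix(rnorm(64), 8)))[, 1:6]
  X <- Q %*% diag(c(5, 3, 6, 1, 4, 2))
  chain <- loquatHSI:::.spaChain(X, start = 4L, maxVars = 4L)
  expect_equal(chain[1], 4L)         # forced start
  expect_equal(chain[2], 3L)         # largest remaining norm (6)
  expect_equal(chain[3], 1L)         # then 5
  # brute-force oracle on a general 6-band matrix
  set.seed(8)
  Xg <- matrix(rnorm(12 * 6), 12)
  bf <- function(start, k) {
    sel <- start
    for (i in seq_len(k - 1)) {
      rest <- setdiff(1:6, sel)
      resid <- vapply(rest, function(j) {
        fit <- lm.fit(Xg[, sel, drop = FALSE], Xg[, j])
        sqrt(sum(fit$residuals^2))
      }, numeric(1))
      sel <- c(sel, rest[which.max(resid)])
    }
    sel
  }
  for (start in 1:6)
    expect_equal(loquatHSI:::.spaChain(Xg, start, 4L), bf(start, 4L))
  # a duplicated column is never co-selected with its twin
  Xd <- cbind(Xg, Xg[, 2])
  for (start in c(2L, 7L)) {
    ch <- loquatHSI:::.spaChain(Xd, start, 5L)
    expect_false(all(c(2L, 7L) %in% ch))
  }
})

test_that("SPA selects a low-RMSE subset deterministically", {
  fx <- synthFixture()
  X <- spectraValues(fx$snv); y <- fx$table$ssc
  w <- wavelengths(fx$snv)
  s1 <- spaSelect(X, y, spaConfig(maxVars = 12), wavelength = w)
  expect_lt(length(bandIndices(s1)), ncol(X))
  # exact permutation invariance
  set.seed(42); perm <- sample(nrow(X))
  s2 <- spaSelect(X[perm, ], y[perm], spaConfig(maxVars = 12),
                  wavelength = w)
  expect_identical(bandIndices(s1), bandIndices(s2))
  expect_equal(s1@rmsecvTrace[s1@winningIteration],
               min(s1@rmsecvTrace, na.rm = TRUE))
})

test_that("wavelength-to-index mapping rejects off-grid values", {
  grid <- seq(390, 1030, length.out = 256)
  idx <- wavelengthToIndex(grid, c(397, 675, 993))
  expect_equal(grid[idx], c(397, 675, 993), tolerance = 2)
  expect_error(wavelengthToIndex(grid, 1100), "off-grid")
  expect_error(wavelengthToIndex(c(400, 500, 600), 700), "off-grid")
})

test_that("reference band subsets load with the published counts", {
  expect_length(referenceSelectedWavelengths("colour_e", "CARS"), 20)
  expect_length(referenceSelectedWavelengths("firmness", "CARS"), 29)
  expect_length(referenceSelectedWavelengths("ssc", "CARS"), 18)
  expect_length(referenceSelectedWavelengths("colour_e", "SPA"), 3)
  expect_length(referenceSelectedWavelengths("firmness", "GA"), 22)
  # every reference wavelength resolves onto the instrument grid
  grid <- seq(390, 1030, length.out = 256)
  for (tgt in c("colour_e", "firmness", "ssc"))
    for (m in c("CARS", "GA", "SPA"))
      expect_silent(wavelengthToIndex(grid,
                                      referenceSelectedWavelengths(tgt, m)))
})

test_that("selection results serialise to JSON and back", {
  fx <- synthFixture()
  sel <- spaSelect(spectraValues(fx$snv)[1:60, ], fx$table$ssc[1:60],
                   spaConfig(maxVars = 8), wavelength = wavelengths(fx$snv))
  p <- tempfile(fileext = ".json")
  writeSelectionJSON(sel, p)
  back <- readSelectionJSON(p)
  expect_identical(bandIndices(back), bandIndices(sel))
  expect_equal(back@rmsecvTrace, sel@rmsecvTrace, tolerance = 1e-12)
  expect_equal(back@method, sel@method)
})
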