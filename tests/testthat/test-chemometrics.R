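test_that("jackknife CI filter keeps informative variables and drops noise", {
  withr::with_seed(21, {
    n <- 24
    X <- matrix(rnorm(n * 10), n)
    y <- 3 * X[, 1] - 2 * X[, 2] + rnorm(n, 0, 0.1)
    keep <- jackknifeCiFilter(X, y, nLv = 2, alpha = 0.10)
    expect_true(all(keep[1:2]))
  })
})

test_that("under the null the filter removes most variables, at alpha-consistent rates", {
  removed <- withr::with_seed(22, {
    vapply(1:40, function(i) {
      X <- matrix(rnorm(12 * 8), 12)
      y <- rnorm(12)
      keep <- tryCatch(jackknifeCiFilter(X, y, nLv = 2, alpha = 0.10),
                       error = function(e) rep(FALSE, 8))
      mean(!keep)
    }, numeric(1))
  })
  ## CI covers 0 for ~1-alpha of pure-noise coefficients
  expect_gt(mean(removed), 0.5)
})

test_that("the filter errors rather than returning an empty model", {
  withr::with_seed(23, {
    X <- matrix(rnorm(15 * 6), 15)
    y <- rnorm(15)
    ## demanding an extremely wide CI forces every variable out
    expect_error(jackknifeCiFilter(X, y, nLv = 2, alpha = 1e-12),
                 "empty model")
  })
})

test_that("bias calibration recovers offsets and slopes from the CV line", {
  ref <- matrix(seq(10, 100, length.out = 12), dimnames = list(NULL, "y"))
  b0 <- calibrateBias(ref, ref)
  expect_equal(b0$offset, 0, tolerance = 1e-12)
  expect_equal(b0$slopeFactor, 1)
  b5 <- calibrateBias(ref + 5, ref)
  expect_equal(b5$offset, 5, tolerance = 1e-10)
  expect_equal(b5$slopeFactor, 1)   # slope 1: offset only
  bs <- calibrateBias(1.1 * ref, ref)
  lmOracle <- coef(lm(1.1 * ref[, 1] ~ ref[, 1]))
  expect_equal(bs$slopeFactor, 1 / lmOracle[[2]], tolerance = 1e-10)
  expect_equal(bs$slopeFactor, 1 / 1.1, tolerance = 1e-10)
  ## slope dead-band: |b - 1| <= 1% leaves the slope alone
  bd <- calibrateBias(1.005 * ref, ref)
  expect_equal(bd$slopeFactor, 1)
  expect_error(calibrateBias(ref, matrix(rep(1, 12))), "degenerate")
  expect_error(calibrateBias(ref[1:2, , drop = FALSE],
                             ref[1:2, , drop = FALSE]), "at least 3")
})

test_that("error metrics match hand arithmetic", {
  expect_equal(regressionMetrics(1:4, 1:4, "calibration")$RMSE, 0)
  expect_equal(regressionMetrics(1:4, 1:4, "calibration")$R2, 1)
  expect_equal(regressionMetrics(2:5, 1:4, "validation")$RMSE, 1)
  ## pairs (pred, ref) = (1,2), (2,2), (3,5)
  m <- regressionMetrics(c(1, 2, 3), c(2, 2, 5), "validation")
  expect_equal(m$RMSE, sqrt(5 / 3))
  expect_equal(m$Q2, 1 - 5 / 6)
  expect_error(regressionMetrics(1:3, 1:4), "length mismatch")
})

test_that("outlier report flags constructed outliers but not clean data", {
  falseFlags <- withr::with_seed(31, {
    vapply(1:100, function(i) {
      inst <- testInstance(30, 10, seed = i, noise = 0.3)
      fit <- fitPls(inst$X, inst$Y, 3)
      sum(detectOutliers(fit, inst$X, inst$Y)$flagged)
    }, numeric(1))
  })
  ## false-flag rate per sample stays below 1%
  expect_lte(sum(falseFlags) / (100 * 30), 0.01)
  ## a y shifted by 10 SD must be flagged
  inst <- testInstance(30, 10, seed = 5, noise = 0.3)
  Y <- inst$Y
  Y[7] <- Y[7] + 10 * sd(Y)
  fit <- fitPls(inst$X, Y, 3)
  rep <- detectOutliers(fit, inst$X, Y)
  expect_true(rep$flagged[7])
})

test_that("leverages sum to nLv + 1 under the intercept convention", {
  inst <- testInstance(25, 12, seed = 9, noise = 0.4)
  for (k in c(2, 4)) {
    fit <- fitPls(inst$X, inst$Y, k)
    rep <- detectOutliers(fit, inst$X, inst$Y)
    expect_equal(sum(rep$leverage), k + 1, tolerance = 1e-10)
    expect_true(all(rep$leverage >= 0 & rep$leverage <= 1))
  }
})

test_that("LoD is 3.3 times the blank prediction SD", {
  lib <- makeComponentLibrary(2)
  cal <- simulateJuiceSpectra(factorialDesign(), lib, 0.001, seed = 1)
  models <- calibrateSugarModels(cal, nLv = c(sucrose = 4, glucose = 4,
                                              fructose = 4), maxLv = 5)
  blankDesign <- data.frame(sucrose = rep(0, 12), glucose = 0, fructose = 0)
  blanks <- simulateJuiceSpectra(blankDesign, lib, 0.001, seed = 9)
  model <- models$sucrose
  lod <- estimateLod(model, blanks)
  p <- predictSpectra(model, blanks)
  expect_equal(unname(lod), 3.3 * sd(p[, 1]), tolerance = 1e-12)
  ## zero-noise blanks give (numerically) zero LoD
  blanks0 <- simulateJuiceSpectra(blankDesign, lib, 0, seed = 9)
  expect_lt(unname(estimateLod(model, blanks0)), 1e-8)
  expect_error(estimateLod(model, blanks[, 1:5]), "at least 10")
})

test_that("model JSON round-trip preserves predictions exactly", {
  lib <- makeComponentLibrary(3)
  cal <- simulateJuiceSpectra(factorialDesign(
    levels = c(sucrose = 4, glucose = 4, fructose = 4)), lib, 0.002,
    seed = 2)
  model <- calibrateSugarModels(cal, nLv = c(sucrose = 3, glucose = 3,
                                             fructose = 3),
                                maxLv = 4)$sucrose
  probe <- simulateJuiceSpectra(randomDesign(10, seed = 5), lib, 0.002,
                                seed = 5)
  f <- withr::local_tempfile(fileext = ".json")
  saveModel(model, f)
  model2 <- loadModel(f)
  expect_equal(predictSpectra(model2, probe), predictSpectra(model, probe),
               tolerance = 1e-12)
})

test_that("model loader rejects corrupt or mis-versioned files", {
  f <- withr::local_tempfile(fileext = ".json")
  writeLines('{"version": "something-else"}', f)
  expect_error(loadModel(f), "version")
  writeLines('{"version": "stalkscreen-pls-1", "recipe', f)  # truncated
  expect_error(loadModel(f), "corrupt")
  expect_error(loadModel("no/such.json"), "not found")
})
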