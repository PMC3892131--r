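test_that("generators are pure functions of their seed", {
  expect_identical(makeComponentLibrary(7), makeComponentLibrary(7))
  lib <- makeComponentLibrary(7)
  d <- factorialDesign(levels = c(sucrose = 3, glucose = 3, fructose = 3))
  expect_identical(spectraMatrix(simulateJuiceSpectra(d, lib, seed = 4)),
                   spectraMatrix(simulateJuiceSpectra(d, lib, seed = 4)))
  expect_identical(spectraMatrix(simulateBagasseSet(10, lib, seed = 4)),
                   spectraMatrix(simulateBagasseSet(10, lib, seed = 4)))
  expect_identical(simulateStalkPopulation(10, seed = 4),
                   simulateStalkPopulation(10, seed = 4))
  ## generators leave the global RNG stream untouched
  withr::with_seed(99, {
    before <- .Random.seed
    invisible(makeComponentLibrary(3))
    expect_identical(.Random.seed, before)
  })
})

test_that("component library satisfies its structural contract", {
  for (seed in c(1, 5, 12)) {
    lib <- makeComponentLibrary(seed)
    sugars <- c("sucrose", "glucose", "fructose")
    for (sg in sugars) {
      bands <- lib$components[[sg]]
      expect_gte(nrow(bands), 4)
      expect_lte(nrow(bands), 8)
      expect_true(all(bands$height > 0))
      expect_true(all(bands$center >= min(lib$grid) &
                        bands$center <= max(lib$grid)))
      expect_true(all(componentSpectrum(lib, sg, 100) >= 0))
    }
    ## every sugar pair shares a band within 30 cm-1
    for (a in sugars) for (b in setdiff(sugars, a)) {
      dmin <- min(outer(lib$components[[a]]$center,
                        lib$components[[b]]$center,
                        function(x, y) abs(x - y)))
      expect_lte(dmin, 30)
    }
    expect_equal(lib$components$water$center, 1635)
  }
  expect_error(componentSpectrum(makeComponentLibrary(1), "starch"),
               "unknown component")
})

test_that("factorial designs enumerate the full grid", {
  expect_equal(nrow(factorialDesign()), 216)
  expect_equal(nrow(factorialDesign(levels = c(sucrose = 2, glucose = 2,
                                               fructose = 2))), 8)
  one <- factorialDesign(levels = c(sucrose = 1, glucose = 1, fructose = 1))
  expect_equal(nrow(one), 1)
  expect_equal(unname(unlist(one)), c(0, 0, 0))
  rg <- attr(factorialDesign(), "ranges")
  expect_equal(rg$sucrose, c(0, 600))
  expect_error(factorialDesign(ranges = list(sucrose = c(10, 0),
                                             glucose = c(0, 1),
                                             fructose = c(0, 1))),
               "invalid range")
})

test_that("juice spectra obey the exact linear mixture model at zero noise", {
  lib <- makeComponentLibrary(2)
  water <- componentSpectrum(lib, "water")
  zero <- simulateJuiceSpectra(data.frame(sucrose = 0, glucose = 0,
                                          fructose = 0), lib, 0, seed = 1)
  expect_equal(as.numeric(spectraMatrix(zero)), water, tolerance = 1e-12)
  c1 <- data.frame(sucrose = 150, glucose = 80, fructose = 40)
  s1 <- spectraMatrix(simulateJuiceSpectra(c1, lib, 0, seed = 1))
  s2 <- spectraMatrix(simulateJuiceSpectra(2 * c1, lib, 0, seed = 1))
  expect_equal(s2[1, ] - water, 2 * (s1[1, ] - water), tolerance = 1e-12)
})

test_that("bagasse digestibility references stay inside the declared range", {
  lib <- makeComponentLibrary(3)
  set <- simulateBagasseSet(80, lib, noiseSdD = 0.3, seed = 6)
  d <- referenceTable(set)$digestibility
  expect_true(all(d >= 0.95 - 3 * 0.3 & d <= 12.1 + 3 * 0.3))
  expect_equal(targetUnits(set)[["digestibility"]], "ug.mgDW-1.h-1")
  expect_error(simulateBagasseSet(1, lib), "n must be")
  expect_error(simulateBagasseSet(10, lib, dRange = c(5, 2)), "invalid")
})

test_that("noise-free bagasse spectra support near-perfect digestibility recovery", {
  lib <- makeComponentLibrary(1)
  cal <- simulateBagasseSet(120, lib, noiseSdSpectral = 0, noiseSdD = 0,
                            scatterSdLog = 0, offsetSd = 0, seed = 5)
  val <- simulateBagasseSet(60, lib, noiseSdSpectral = 0, noiseSdD = 0,
                            scatterSdLog = 0, offsetSd = 0, seed = 6)
  model <- calibrateDigestibilityModel(cal, ciAlpha = NULL)
  p <- predictSpectra(model, val)
  m <- regressionMetrics(p[, 1], referenceTable(val)$digestibility,
                         "validation")
  expect_gte(m$Q2, 0.999)
})

test_that("stalk populations respect the field ranges and geometry invariants", {
  pop <- simulateStalkPopulation(300, noiseCv = 0.05, seed = 8)
  expect_true(all(pop$H >= 237 & pop$H <= 338))
  expect_true(all(pop$ws_FW >= 228 & pop$ws_FW <= 941))
  expect_true(all(pop$R >= pop$r & pop$r > 0))
  expect_true(all(pop$HB + pop$LSI <= pop$H))
  expect_true(all(pop$ws_DW <= pop$ws_FW))
  expect_true(all(pop$v_ratio > 0 & pop$v_ratio < 1))
  expect_error(simulateStalkPopulation(2), "n must be")
  expect_error(simulateStalkPopulation(10, noiseCv = -0.1), "invalid noise")
})
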