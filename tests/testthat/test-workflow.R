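## End-to-end workflow and command-level behaviour on small synthetic runs.

smallCal <- function(lib, seed = 1) {
  simulateJuiceSpectra(
    factorialDesign(levels = c(sucrose = 4, glucose = 4, fructose = 4)),
    lib, 0.002, seed = seed)
}

test_that("sugar calibration returns one model and metrics row per sugar", {
  lib <- makeComponentLibrary(4)
  cal <- smallCal(lib)
  models <- calibrateSugarModels(cal, nLv = c(sucrose = 3, glucose = 4,
                                              fructose = 3), maxLv = 5)
  expect_named(models, c("sucrose", "glucose", "fructose"))
  metrics <- attr(models, "metrics")
  expect_equal(metrics$target, c("sucrose", "glucose", "fructose"))
  expect_equal(metrics$nLv, c(3, 4, 3))
  expect_true(all(metrics$R2 > 0.99))
  ## stored RMSEC is reproduced by predicting the calibration set
  p <- predictSpectra(models$sucrose, cal)
  rmsec <- sqrt(mean((p[, 1] - referenceTable(cal)$sucrose)^2))
  expect_equal(rmsec, models$sucrose@metrics$RMSEC, tolerance = 1e-8)
  ## spectra without reference cannot calibrate
  bare <- SpectraSet(wavenumbers(cal), spectraMatrix(cal))
  expect_error(calibrateSugarModels(bare), "no sugar reference")
})

test_that("calibration is deterministic given identical inputs", {
  lib <- makeComponentLibrary(4)
  m1 <- calibrateSugarModels(smallCal(lib), nLv = c(sucrose = 3,
                                                    glucose = 3,
                                                    fructose = 3), maxLv = 4)
  m2 <- calibrateSugarModels(smallCal(lib), nLv = c(sucrose = 3,
                                                    glucose = 3,
                                                    fructose = 3), maxLv = 4)
  expect_identical(attr(m1, "metrics"), attr(m2, "metrics"))
  expect_identical(m1$sucrose@coefficients, m2$sucrose@coefficients)
})

test_that("digestibility calibration filters variables and stores the mask", {
  lib <- makeComponentLibrary(4)
  cal <- simulateBagasseSet(40, lib, seed = 3)
  model <- calibrateDigestibilityModel(cal, maxLv = 6)
  expect_s4_class(model, "PLSModel")
  expect_lt(sum(model@mask), length(model@mask))  # some variables removed
  expect_equal(model@targets, "digestibility")
  expect_gte(model@metrics$R2, 0.9)
})

test_that("per-stalk yields match hand-computed values", {
  ## one stalk with round-number geometry: H=100, R=r=1 (cylinder),
  ## internode of 10 cm -> V_ratio = 0.1
  ft <- data.frame(sample_id = "s1", H = 100, R = 1, r = 1, HB = 40,
                   LSI = 10, FW = 50, DW = 12.5)
  sp <- data.frame(sample_id = "s1", sucrose = 291, glucose = 126,
                   fructose = 63)
  dp <- data.frame(sample_id = "s1", digestibility = 6.45)
  rt <- defaultFixedRatios()
  y <- computeStalkYields(ft, sp, dp, rt)
  ## FW 50/0.1/0.91, DW 12.5/0.1/1.00 -> V = FW_ws - DW_ws
  fwWS <- 50 / 0.1 / 0.91; dwWS <- 125
  V <- fwWS - dwWS
  S <- totalSugarConc(291 / 0.97, 126 / 1.05, 63 / 0.97)
  D <- 6.45 / 1.29
  expect_equal(y$V_mL, V, tolerance = 1e-9)
  expect_equal(y$S_g_per_100mL, S, tolerance = 1e-9)
  expect_equal(y$D, D, tolerance = 1e-9)
  expect_equal(y$total_g, V / 100 * S + D * dwWS * 1000 * 24 * 1e-6,
               tolerance = 1e-9)
  expect_equal(y$flag, "")
})

test_that("invalid geometry rows are flagged while the run continues", {
  ft <- data.frame(sample_id = c("ok", "bad"), H = c(100, 100),
                   R = c(1, 1), r = c(1, 1), HB = c(40, 95),
                   LSI = c(10, 10), FW = c(50, 50), DW = c(10, 10))
  sp <- data.frame(sample_id = c("ok", "bad"), sucrose = c(100, 100),
                   glucose = c(50, 50), fructose = c(20, 20))
  dp <- data.frame(sample_id = c("ok", "bad"), digestibility = c(5, 5))
  y <- computeStalkYields(ft, sp, dp)
  expect_equal(y$flag[y$sample_id == "ok"], "")
  expect_match(y$flag[y$sample_id == "bad"], "beyond")
  expect_false(is.na(y$total_g[y$sample_id == "ok"]))
  expect_true(is.na(y$total_g[y$sample_id == "bad"]))
  ## an empty join is an error
  dpX <- data.frame(sample_id = "zz", digestibility = 5)
  expect_error(computeStalkYields(ft, sp, dpX), "no common sample_ids")
})

test_that("command pipeline runs from config files end to end", {
  dir <- withr::local_tempdir()
  fixtures <- file.path(dir, "fix")
  cfgFile <- file.path(dir, "run.yaml")
  writeLines(c(paste0("out_dir: ", fixtures), "seed: 11"), cfgFile)
  cfg <- readRunConfig(cfgFile)
  runSimulate(cfg)
  expect_true(file.exists(file.path(fixtures, "manifest.json")))
  ## calibrate on a reduced juice set for speed
  lib <- makeComponentLibrary(11)
  writeSpectraTable(smallCal(lib, seed = 11),
                    file.path(fixtures, "cal_small.csv"))
  writeLines(c(paste0("out_dir: ", file.path(dir, "models")),
               paste0("spectra: ", file.path(fixtures, "cal_small.csv")),
               "n_lv: {sucrose: 3, glucose: 3, fructose: 3}",
               "max_lv: 4"), cfgFile)
  cfg <- readRunConfig(cfgFile)
  files <- runCalibrate(cfg, target = "sugars")
  expect_true(all(file.exists(files)))
  ## predictions via the command match in-memory predictions
  model <- loadModel(file.path(dir, "models", "model_sucrose.json"))
  cfg$model <- file.path(dir, "models", "model_sucrose.json")
  predFile <- runPredict(cfg, spectraPath = file.path(fixtures,
                                                      "cal_small.csv"))
  pred <- read.csv(predFile)
  inMem <- predictSpectra(model, readSpectraTable(
    file.path(fixtures, "cal_small.csv")))
  expect_equal(pred$sucrose, unname(inMem[, 1]), tolerance = 1e-12)
  expect_error(readRunConfig(file.path(dir, "missing.yaml")), "not found")
})

test_that("the CLI script dispatches and sets exit codes", {
  script <- system.file("scripts", "stalkscreen.R", package = "stalkscreen")
  expect_true(nzchar(script))
  dir <- withr::local_tempdir()
  cfgFile <- file.path(dir, "cfg.yaml")
  writeLines(c(paste0("out_dir: ", file.path(dir, "out")), "seed: 3"),
             cfgFile)
  rscript <- file.path(R.home("bin"), "Rscript")
  ok <- system2(rscript, c(script, "simulate", "--config", cfgFile),
                stdout = FALSE, stderr = FALSE)
  expect_equal(ok, 0)
  expect_true(file.exists(file.path(dir, "out", "stalk_population.csv")))
  bad <- system2(rscript, c(script, "frobnicate", "--config", cfgFile),
                 stdout = FALSE, stderr = FALSE)
  expect_equal(bad, 2)
})
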