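#' Default preprocessing recipes
#'
#' `juiceRecipe()`: truncate to the 1,180-900 cm-1 sugar window, 9-point
#' Savitzky-Golay smoothing. `bagasseRecipe()`: truncate to the 1,800-850
#' cm-1 cell-wall fingerprint, 9-point Savitzky-Golay second derivative,
#' EMSC. Mean centering happens inside the PLS fit in both cases.
#'
#' @param window,polyorder Savitzky-Golay settings.
#' @return an unfitted `preprocessRecipe`.
#' @export
juiceRecipe <- function(window = 9, polyorder = 2) {
  preprocessRecipe(
    recipeStep("truncate", list(wnHigh = 1180, wnLow = 900)),
    recipeStep("savgol", list(window = window, polyorder = polyorder,
                              deriv = 0)))
}

#' @rdname juiceRecipe
#' @export
bagasseRecipe <- function(window = 9, polyorder = 2) {
  preprocessRecipe(
    recipeStep("truncate", list(wnHigh = 1800, wnLow = 850)),
    recipeStep("savgol", list(window = window, polyorder = polyorder,
                              deriv = 2)),
    recipeStep("emsc"))
}

## shared calibration core: recipe -> CV -> LV choice -> (CI filter) ->
## bias -> final fit -> metrics
.calibrateOne <- function(calSet, target, recipe, nLv = NULL, maxLv = 15,
                          ciAlpha = NULL, algorithm = "nipals",
                          deadband = 0.01) {
  ref <- referenceTable(calSet)
  if (is.null(ref) || !target %in% names(ref))
    stop("calibration spectra carry no '", target, "' reference")
  y <- matrix(ref[[target]], dimnames = list(NULL, target))
  fitted <- fitRecipe(recipe, calSet)
  X <- spectraMatrix(fitted$set)
  wn <- wavenumbers(fitted$set)
  mask <- rep(TRUE, ncol(X))
  cv <- crossValidate(X, y, maxLv, algorithm = algorithm)
  k <- if (is.null(nLv)) selectNLv(cv$rmsecv[, 1]) else min(nLv, cv$maxLv)
  if (!is.null(ciAlpha)) {
    mask <- jackknifeCiFilter(X, y, k, alpha = ciAlpha,
                              algorithm = algorithm)
    X <- X[, mask, drop = FALSE]
    cv <- crossValidate(X, y, maxLv, algorithm = algorithm)
    k <- if (is.null(nLv)) selectNLv(cv$rmsecv[, 1]) else min(nLv, cv$maxLv)
  }
  oof <- cv$oof[, 1, k]
  bias <- calibrateBias(oof, y, deadband = deadband)
  fit <- fitPls(X, y, k, algorithm)
  calPred <- (plsPredict(fit, X)[, 1] - bias$offset[1]) * bias$slopeFactor[1]
  oofCorr <- (oof - bias$offset[1]) * bias$slopeFactor[1]
  mc <- regressionMetrics(calPred, y, "calibration")
  mcv <- regressionMetrics(oofCorr, y, "validation")
  units <- targetUnits(calSet)[target]
  if (is.na(units)) units <- ""
  model <- newPLSModel(fit, fitted$recipe, wn, mask, bias,
                       targets = target, units = unname(units),
                       metrics = list(RMSEC = mc$RMSE, R2 = mc$R2,
                                      RMSECV = mcv$RMSE, Q2cv = mcv$Q2,
                                      nLv = k, nVars = sum(mask),
                                      yMin = min(y), yMax = max(y)))
  model
}

#' Calibrate juice sugar PLS models
#'
#' Runs the full sugar workflow on a calibration [SpectraSet-class] whose
#' reference table holds sucrose, glucose and fructose concentrations (mM):
#' preprocessing, leave-one-out cross-validation, per-sugar latent-variable
#' choice, offset/slope bias correction, final NIPALS fit. One single-target
#' model is fitted per sugar; the shipped defaults (6 LVs for sucrose and
#' fructose, 9 for glucose) reproduce the screening configuration, or pass
#' `nLv = NULL` to select by the RMSECV parsimony rule.
#'
#' @param calSet calibration spectra with sugar references.
#' @param nLv named vector of LV counts per sugar, or `NULL` to select by
#'   cross-validation.
#' @param maxLv cross-validation factor ceiling (screening default 15).
#' @param recipe preprocessing recipe; default [juiceRecipe()].
#' @param algorithm `"nipals"` or `"widekernel"`.
#' @return named list of [PLSModel-class] objects, one per sugar, with a
#'   `metrics` attribute: a data.frame of per-sugar RMSEC, R2, RMSECV, LVs
#'   and retained-variable counts.
#' @export
calibrateSugarModels <- function(calSet,
                                 nLv = c(sucrose = 6, glucose = 9,
                                         fructose = 6),
                                 maxLv = 15, recipe = juiceRecipe(),
                                 algorithm = "nipals") {
  sugars <- intersect(c("sucrose", "glucose", "fructose"),
                      names(referenceTable(calSet)))
  if (length(sugars) == 0) stop("no sugar reference columns present")
  models <- lapply(sugars, function(sg)
    .calibrateOne(calSet, sg, recipe,
                  nLv = if (is.null(nLv)) NULL else nLv[[sg]],
                  maxLv = maxLv, algorithm = algorithm))
  names(models) <- sugars
  attr(models, "metrics") <- do.call(rbind, lapply(sugars, function(sg) {
    m <- models[[sg]]@metrics
    data.frame(target = sg, nLv = m$nLv, nVars = m$nVars, RMSEC = m$RMSEC,
               R2 = m$R2, RMSECV = m$RMSECV)
  }))
  models
}

#' Calibrate the cell-wall digestibility PLS model
#'
#' Runs the bagasse workflow on a calibration set whose reference table holds
#' `digestibility` (ug.mgDW-1.h-1): second-derivative + EMSC preprocessing,
#' LOO cross-validation with LV choice by the parsimony rule (capped at
#' `maxLv`), the 90% jackknife confidence-interval variable filter with a
#' refit on the retained wavenumbers, and offset/slope bias correction.
#'
#' @param calSet calibration spectra with a `digestibility` reference.
#' @param maxLv cross-validation factor ceiling.
#' @param ciAlpha two-sided level for the CI filter (0.10 = 90% CI); `NULL`
#'   disables filtering.
#' @param recipe preprocessing recipe; default [bagasseRecipe()].
#' @param algorithm `"nipals"` or `"widekernel"` (the wide-kernel route suits
#'   these wide matrices).
#' @return a [PLSModel-class].
#' @export
calibrateDigestibilityModel <- function(calSet, maxLv = 15, ciAlpha = 0.10,
                                        recipe = bagasseRecipe(),
                                        algorithm = "widekernel") {
  .calibrateOne(calSet, "digestibility", recipe, nLv = NULL, maxLv = maxLv,
                ciAlpha = ciAlpha, algorithm = algorithm)
}

#' Per-stalk total fermentable sugar yields
#'
#' Joins a field geometry table with per-sample sugar and digestibility
#' predictions and runs the whole-stalk yield chain: `V_ratio` from the
#' frustum model; whole-stalk FW/DW via the fixed ratios; juice volume from
#' the water content; total sugar concentration from the three sugars
#' (intensive — fixed ratio only); whole-stalk digestibility; then
#' `V.[S] + B.D`. Rows violating geometry invariants are flagged and
#' reported, not dropped silently; the run continues for the rest.
#'
#' @param fieldTable data.frame as from [readFieldTable()]: `sample_id`,
#'   `H`, `R`, `r`, `HB`, `LSI`, internode `FW`, `DW` (g).
#' @param sugarPred data.frame or matrix with rownames (or a `sample_id`
#'   column) and columns `sucrose`, `glucose`, `fructose` (mM, internode
#'   juice).
#' @param digPred as above with a `digestibility` column (ug.mgDW-1.h-1).
#' @param ratios fixed-ratio table; default [defaultFixedRatios()].
#' @param hours digestion time (default 24 h).
#' @param density juice density for volume conversion (g/mL).
#' @return data.frame per stalk: `sample_id`, `V_mL`, `S_g_per_100mL`,
#'   `B_gDW`, `D`, `soluble_g`, `cell_wall_g`, `total_g`, `flag` (empty when
#'   clean).
#' @export
computeStalkYields <- function(fieldTable, sugarPred, digPred,
                               ratios = defaultFixedRatios(), hours = 24,
                               density = 1) {
  toDf <- function(m) {
    df <- as.data.frame(m)
    if (!"sample_id" %in% names(df)) df$sample_id <- rownames(m)
    df
  }
  sugarPred <- toDf(sugarPred); digPred <- toDf(digPred)
  ids <- Reduce(intersect, list(fieldTable$sample_id, sugarPred$sample_id,
                                digPred$sample_id))
  if (length(ids) == 0) stop("no common sample_ids to join")
  ft <- fieldTable[match(ids, fieldTable$sample_id), ]
  sp <- sugarPred[match(ids, sugarPred$sample_id), ]
  dp <- digPred[match(ids, digPred$sample_id), ]
  rt <- stats::setNames(ratios$ratio, ratios$analyte)
  out <- data.frame(sample_id = ids, V_mL = NA_real_,
                    S_g_per_100mL = NA_real_, B_gDW = NA_real_, D = NA_real_,
                    soluble_g = NA_real_, cell_wall_g = NA_real_,
                    total_g = NA_real_, flag = "")
  for (i in seq_along(ids)) {
    res <- tryCatch({
      vr <- volumetricRatio(ft$H[i], ft$R[i], ft$r[i], ft$HB[i], ft$LSI[i])
      fwWS <- extrapolateToWholeStalk(ft$FW[i], vr, rt[["FW"]], TRUE)
      dwWS <- extrapolateToWholeStalk(ft$DW[i], vr, rt[["DW"]], TRUE)
      V <- juiceVolumeEstimate(fwWS, dwWS, density)
      S <- totalSugarConc(
        extrapolateToWholeStalk(sp$sucrose[i], vr, rt[["sucrose"]], FALSE),
        extrapolateToWholeStalk(sp$glucose[i], vr, rt[["glucose"]], FALSE),
        extrapolateToWholeStalk(sp$fructose[i], vr, rt[["fructose"]], FALSE))
      D <- extrapolateToWholeStalk(dp$digestibility[i], vr,
                                   rt[["digestibility"]], FALSE)
      yr <- totalFermentableYield(V, S, dwWS, D, hours)
      list(V = V, S = S, B = dwWS, D = D, yr = yr)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      out$flag[i] <- res
    } else {
      out$V_mL[i] <- res$V; out$S_g_per_100mL[i] <- res$S
      out$B_gDW[i] <- res$B; out$D[i] <- res$D
      out$soluble_g[i] <- res$yr$soluble_g
      out$cell_wall_g[i] <- res$yr$cell_wall_g
      out$total_g[i] <- res$yr$total_g
    }
  }
  out
}

#' Write synthetic fixture files
#'
#' Generates a complete synthetic study — juice calibration and validation
#' spectra, bagasse calibration and validation spectra, and a paired stalk
#' field table — and writes them as CSVs plus a manifest JSON recording all
#' parameters and seeds.
#'
#' @param outDir output directory (created if needed).
#' @param seed base seed; sub-generators use `seed + 0..4`.
#' @param nValidation juice validation set size.
#' @param nBagasseCal,nBagasseVal bagasse set sizes (52/38 mirrors a split of
#'   a 90-ecotype field collection).
#' @param nStalks stalk population size.
#' @return invisibly, the manifest list.
#' @export
simulateFixtures <- function(outDir, seed = 1, nValidation = 100,
                             nBagasseCal = 52, nBagasseVal = 38,
                             nStalks = 200) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  lib <- makeComponentLibrary(seed)
  des <- factorialDesign()
  noiseSd <- defaultJuiceNoiseSd(lib)
  cal <- simulateJuiceSpectra(des, lib, noiseSd, seed = seed)
  val <- simulateJuiceSpectra(randomDesign(nValidation, seed = seed + 1),
                              lib, noiseSd, seed = seed + 1)
  bagCal <- simulateBagasseSet(nBagasseCal, lib, seed = seed + 2)
  bagVal <- simulateBagasseSet(nBagasseVal, lib, seed = seed + 3)
  stalks <- simulateStalkPopulation(nStalks, seed = seed + 4)
  writeSpectraTable(cal, file.path(outDir, "juice_calibration.csv"))
  writeSpectraTable(val, file.path(outDir, "juice_validation.csv"))
  writeSpectraTable(bagCal, file.path(outDir, "bagasse_calibration.csv"))
  writeSpectraTable(bagVal, file.path(outDir, "bagasse_validation.csv"))
  utils::write.csv(stalks, file.path(outDir, "stalk_population.csv"),
                   row.names = FALSE)
  manifest <- list(seed = seed, noiseSd = noiseSd,
                   design = list(levels = c(6, 6, 6),
                                 n_calibration = nrow(des),
                                 n_validation = nValidation),
                   bagasse = list(n_cal = nBagasseCal, n_val = nBagasseVal),
                   stalks = list(n = nStalks),
                   files = c("juice_calibration.csv", "juice_validation.csv",
                             "bagasse_calibration.csv",
                             "bagasse_validation.csv",
                             "stalk_population.csv"))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
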