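#' Assemble a PLSModel from a fitted pipeline
#'
#' Internal-facing constructor used by the calibration workflows; bundles the
#' frozen preprocessing recipe, variable mask, PLS solution and bias
#' correction into a serializable [PLSModel-class].
#'
#' @param fit a `plsFit` from [fitPls()] (fitted on the masked, preprocessed
#'   calibration matrix).
#' @param recipe frozen recipe from [fitRecipe()].
#' @param wavenumbers the post-recipe grid.
#' @param mask logical retained-variable mask over that grid.
#' @param bias data.frame from [calibrateBias()] (or NULL for no correction).
#' @param targets,units target names and units.
#' @param metrics list of training metrics to store.
#' @return a `PLSModel`.
#' @export
newPLSModel <- function(fit, recipe, wavenumbers, mask, bias = NULL,
                        targets, units = rep("", length(targets)),
                        metrics = list()) {
  if (is.null(bias))
    bias <- data.frame(target = targets, offset = 0, slopeFactor = 1)
  methods::new("PLSModel",
    recipe = unclass(recipe), wavenumbers = as.numeric(wavenumbers),
    mask = as.logical(mask), nLv = fit$nLv, algorithm = fit$algorithm,
    weights = fit$W, xLoadings = fit$P, yLoadings = fit$Q,
    coefficients = fit$B, xMeans = fit$xMeans, yMeans = as.numeric(fit$yMeans),
    bias = bias, targets = targets, units = units, metrics = metrics,
    version = "stalkscreen-pls-1")
}

#' Predict target values for new spectra
#'
#' Applies the model's frozen preprocessing recipe, variable mask, regression
#' coefficients and offset/slope bias correction to a set of raw spectra. If
#' the preprocessed grid does not match the model's grid but covers its span,
#' spectra are linearly interpolated onto it. Negative concentration
#' predictions are reported as-is (clamping would corrupt error statistics)
#' and listed in the `flags` attribute.
#'
#' @param model a [PLSModel-class].
#' @param x a [SpectraSet-class] of raw (unpreprocessed) spectra.
#' @return matrix of bias-corrected predictions (samples x targets), with
#'   attribute `flags`: a data.frame of (sample, target) pairs with negative
#'   predictions.
#' @export
predictSpectra <- function(model, x) {
  recipe <- structure(model@recipe, class = "preprocessRecipe")
  prep <- applyRecipe(recipe, x)
  wn <- wavenumbers(prep)
  if (length(wn) != length(model@wavenumbers) ||
      max(abs(wn - model@wavenumbers)) > 1e-9) {
    if (max(model@wavenumbers) > max(wn) || min(model@wavenumbers) < min(wn))
      stop("spectra do not cover the model's wavenumbers")
    prep <- alignToGrid(prep, model@wavenumbers)
  }
  X <- spectraMatrix(prep)[, model@mask, drop = FALSE]
  raw <- sweep(sweep(X, 2, model@xMeans) %*% model@coefficients, 2,
               model@yMeans, "+")
  for (j in seq_along(model@targets))
    raw[, j] <- (raw[, j] - model@bias$offset[j]) * model@bias$slopeFactor[j]
  colnames(raw) <- model@targets
  rownames(raw) <- sampleIds(x)
  neg <- which(raw < 0, arr.ind = TRUE)
  flags <- data.frame(sample = rownames(raw)[neg[, 1]],
                      target = model@targets[neg[, 2]],
                      reason = rep("negative", nrow(neg)))
  attr(raw, "flags") <- flags
  raw
}

#' Limit of detection from blank spectra
#'
#' ICH-style estimate: 3.3 times the standard deviation of the bias-corrected
#' predictions on background-only (blank) spectra, per target. One admissible
#' reading of a conservatively stated detection limit; requires at least 10
#' blanks for a usable SD.
#'
#' @param model a [PLSModel-class].
#' @param blanks a [SpectraSet-class] of >= 10 blank spectra.
#' @return named numeric vector of LoD values in the model's target units.
#' @export
estimateLod <- function(model, blanks) {
  if (ncol(blanks) < 10) stop("need at least 10 blank spectra")
  p <- predictSpectra(model, blanks)
  3.3 * apply(p, 2, stats::sd)
}

.matToList <- function(m) list(data = as.numeric(m), dim = dim(m))
.listToMat <- function(l) matrix(unlist(l$data), l$dim[[1]], l$dim[[2]])

#' Save / load a PLSModel as JSON
#'
#' The model file is versioned JSON holding the recipe (with fitted state),
#' the retained wavenumbers, coefficient vectors, centering, bias terms and
#' stored metrics; `loadModel(saveModel(m))` reproduces predictions exactly.
#'
#' @param model a [PLSModel-class].
#' @param path file path.
#' @return `saveModel`: `path` invisibly; `loadModel`: the `PLSModel`.
#' @export
saveModel <- function(model, path) {
  steps <- lapply(model@recipe$steps, function(s) {
    st <- s$state
    if (!is.null(st) && s$op == "emsc")
      st <- list(wavenumbers = as.numeric(st$wavenumbers),
                 reference = as.numeric(st$reference))
    list(op = s$op, params = s$params, state = st)
  })
  obj <- list(
    version = model@version,
    recipe = list(steps = steps, fitted = isTRUE(model@recipe$fitted)),
    wavenumbers = as.numeric(model@wavenumbers),
    mask = as.logical(model@mask),
    nLv = model@nLv,
    algorithm = model@algorithm,
    weights = .matToList(model@weights),
    xLoadings = .matToList(model@xLoadings),
    yLoadings = .matToList(model@yLoadings),
    coefficients = .matToList(model@coefficients),
    xMeans = as.numeric(model@xMeans),
    yMeans = as.numeric(model@yMeans),
    bias = list(target = model@bias$target,
                offset = as.numeric(model@bias$offset),
                slopeFactor = as.numeric(model@bias$slopeFactor)),
    targets = model@targets,
    units = model@units,
    metrics = model@metrics)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) stop("corrupt model file: ",
                                           conditionMessage(e)))
  if (is.null(obj$version) || !identical(obj$version, "stalkscreen-pls-1"))
    stop("unknown model file version: ",
         if (is.null(obj$version)) "<missing>" else obj$version)
  num <- function(x) as.numeric(unlist(x))
  chr <- function(x) as.character(unlist(x))
  steps <- lapply(obj$recipe$steps, function(s) {
    state <- s$state
    if (!is.null(state)) {
      if (identical(s$op, "emsc"))
        state <- list(wavenumbers = num(state$wavenumbers),
                      reference = num(state$reference))
      else state <- num(state)
    }
    list(op = s$op, params = lapply(s$params, unlist), state = state)
  })
  obj$mask <- as.logical(unlist(obj$mask))
  obj$weights <- list(data = num(obj$weights$data),
                      dim = num(obj$weights$dim))
  obj$xLoadings <- list(data = num(obj$xLoadings$data),
                        dim = num(obj$xLoadings$dim))
  obj$yLoadings <- list(data = num(obj$yLoadings$data),
                        dim = num(obj$yLoadings$dim))
  obj$coefficients <- list(data = num(obj$coefficients$data),
                           dim = num(obj$coefficients$dim))
  obj$xMeans <- num(obj$xMeans); obj$yMeans <- num(obj$yMeans)
  obj$wavenumbers <- num(obj$wavenumbers)
  obj$nLv <- as.integer(unlist(obj$nLv))
  obj$algorithm <- chr(obj$algorithm)
  obj$targets <- chr(obj$targets); obj$units <- chr(obj$units)
  obj$bias <- data.frame(target = chr(obj$bias$target),
                         offset = num(obj$bias$offset),
                         slopeFactor = num(obj$bias$slopeFactor))
  methods::new("PLSModel",
    recipe = list(steps = steps, fitted = isTRUE(obj$recipe$fitted)),
    wavenumbers = as.numeric(obj$wavenumbers),
    mask = as.logical(obj$mask),
    nLv = as.integer(obj$nLv),
    algorithm = obj$algorithm,
    weights = .listToMat(obj$weights),
    xLoadings = .listToMat(obj$xLoadings),
    yLoadings = .listToMat(obj$yLoadings),
    coefficients = .listToMat(obj$coefficients),
    xMeans = as.numeric(obj$xMeans),
    yMeans = as.numeric(obj$yMeans),
    bias = as.data.frame(obj$bias),
    targets = obj$targets,
    units = obj$units,
    metrics = as.list(obj$metrics),
    version = obj$version)
}
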