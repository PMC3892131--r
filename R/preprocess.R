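#' Savitzky-Golay smoothing and derivatives
#'
#' Applies a Savitzky-Golay polynomial filter to every spectrum. The filter
#' coefficients come from [signal::sgolay()]; only interior (fully supported)
#' windows are kept, so the output grid shrinks by `(window-1)/2` points at
#' each end — no fabricated edge values enter downstream modelling.
#' Derivatives are scaled by the grid spacing, so `deriv = k` outputs are
#' d^k A / d nu^k in AU.cm^k regardless of grid orientation.
#'
#' @param x a [SpectraSet-class] on a uniformly spaced grid.
#' @param window odd filter length in points (the field standard for juice and
#'   bagasse spectra here is 9).
#' @param polyorder fitting polynomial order; default 2 (classic quadratic
#'   window).
#' @param deriv derivative order, `0 <= deriv <= polyorder`.
#' @return the filtered `SpectraSet` on the trimmed grid.
#' @export
sgFilter <- function(x, window = 9, polyorder = 2, deriv = 0) {
  if (window %% 2 == 0) stop("window must be odd")
  if (polyorder >= window) stop("polyorder must be < window")
  if (deriv > polyorder) stop("deriv must be <= polyorder")
  wn <- wavenumbers(x)
  n <- length(wn)
  if (window > n) stop("window exceeds number of grid points")
  d <- diff(wn)
  if (max(abs(d - d[1])) > 1e-6)
    stop("grid spacing must be uniform for Savitzky-Golay filtering")
  h <- d[1]
  cc <- signal::sgolay(p = polyorder, n = window, m = deriv,
                       ts = 1)[(window + 1) / 2, ]
  half <- (window - 1) / 2
  mat <- spectraMatrix(x)
  idx <- (half + 1):(n - half)
  out <- matrix(0, nrow(mat), length(idx))
  for (j in seq_along(idx))
    out[, j] <- mat[, (idx[j] - half):(idx[j] + half), drop = FALSE] %*% cc
  out <- out / h^deriv
  .respectra(x, wn[idx], out)
}

#' Extended multiplicative scatter correction (EMSC)
#'
#' `fitEmsc` estimates the EMSC reference (the mean calibration spectrum) on a
#' calibration set; `applyEmsc` corrects spectra against that frozen state.
#' Each spectrum `s` is regressed as
#' `s ~ a*1 + d*nu + e*nu^2 + b*m` (least squares on the constant, linear and
#' quadratic wavenumber terms plus the reference `m`), and the corrected
#' spectrum is `(s - a - d*nu - e*nu^2) / b`. This removes additive baselines
#' and multiplicative scatter — the dominant artefacts of ATR spectra of
#' milled cell-wall particles.
#'
#' @param calibration a [SpectraSet-class]; its mean spectrum becomes the
#'   reference.
#' @param x a `SpectraSet` to correct (grid must match the state's).
#' @param state an EMSC state from `fitEmsc`.
#' @return `fitEmsc`: a list with elements `wavenumbers` and `reference`;
#'   `applyEmsc`: the corrected `SpectraSet`.
#' @export
fitEmsc <- function(calibration) {
  if (ncol(calibration) < 1) stop("empty calibration set")
  list(wavenumbers = wavenumbers(calibration),
       reference = colMeans(spectraMatrix(calibration)))
}

#' @rdname fitEmsc
#' @export
applyEmsc <- function(x, state) {
  wn <- wavenumbers(x)
  if (length(wn) != length(state$wavenumbers) ||
      max(abs(wn - state$wavenumbers)) > 1e-9)
    stop("grid mismatch between spectra and EMSC state")
  nu <- (wn - mean(wn)) / (max(wn) - min(wn))  # scaled for conditioning
  basis <- cbind(1, nu, nu^2, state$reference)
  qrB <- qr(basis)
  mat <- spectraMatrix(x)
  out <- mat
  for (i in seq_len(nrow(mat))) {
    cf <- qr.coef(qrB, mat[i, ])
    if (abs(cf[4]) < 1e-8)
      stop("degenerate scatter fit: spectrum orthogonal to reference")
    out[i, ] <- (mat[i, ] - basis[, 1:3, drop = FALSE] %*% cf[1:3]) / cf[4]
  }
  .respectra(x, wn, out)
}

#' Mean centering fitted on calibration data
#'
#' @param X numeric matrix (samples x variables).
#' @param means column means fitted on the calibration matrix.
#' @return `fitCenter`: the column means; `applyCenter`: the centered matrix.
#' @export
fitCenter <- function(X) colMeans(as.matrix(X))

#' @rdname fitCenter
#' @export
applyCenter <- function(X, means) {
  X <- as.matrix(X)
  if (ncol(X) != length(means)) stop("centering vector length mismatch")
  sweep(X, 2, means, "-")
}

#' Preprocessing recipes
#'
#' A recipe is an ordered list of steps, each `list(op =, params =, state =)`.
#' Supported ops: `truncate` (params `wnHigh`, `wnLow`), `savgol` (params
#' `window`, `polyorder`, `deriv`), `emsc` (state fitted from calibration),
#' `mean_center` (state = column means). `fitRecipe` runs the steps over a
#' calibration set, estimating and freezing any fitted state; `applyRecipe`
#' replays the frozen recipe on new spectra without re-estimating anything, so
#' prediction-time preprocessing is provably identical to calibration-time.
#'
#' @param ... steps created by `recipeStep()`.
#' @param op step name.
#' @param params named list of step parameters.
#' @return `preprocessRecipe`/`recipeStep`: recipe structures; `fitRecipe`: a
#'   list with elements `recipe` (frozen) and `set` (the preprocessed
#'   calibration set); `applyRecipe`: the preprocessed `SpectraSet`.
#' @examples
#' rec <- preprocessRecipe(
#'   recipeStep("truncate", list(wnHigh = 1180, wnLow = 900)),
#'   recipeStep("savgol", list(window = 9, polyorder = 2, deriv = 0)))
#' @export
preprocessRecipe <- function(...) {
  steps <- list(...)
  for (s in steps)
    if (!s$op %in% c("truncate", "savgol", "emsc", "mean_center"))
      stop("unknown recipe op: ", s$op)
  structure(list(steps = steps), class = "preprocessRecipe")
}

#' @rdname preprocessRecipe
#' @export
recipeStep <- function(op, params = list()) {
  list(op = op, params = params, state = NULL)
}

.applyStep <- function(step, x) {
  switch(step$op,
    truncate = truncateRegion(x, step$params$wnHigh, step$params$wnLow),
    savgol = sgFilter(x, step$params$window,
                      if (is.null(step$params$polyorder)) 2
                      else step$params$polyorder,
                      if (is.null(step$params$deriv)) 0 else step$params$deriv),
    emsc = applyEmsc(x, step$state),
    mean_center = .respectra(x, wavenumbers(x),
                             applyCenter(spectraMatrix(x), step$state)),
    stop("unknown recipe op: ", step$op))
}

#' @rdname preprocessRecipe
#' @param recipe a `preprocessRecipe`.
#' @param calibration,x a [SpectraSet-class].
#' @export
fitRecipe <- function(recipe, calibration) {
  x <- calibration
  steps <- recipe$steps
  for (i in seq_along(steps)) {
    if (steps[[i]]$op == "emsc") steps[[i]]$state <- fitEmsc(x)
    if (steps[[i]]$op == "mean_center")
      steps[[i]]$state <- fitCenter(spectraMatrix(x))
    x <- .applyStep(steps[[i]], x)
  }
  list(recipe = structure(list(steps = steps, fitted = TRUE),
                          class = "preprocessRecipe"),
       set = x)
}

#' @rdname preprocessRecipe
#' @export
applyRecipe <- function(recipe, x) {
  for (step in recipe$steps) {
    if (step$op %in% c("emsc", "mean_center") && is.null(step$state))
      stop("recipe not fitted: run fitRecipe() on calibration data first")
    x <- .applyStep(step, x)
  }
  x
}
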