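#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames rowData colData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom stats coef cor integrate lm predict qnorm rnorm runif sd var setNames
#' @importFrom utils read.csv write.csv
NULL

#' SpectraSet: a collection of FTIR absorbance spectra on a shared grid
#'
#' `SpectraSet` extends [SummarizedExperiment::SummarizedExperiment] to hold a
#' set of absorbance spectra sharing one wavenumber grid. Rows are wavenumbers
#' (stored descending, the instrument convention for 4,000 to 400 cm-1
#' acquisitions), columns are samples. Reference values for modelling targets
#' (e.g. sugar concentrations in mM, or cell-wall digestibility in
#' ug.mgDW-1.h-1) live in `colData`; the names and units of the columns that
#' are modelling targets are recorded in `metadata(x)$targets`.
#'
#' @slot .  inherits all slots from `SummarizedExperiment`.
#'
#' @section Validity:
#' The wavenumber grid (`rowData(x)$wavenumber`) must be numeric, of length
#' >= 2, strictly monotone, and stored in descending order; the assay matrix
#' must be numeric with no missing values; sample identifiers (colnames) must
#' be unique.
#'
#' @seealso [SpectraSet()] for construction, [wavenumbers()],
#'   [spectraMatrix()], [referenceTable()] for access, [truncateRegion()],
#'   [alignToGrid()] for manipulation.
#' @export
setClass("SpectraSet", contains = "SummarizedExperiment")

setValidity("SpectraSet", function(object) {
  wn <- SummarizedExperiment::rowData(object)$wavenumber
  if (is.null(wn)) return("rowData must contain a 'wavenumber' column")
  if (!is.numeric(wn) || length(wn) < 2)
    return("wavenumber grid must be numeric with length >= 2")
  d <- diff(wn)
  if (any(d >= 0)) return("wavenumber grid must be strictly descending")
  if (!"absorbance" %in% SummarizedExperiment::assayNames(object))
    return("assay 'absorbance' is required")
  a <- SummarizedExperiment::assay(object, "absorbance")
  if (anyNA(a)) return("absorbance matrix contains missing values")
  ids <- colnames(object)
  if (is.null(ids) || anyDuplicated(ids)) return("sample ids must be unique")
  TRUE
})

#' PLSModel: a fitted, serializable PLS calibration
#'
#' Container for a NIPALS / wide-kernel PLS regression fitted on preprocessed
#' FTIR spectra, together with everything needed to reproduce its predictions:
#' the frozen preprocessing recipe, the retained-variable mask, centering
#' vectors, per-latent-variable weights and loadings, regression coefficients
#' and the offset/slope bias correction estimated from cross-validation.
#'
#' @slot recipe list; frozen preprocessing recipe (see [fitRecipe()]).
#' @slot wavenumbers numeric; the post-recipe grid the model was fitted on.
#' @slot mask logical; retained variables on that grid (all `TRUE` unless
#'   jackknife CI filtering was applied).
#' @slot nLv integer; number of latent variables.
#' @slot algorithm character; `"nipals"` or `"widekernel"`.
#' @slot weights,xLoadings matrix (p x nLv); X weights W and loadings P.
#' @slot yLoadings matrix (m x nLv); Y loadings Q.
#' @slot coefficients matrix (p x m); regression coefficients on centered data.
#' @slot xMeans,yMeans numeric; centering vectors fitted on calibration data.
#' @slot bias data.frame with columns `offset` and `slopeFactor`, one row per
#'   target; corrected prediction = (raw - offset) * slopeFactor.
#' @slot targets character; target names.
#' @slot units character; target units (parallel to `targets`).
#' @slot metrics list; training/cross-validation metrics as recorded at fit.
#' @slot version character; serialization schema version.
#' @export
setClass("PLSModel", representation(
  recipe = "list",
  wavenumbers = "numeric",
  mask = "logical",
  nLv = "integer",
  algorithm = "character",
  weights = "matrix",
  xLoadings = "matrix",
  yLoadings = "matrix",
  coefficients = "matrix",
  xMeans = "numeric",
  yMeans = "numeric",
  bias = "data.frame",
  targets = "character",
  units = "character",
  metrics = "list",
  version = "character"
))

setValidity("PLSModel", function(object) {
  p <- sum(object@mask)
  if (nrow(object@coefficients) != p)
    return("coefficient rows must match retained variables")
  if (object@nLv < 1L) return("nLv must be >= 1")
  if (length(object@targets) != ncol(object@coefficients))
    return("one coefficient column per target")
  if (length(object@mask) != length(object@wavenumbers))
    return("mask length must match wavenumber grid")
  TRUE
})

#' @describeIn SpectraSet-class compact display
#' @param object a `SpectraSet`
#' @export
setMethod("show", "SpectraSet", function(object) {
  wn <- wavenumbers(object)
  cat(sprintf("SpectraSet: %d spectra x %d wavenumbers (%.0f..%.0f cm-1)\n",
              ncol(object), length(wn), wn[1], wn[length(wn)]))
  tg <- S4Vectors::metadata(object)$targets
  if (!is.null(tg) && length(tg$name))
    cat("  reference targets:",
        paste(sprintf("%s (%s)", tg$name, tg$unit), collapse = ", "), "\n")
})

#' @describeIn PLSModel-class compact display
#' @param object a `PLSModel`
#' @export
setMethod("show", "PLSModel", function(object) {
  cat(sprintf("PLSModel (%s): %d LV, %d/%d variables retained\n",
              object@algorithm, object@nLv, sum(object@mask),
              length(object@mask)))
  cat("  targets:", paste(sprintf("%s (%s)", object@targets, object@units),
                          collapse = ", "), "\n")
  if (!is.null(object@metrics$RMSEC))
    cat("  RMSEC:", paste(signif(object@metrics$RMSEC, 4), collapse = ", "),
        "\n")
})
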