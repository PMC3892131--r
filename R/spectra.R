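#' Construct a SpectraSet
#'
#' Builds a [SpectraSet-class] from a wavenumber grid and a samples-by-
#' wavenumbers absorbance matrix. Grids supplied in ascending order are
#' flipped to the descending instrument convention (the flip is recorded in
#' `metadata(x)$flipped`).
#'
#' @param wavenumbers numeric grid in cm-1, strictly monotone.
#' @param absorbance numeric matrix, `n_samples x length(wavenumbers)`, in
#'   absorbance units (AU).
#' @param sampleIds unique sample identifiers; defaults to
#'   `rownames(absorbance)` or `spec_1..n`.
#' @param reference optional data.frame of known target values, one row per
#'   sample, in the same order.
#' @param units named character vector of units for the reference columns
#'   (defaults to `""`).
#' @return a `SpectraSet`.
#' @examples
#' wn <- seq(1800, 800, by = -4)
#' s <- SpectraSet(wn, matrix(rnorm(2 * length(wn)), 2))
#' @export
SpectraSet <- function(wavenumbers, absorbance, sampleIds = NULL,
                       reference = NULL, units = NULL) {
  if (is.vector(absorbance)) absorbance <- matrix(absorbance, nrow = 1)
  absorbance <- as.matrix(absorbance)
  stopifnot(is.numeric(wavenumbers), ncol(absorbance) == length(wavenumbers))
  flipped <- FALSE
  if (length(wavenumbers) >= 2 && wavenumbers[2] > wavenumbers[1]) {
    wavenumbers <- rev(wavenumbers)
    absorbance <- absorbance[, ncol(absorbance):1, drop = FALSE]
    flipped <- TRUE
  }
  if (is.null(sampleIds))
    sampleIds <- rownames(absorbance)
  if (is.null(sampleIds))
    sampleIds <- paste0("spec_", seq_len(nrow(absorbance)))
  if (anyDuplicated(sampleIds)) stop("duplicate sample_ids")
  cd <- S4Vectors::DataFrame(row.names = sampleIds)
  targets <- list(name = character(0), unit = character(0))
  if (!is.null(reference)) {
    reference <- as.data.frame(reference)
    if (nrow(reference) != nrow(absorbance))
      stop("reference not row-aligned with matrix")
    for (nm in names(reference)) cd[[nm]] <- reference[[nm]]
    un <- rep("", ncol(reference))
    names(un) <- names(reference)
    if (!is.null(units)) un[names(units)] <- units
    targets <- list(name = names(reference), unit = unname(un))
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(absorbance = t(absorbance)),
    rowData = S4Vectors::DataFrame(wavenumber = wavenumbers),
    colData = cd,
    metadata = list(targets = targets, flipped = flipped))
  methods::new("SpectraSet", se)
}

#' Accessors for SpectraSet
#'
#' @param x a [SpectraSet-class].
#' @return `wavenumbers()` the descending grid (cm-1); `spectraMatrix()` the
#'   `n_samples x n_wavenumbers` absorbance matrix; `sampleIds()` the sample
#'   identifiers; `referenceTable()` the reference target data.frame (or
#'   `NULL` when no targets are attached); `targetUnits()` a named character
#'   vector of target units.
#' @name spectra-accessors
NULL

#' @rdname spectra-accessors
#' @export
wavenumbers <- function(x) {
  stopifnot(methods::is(x, "SpectraSet"))
  SummarizedExperiment::rowData(x)$wavenumber
}

#' @rdname spectra-accessors
#' @export
spectraMatrix <- function(x) {
  stopifnot(methods::is(x, "SpectraSet"))
  m <- t(SummarizedExperiment::assay(x, "absorbance"))
  rownames(m) <- colnames(x)
  colnames(m) <- NULL
  m
}

#' @rdname spectra-accessors
#' @export
sampleIds <- function(x) colnames(x)

#' @rdname spectra-accessors
#' @export
referenceTable <- function(x) {
  tg <- S4Vectors::metadata(x)$targets
  if (is.null(tg) || length(tg$name) == 0) return(NULL)
  as.data.frame(SummarizedExperiment::colData(x)[, tg$name, drop = FALSE])
}

#' @rdname spectra-accessors
#' @export
targetUnits <- function(x) {
  tg <- S4Vectors::metadata(x)$targets
  if (is.null(tg)) return(character(0))
  stats::setNames(tg$unit, tg$name)
}

## internal: rebuild a SpectraSet with a new grid/matrix, keeping reference
.respectra <- function(x, wavenumbers, absorbance) {
  SpectraSet(wavenumbers, absorbance, sampleIds = sampleIds(x),
             reference = referenceTable(x), units = targetUnits(x))
}

#' Read spectra from a wide CSV table
#'
#' The canonical interchange format is a wide CSV: one spectrum per row, a
#' `sample_id` column, numeric column headers holding the wavenumber grid, and
#' optional reference columns whose names carry a `ref:` prefix (e.g.
#' `ref:sucrose`). Ascending grids are reoriented to descending.
#'
#' @param path path to the CSV file.
#' @return a [SpectraSet-class]; reference columns are split out of the
#'   spectral matrix into the reference table.
#' @seealso [writeSpectraTable()]
#' @export
readSpectraTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = NA)
  if (anyNA(raw)) stop("ragged rows or missing cells in ", path)
  nm <- names(raw)
  idCol <- which(nm == "sample_id")
  refCols <- grep("^ref:", nm)
  wnCols <- setdiff(seq_along(nm), c(idCol, refCols))
  wn <- suppressWarnings(as.numeric(nm[wnCols]))
  if (anyNA(wn)) stop("non-numeric header cell: ",
                      paste(nm[wnCols][is.na(wn)], collapse = ", "))
  ids <- if (length(idCol)) as.character(raw[[idCol]]) else NULL
  if (!is.null(ids) && anyDuplicated(ids)) stop("duplicate sample_ids")
  mat <- as.matrix(raw[, wnCols, drop = FALSE])
  if (!is.numeric(mat)) stop("non-numeric absorbance values")
  ref <- NULL
  if (length(refCols)) {
    ref <- raw[, refCols, drop = FALSE]
    names(ref) <- sub("^ref:", "", names(ref))
  }
  SpectraSet(wn, mat, sampleIds = ids, reference = ref)
}

#' Write spectra to a wide CSV table
#'
#' @param x a [SpectraSet-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeSpectraTable <- function(x, path) {
  mat <- spectraMatrix(x)
  df <- data.frame(sample_id = sampleIds(x), check.names = FALSE)
  ref <- referenceTable(x)
  if (!is.null(ref)) {
    names(ref) <- paste0("ref:", names(ref))
    df <- cbind(df, ref)
  }
  sp <- as.data.frame(mat)
  names(sp) <- format(wavenumbers(x), trim = TRUE, scientific = FALSE)
  df <- cbind(df, sp)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Truncate spectra to a wavenumber window
#'
#' Restricts the set to grid points inside `[wnLow, wnHigh]`, both ends
#' inclusive — on a 4 cm-1 grid the 1,180–900 cm-1 juice-sugar window retains
#' (1180-900)/4 + 1 = 71 points. Reference values are carried through
#' unchanged.
#'
#' @param x a [SpectraSet-class].
#' @param wnHigh,wnLow window bounds in cm-1, `wnHigh > wnLow`.
#' @return the truncated `SpectraSet`.
#' @export
truncateRegion <- function(x, wnHigh, wnLow) {
  if (wnHigh <= wnLow) stop("bounds inverted: wnHigh must exceed wnLow")
  wn <- wavenumbers(x)
  keep <- wn >= wnLow & wn <= wnHigh
  if (sum(keep) < 2) stop("empty selection: fewer than 2 grid points in window")
  .respectra(x, wn[keep], spectraMatrix(x)[, keep, drop = FALSE])
}

#' Interpolate spectra onto a new wavenumber grid
#'
#' Linear interpolation of every spectrum onto `targetGrid`; extrapolation is
#' refused. Linear interpolation keeps alignment monotone and bounded and is
#' exact for spectra affine in wavenumber.
#'
#' @param x a [SpectraSet-class].
#' @param targetGrid numeric grid (cm-1) within the span of `wavenumbers(x)`.
#' @return a `SpectraSet` on `targetGrid`.
#' @export
alignToGrid <- function(x, targetGrid) {
  wn <- wavenumbers(x)
  if (max(targetGrid) > max(wn) || min(targetGrid) < min(wn))
    stop("target grid outside source span; no extrapolation")
  tg <- sort(targetGrid, decreasing = TRUE)
  mat <- spectraMatrix(x)
  ## approx needs ascending x
  out <- t(apply(mat, 1, function(a)
    stats::approx(rev(wn), rev(a), xout = rev(tg))$y))
  out <- out[, ncol(out):1, drop = FALSE]
  .respectra(x, tg, out)
}
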