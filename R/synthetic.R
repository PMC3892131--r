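## Synthetic-data subsystem. Emulates the three data classes the pipeline
## consumes: (i) juice spectra as Beer-Lambert linear mixtures of overlapping
## pure-sugar component spectra on a water background, (ii) bagasse spectra
## whose digestibility is a noisy affine function of a latent cell-wall
## composition, corrupted by multiplicative scatter and additive baselines,
## and (iii) stalk populations obeying the frustum taper model with fixed
## internode-to-whole-stalk ratios. Every generator is a pure function of
## (parameters, seed).

.gaussianBands <- function(grid, bands) {
  out <- numeric(length(grid))
  for (i in seq_len(nrow(bands)))
    out <- out + bands$height[i] *
      exp(-(grid - bands$center[i])^2 / (2 * bands$width[i]^2))
  out
}

#' Generate a spectral component library
#'
#' Builds Gaussian-band component spectra for sucrose, glucose, fructose (4-8
#' bands each, concentrated in the 1,190-850 cm-1 sugar fingerprint window,
#' in AU per mM), a water background (one broad band near 1,635 cm-1, in AU),
#' and cellulose-, xylan- and lignin-like cell-wall components (AU per unit
#' mass fraction) across the 1,800-850 cm-1 region. Each sugar shares a band
#' position within 30 cm-1 of every other sugar, so the components overlap
#' and quantification genuinely requires multivariate regression rather than
#' single-band Beer's-law fits.
#'
#' @param seed integer; the library is a deterministic function of it.
#' @param grid wavenumber grid (cm-1), default 1,800 to 800 step 4.
#' @return object of class `componentLibrary`: list with `grid` and
#'   `components` (named list of band tables `center`, `width`, `height`).
#' @export
makeComponentLibrary <- function(seed, grid = seq(1800, 800, by = -4)) {
  withr::with_seed(seed, {
    sugars <- c("sucrose", "glucose", "fructose")
    anchor <- stats::runif(1, 960, 1100)
    comps <- list()
    for (sg in sugars) {
      nb <- sample(4:8, 1)
      centers <- c(anchor + stats::runif(1, -10, 10),
                   stats::runif(nb - 1, 870, 1150))
      comps[[sg]] <- data.frame(
        center = centers,
        width = stats::runif(nb, 8, 25),
        height = stats::runif(nb, 5e-4, 1.5e-3))
    }
    comps$water <- data.frame(center = 1635, width = 80, height = 0.4)
    ## cell-wall components occupy largely distinct sub-regions, as real
    ## polysaccharide C-O (cellulose ~950-1180), hemicellulose/acetyl
    ## (~1190-1470) and aromatic lignin (~1480-1750) bands do; the Gaussian
    ## tails still overlap at region boundaries
    cwRegions <- list(cellulose = c(950, 1180), xylan = c(1190, 1470),
                      lignin = c(1480, 1750))
    for (cw in names(cwRegions)) {
      nb <- sample(5:7, 1)
      comps[[cw]] <- data.frame(
        center = stats::runif(nb, cwRegions[[cw]][1], cwRegions[[cw]][2]),
        width = stats::runif(nb, 10, 30),
        height = stats::runif(nb, 0.1, 0.4))
    }
    lib <- structure(list(grid = grid, components = comps, seed = seed),
                     class = "componentLibrary")
    .equalizeCellWall(lib)
  })
}

## Scale the cell-wall components to equal effective absorptivity: each pure
## component is given a unit EMSC reference coefficient in the standard
## bagasse preprocessing domain (1,800-850 cm-1, 9-point SG second
## derivative, poly-2 baseline). EMSC coefficients are linear in the
## spectrum, so every convex mixture of the scaled components then has
## b ~= 1 and the scatter correction preserves the linear mixture model --
## the analog of mass-based absorptivity in real powders, where per-mg
## spectra of different wall polymers have comparable intensity.
.equalizeCellWall <- function(lib, iters = 50) {
  cw <- c("cellulose", "xylan", "lignin")
  probe <- SpectraSet(lib$grid,
                      do.call(rbind, lapply(cw, function(a)
                        componentSpectrum(lib, a, 1))))
  dd <- spectraMatrix(sgFilter(truncateRegion(probe, 1800, 850),
                               9, 2, 2))
  wn <- seq_len(ncol(dd))
  nu <- (wn - mean(wn)) / length(wn)
  B <- cbind(1, nu, nu^2)
  M <- diag(length(nu)) - B %*% solve(crossprod(B), t(B))
  z <- dd %*% M  # poly-projected pure-component spectra (rows)
  s <- rep(1, 3)
  for (it in seq_len(iters)) {
    mM <- colMeans(s * z)
    b <- (s * (z %*% mM)) / sum(mM^2)
    if (any(b <= 0)) break  # pathological library; leave scales as-is
    ## b is ~quadratic in s, so damp with a square root: for a diagonal
    ## Gram this lands on the fixed point in a single step
    s <- s / sqrt(as.numeric(b))
    s <- s / mean(s)
  }
  for (j in seq_along(cw))
    lib$components[[cw[j]]]$height <- lib$components[[cw[j]]]$height * s[j]
  lib
}

#' Evaluate a component spectrum on the library grid
#'
#' @param lib a `componentLibrary`.
#' @param name component name.
#' @param conc concentration multiplier (mM for sugars, mass fraction for
#'   cell-wall components, 1 for water).
#' @return absorbance vector (AU) on `lib$grid`.
#' @export
componentSpectrum <- function(lib, name, conc = 1) {
  bands <- lib$components[[name]]
  if (is.null(bands)) stop("unknown component: ", name)
  conc * .gaussianBands(lib$grid, bands)
}

#' Full-factorial calibration mixture design
#'
#' Cartesian product of equally spaced concentration levels per sugar. The
#' default 6 x 6 x 6 design gives the 216-mixture calibration set; the
#' default ranges (sucrose 0-600, glucose 0-300, fructose 0-150 mM) bracket
#' the concentrations observed in sweet sorghum juice (roughly 120-461 /
#' 52-126 / 22-70 mM for low to high juices).
#'
#' @param levels named integer vector of levels per sugar.
#' @param ranges named list of `c(lo, hi)` concentration ranges (mM).
#' @return data.frame of mixture concentrations, one row per mixture, with
#'   attribute `ranges`.
#' @export
factorialDesign <- function(levels = c(sucrose = 6, glucose = 6, fructose = 6),
                            ranges = list(sucrose = c(0, 600),
                                          glucose = c(0, 300),
                                          fructose = c(0, 150))) {
  stopifnot(all(levels >= 1))
  grids <- lapply(names(levels), function(a) {
    rg <- ranges[[a]]
    if (is.null(rg) || rg[1] > rg[2]) stop("invalid range for ", a)
    if (levels[[a]] == 1) rg[1] else seq(rg[1], rg[2],
                                         length.out = levels[[a]])
  })
  names(grids) <- names(levels)
  des <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE)
  attr(des, "ranges") <- ranges
  des
}

#' Random (uniform) mixture design
#'
#' @param n number of mixtures.
#' @param ranges as in [factorialDesign()].
#' @param seed integer seed.
#' @return data.frame of concentrations with attribute `ranges`.
#' @export
randomDesign <- function(n, ranges = list(sucrose = c(0, 600),
                                          glucose = c(0, 300),
                                          fructose = c(0, 150)), seed = 1) {
  withr::with_seed(seed, {
    des <- as.data.frame(lapply(ranges, function(rg)
      stats::runif(n, rg[1], rg[2])))
    attr(des, "ranges") <- ranges
    des
  })
}

#' Default spectral noise level for juice simulations
#'
#' 0.2% of the maximum sugar band absorbance at mid-range concentrations —
#' a noise floor at which the simulated calibration behaves like a
#' well-maintained ATR accessory (validation errors a few percent of the
#' calibration range).
#'
#' @param lib a `componentLibrary`.
#' @param ranges concentration ranges as in [factorialDesign()].
#' @return noise standard deviation in AU.
#' @export
defaultJuiceNoiseSd <- function(lib, ranges = list(sucrose = c(0, 600),
                                                   glucose = c(0, 300),
                                                   fructose = c(0, 150))) {
  peak <- max(vapply(names(ranges), function(a)
    max(componentSpectrum(lib, a, mean(ranges[[a]]))), numeric(1)))
  0.002 * peak
}

#' Simulate juice FTIR spectra from a mixture design
#'
#' Beer-Lambert linear mixing: `A(nu) = water(nu) + sum_i c_i * eps_i(nu) +
#' N(0, noiseSd)` per grid point. The design concentrations are attached as
#' the reference table (mM).
#'
#' @param design data.frame of sugar concentrations (mM), e.g. from
#'   [factorialDesign()].
#' @param lib a `componentLibrary`.
#' @param noiseSd iid Gaussian noise SD in AU (default
#'   [defaultJuiceNoiseSd()]).
#' @param seed integer seed.
#' @return a [SpectraSet-class] with reference concentrations.
#' @export
simulateJuiceSpectra <- function(design, lib, noiseSd = NULL, seed = 1) {
  if (is.null(noiseSd)) noiseSd <- defaultJuiceNoiseSd(lib)
  if (noiseSd < 0) stop("negative noise")
  grid <- lib$grid
  water <- componentSpectrum(lib, "water")
  E <- vapply(names(design), function(a) componentSpectrum(lib, a, 1),
              numeric(length(grid)))
  withr::with_seed(seed, {
    mat <- as.matrix(design) %*% t(E) +
      matrix(water, nrow(design), length(grid), byrow = TRUE)
    if (noiseSd > 0)
      mat <- mat + matrix(stats::rnorm(length(mat), 0, noiseSd),
                          nrow(mat))
    SpectraSet(grid, mat,
               sampleIds = sprintf("mix_%03d", seq_len(nrow(design))),
               reference = design,
               units = stats::setNames(rep("mM", ncol(design)),
                                       names(design)))
  })
}

#' Simulate a bagasse spectral set with digestibility reference
#'
#' Each sample draws a latent cell-wall composition `x` (cellulose, xylan,
#' lignin fractions on the simplex); its spectrum is
#' `(sum_j x_j * eps_j(nu)) * m + a + N(0, noiseSdSpectral)` with
#' multiplicative scatter `m ~ LogNormal(0, scatterSdLog)` and additive
#' offset `a ~ N(0, offsetSd)` — the artefacts EMSC exists to remove.
#' Digestibility is an affine function of the composition (increasing in
#' cellulose, decreasing in lignin), min-max scaled onto `dRange`, plus
#' `N(0, noiseSdD)`.
#'
#' @param n number of samples (>= 2).
#' @param lib a `componentLibrary`.
#' @param dRange digestibility range (ug.mgDW-1.h-1); the default 0.95-12.1
#'   matches the spread of a diverse field population.
#' @param noiseSdSpectral spectral noise SD (AU).
#' @param noiseSdD digestibility reference noise SD.
#' @param scatterSdLog log-SD of the multiplicative scatter term.
#' @param offsetSd SD of the additive baseline offset (AU).
#' @param seed integer seed.
#' @return a [SpectraSet-class] with a `digestibility` reference column; the
#'   noise-free digestibility and the latent compositions are stored in
#'   `metadata(x)$truth`.
#' @export
simulateBagasseSet <- function(n, lib, dRange = c(0.95, 12.1),
                               noiseSdSpectral = 0.002, noiseSdD = 0.3,
                               scatterSdLog = 0.05, offsetSd = 0.01,
                               seed = 1) {
  if (n < 2) stop("n must be >= 2")
  if (dRange[1] >= dRange[2]) stop("invalid digestibility range")
  grid <- lib$grid
  E <- vapply(c("cellulose", "xylan", "lignin"),
              function(a) componentSpectrum(lib, a, 1),
              numeric(length(grid)))
  withr::with_seed(seed, {
    g <- matrix(stats::rgamma(3 * n, shape = 1), n)  # uniform on the simplex
    x <- g / rowSums(g)
    ## fixed affine map: score is 1 at the pure-cellulose vertex, 0.4 at pure
    ## xylan, -0.8 at pure lignin, so the simplex maps exactly onto dRange --
    ## the same map for every generated set, so calibration and validation
    ## sets share one digestibility/composition relationship
    score <- x[, 1] + 0.4 * x[, 2] - 0.8 * x[, 3]
    d0 <- dRange[1] + (score + 0.8) / 1.8 * (dRange[2] - dRange[1])
    d <- d0 + stats::rnorm(n, 0, noiseSdD)
    m <- stats::rlnorm(n, 0, scatterSdLog)
    a <- stats::rnorm(n, 0, offsetSd)
    mat <- (x %*% t(E)) * m + a
    if (noiseSdSpectral > 0)
      mat <- mat + matrix(stats::rnorm(length(mat), 0, noiseSdSpectral),
                          nrow(mat))
    out <- SpectraSet(grid, mat,
                      sampleIds = sprintf("bag_%03d", seq_len(n)),
                      reference = data.frame(digestibility = d),
                      units = c(digestibility = "ug.mgDW-1.h-1"))
    S4Vectors::metadata(out)$truth <- list(composition = x,
                                           digestibility_true = d0)
    out
  })
}

#' Simulate a paired stalk population under the frustum / fixed-ratio model
#'
#' Draws stalk geometries and whole-stalk truths matching a mature sweet
#' sorghum field population (heights 237-338 cm, fresh weights 228-941 g,
#' juice sugars and digestibility over their observed spreads), computes each
#' stalk's `V_ratio`, and generates fourth-internode measurements as
#' `whole-stalk value x V_ratio (extensive analytes only) x fixed ratio x
#' (1 + N(0, noiseCv))`. Whole-stalk truths are retained so recovery can be
#' checked.
#'
#' @param n number of stalks (>= 3).
#' @param ratios fixed-ratio table as from [defaultFixedRatios()].
#' @param noiseCv multiplicative noise CV on internode measurements.
#' @param seed integer seed.
#' @return data.frame with `sample_id`, geometry (`H`, `R`, `r`, `HB`,
#'   `LSI`), `v_ratio`, whole-stalk truths (`ws_*`) and internode
#'   measurements (`in_*`).
#' @export
simulateStalkPopulation <- function(n, ratios = defaultFixedRatios(),
                                    noiseCv = 0.05, seed = 1) {
  if (n < 3) stop("n must be >= 3")
  if (noiseCv < 0) stop("invalid noise")
  withr::with_seed(seed, {
    H <- stats::runif(n, 237, 338)
    R <- stats::runif(n, 0.7, 1.3)
    r <- R * stats::runif(n, 0.5, 0.95)
    HB <- H * stats::runif(n, 0.05, 0.45)
    LSI <- H * stats::runif(n, 0.05, 0.15)
    df <- data.frame(sample_id = sprintf("stalk_%04d", seq_len(n)),
                     H = H, R = R, r = r, HB = HB, LSI = LSI)
    df$v_ratio <- volumetricRatio(H, R, r, HB, LSI)
    df$ws_FW <- stats::runif(n, 228, 941)
    df$ws_DW <- df$ws_FW * stats::runif(n, 0.2, 0.35)
    df$ws_sucrose <- stats::runif(n, 120, 461)
    df$ws_glucose <- stats::runif(n, 52, 126)
    df$ws_fructose <- stats::runif(n, 22, 70)
    df$ws_digestibility <- stats::runif(n, 0.95, 12.1)
    for (i in seq_len(nrow(ratios))) {
      a <- ratios$analyte[i]
      scale <- if (ratios$extensive[i]) df$v_ratio else 1
      df[[paste0("in_", a)]] <- df[[paste0("ws_", a)]] * scale *
        ratios$ratio[i] * (1 + stats::rnorm(n, 0, noiseCv))
    }
    df
  })
}
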