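---
title: "Methods: models, parameters and design choices in stalkscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in stalkscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stalkscreen)
```

# Overview

`stalkscreen` estimates the total fermentable sugar yield of a grass stalk
as `V·[S] + B·D`: juice volume times total soluble sugar concentration,
plus dry biomass times enzymatic cell-wall digestibility over a 24-hour
cellulase digestion. Its three model components — the conical-frustum stalk
geometry, the juice-sugar PLS calibration, and the bagasse digestibility
PLS calibration — are described here together with the assumptions behind
them, the parameters a user may want to change, and the numerical decisions
taken where the design was genuinely open.

# The frustum stalk model

A stalk is modelled as a frustum of a cone: radius tapers linearly from `R`
at the base to `r` at the top over height `H` (all cm), so

$$V_{WS} = \frac{\pi H}{3}\left(r^2 + rR + R^2\right),$$

and the sampled internode occupying `[H_B, H_B + L_{SI}]` has volume given
by the same formula on its own end radii, obtained from the linear taper.
`volumetricRatio()` returns `V_ratio = V_SI / V_WS`.

Assumptions and conventions:

* **Extensive vs intensive analytes.** Dividing by `V_ratio` converts an
  *amount* measured on the internode (fresh weight, dry weight, a mass of
  sugar) into a whole-stalk amount. Concentrations and rates
  (mM, μg·mgDW⁻¹·h⁻¹) are volume-independent, so only the empirical fixed
  internode/whole-stalk ratio applies to them. The shipped
  `defaultFixedRatios()` table records, per analyte, both the ratio (FW
  0.91, DW 1.00, sucrose 0.97, glucose 1.05, fructose 0.97, digestibility
  1.29, each with a standard error) and the extensive flag. These ratios
  are species- and protocol-specific; `estimateFixedRatios()` re-estimates
  them from paired internode/whole-stalk measurements (at least 3 pairs,
  reporting the mean ratio, its SE, the Pearson correlation and RMSEP as a
  percentage of the whole-stalk mean).
* **Field sheets record diameters**; `readFieldTable()` halves them once at
  ingest and everything downstream works in radii.
* **Inverted tapers are rejected.** Geometries with `R < r` violate the
  frustum assumption the extrapolation rests on; the constructor errors
  rather than silently extrapolating a widening stalk.
* **Juice volume** is taken as whole-stalk water content, `(FW − DW)` g at
  1 g/mL. This treats the relative water content as pressable juice; a
  `density` argument lets users fold in an extraction-efficiency or density
  correction. It is one admissible reading of converting stalk water
  content to juice volume, and is flagged as such.

# Spectral preprocessing

All pretreatment is expressed as a *recipe*: an ordered list of steps
fitted once on calibration spectra and then frozen, so prediction-time
preprocessing is provably identical to calibration-time (the fitted state
serializes with the model JSON).

* **Truncation** is inclusive at both window ends. On a 4 cm⁻¹ grid the
  juice-sugar window 1,180–900 cm⁻¹ keeps exactly 71 points; the cell-wall
  fingerprint window is 1,800–850 cm⁻¹.
* **Savitzky–Golay** filtering uses a 9-point window by default. The
  polynomial order is not recoverable from common instrument-software
  descriptions of "9-point smoothing", so it is a parameter with default 2
  (the classic quadratic window), recorded in the recipe. Derivatives are
  scaled by the grid spacing so a second derivative is in AU·cm². Edge
  handling: the output shrinks to fully supported windows — 4 points per
  end for a 9-point filter — rather than padding, so no fabricated edge
  values enter the regression.
* **EMSC** regresses each spectrum on a constant, linear and quadratic
  wavenumber term plus the mean calibration spectrum (the standard
  "extended" basis; the basis choice is logged in the recipe), then
  corrects as `(s − baseline)/b`. Spectra nearly orthogonal to the
  reference (|b| < 1e-8) are rejected as degenerate rather than amplified.
* **Mean centering** is fitted on calibration data only. In the shipped
  workflows centering happens inside the PLS fit; the `mean_center` recipe
  step exists for recipes that need it explicitly.

# PLS calibration

Both fitting routes solve the same bilinear model on mean-centered data and
agree in their predictions:

* **NIPALS** deflates X and Y component by component, iterating scores to a
  1e-12 relative tolerance (max 500 iterations; a single pass is exact for
  one response). The iteration starts from the response column of maximal
  variance.
* **Wide-kernel PLS** works on the n×n association matrix XX′, suited to
  spectral matrices with many more wavenumbers than samples. Rather than a
  power iteration — which stalls when leading eigenvalues nearly tie — the
  dominant component is computed exactly from the m×m symmetric eigenproblem
  `Y′XX′Y v = λv`, with `t ∝ XX′Yv`.

Components beyond the effective rank of the centered data are numerically
arbitrary; cross-validation therefore caps the assessed component count at
that rank, and the fitters refuse to fit past it.

Model-building follows the screening workflow:

* **"Full" cross-validation is leave-one-out** (the established meaning of
  the term in chemometrics software), with a default ceiling of 15 factors.
  RMSECV per component count is pooled from the out-of-fold predictions,
  which are retained for bias calibration.
* **Component choice** uses a parsimony rule: the smallest count whose
  RMSECV is within 1% of the minimum, ties breaking toward fewer. The
  shipped juice defaults (6 LVs for sucrose and fructose, 9 for glucose)
  reproduce the screening configuration; passing `nLv = NULL` selects by
  the rule instead. Which count a given dataset favours is data-dependent,
  so the package records the choice in the model metadata rather than
  hard-coding it.
* **Variable filtering** (digestibility workflow) uses Martens' jackknife
  over the LOO refits: coefficient variance `((n−1)/n)·Σ(bᵢ − b̄)²`, a
  normal-approximation CI at level 1−α (default α = 0.10, i.e. a 90% CI),
  and removal of variables whose CI spans zero, followed by a refit on the
  retained wavenumbers. The jackknife flavour is a declared choice — the
  CI construction is not otherwise pinned down — and is logged with the
  model. Removing every variable is an error, not an empty model.
* **Bias correction** fits `pred = a + b·ref` by OLS on the out-of-fold
  pairs; predictions are corrected as `(raw − a)·(1/b)`, with the slope
  factor applied only when |b − 1| exceeds a 1% dead-band. For juice
  models the offset is, in effect, the water background. Negative corrected
  concentrations are reported and flagged, never clamped, so error
  statistics stay honest.
* **Outlier diagnostics** (`detectOutliers()`) report studentized
  y-residuals and score-space leverages (`h = 1/n + t′(T′T)⁻¹t`, summing to
  `nLv + 1` under the intercept convention). Mirroring manual-review
  practice, flagged samples are never removed automatically.
* **Limit of detection** is estimated ICH-style as 3.3× the SD of
  bias-corrected predictions on ≥10 blank spectra — one admissible reading
  of a conservatively stated detection limit, documented as such.

# The synthetic-data subsystem

The generators encode the study conditions every test and the acceptance
script run under; they are pure functions of their parameters and seed.

* **Juice spectra** are Beer–Lambert linear mixtures: a fixed water
  background (broad band at 1,635 cm⁻¹) plus per-sugar Gaussian band sets
  (4–8 bands each, concentrated in the 1,190–850 cm⁻¹ fingerprint) and iid
  Gaussian noise. Every sugar pair shares a band position within 30 cm⁻¹,
  so single-band Beer's-law quantification genuinely fails and multivariate
  calibration is required. The default calibration design is the full
  6×6×6 factorial — 216 mixtures — over sucrose 0–600, glucose 0–300,
  fructose 0–150 mM, ranges bracketing observed low/medium/high sweet
  sorghum juices (roughly 120–461 / 52–126 / 22–70 mM). The default noise
  SD is 0.2% of the maximum sugar band height at mid-range concentration,
  a level representative of a well-maintained ATR accessory.
* **Bagasse spectra** draw a latent cellulose/xylan/lignin composition
  uniformly on the simplex; the spectrum is the composition-weighted sum of
  component spectra times a multiplicative scatter factor
  (LogNormal(0, 0.05)) plus an additive baseline offset (N(0, 0.01 AU)) —
  exactly the artefacts EMSC exists to remove — plus spectral noise.
  Digestibility is a *fixed* affine function of composition (increasing in
  cellulose, decreasing in lignin) mapping the simplex onto
  0.95–12.1 μg·mgDW⁻¹·h⁻¹, plus reference noise (default SD 0.3,
  representing DNS-assay repeatability). Two design details matter:
  the affine map is anchored to the simplex vertices, not rescaled per
  generated set, so calibration and validation sets share one
  digestibility/composition relationship; and each cell-wall component is
  normalized to a unit EMSC reference coefficient in the standard
  preprocessing domain, the analog of comparable per-mg absorptivity across
  wall polymers. Without that normalization the EMSC division would turn
  the linear mixture into a projective one and no linear calibration could
  be exact even at zero noise. Component bands occupy largely distinct
  sub-regions (cellulose-like ~950–1,180, xylan-like ~1,190–1,470,
  lignin-like ~1,480–1,750 cm⁻¹), as real polysaccharide and aromatic
  bands do.
* **Stalk populations** draw heights uniformly on 237–338 cm and whole-stalk
  fresh weights on 228–941 g (a mature field population), radii with
  `R ≥ r`, internode positions respecting the geometry invariants, dry
  matter fractions of 20–35%, juice sugars and digestibility over their
  observed spreads; internode measurements follow the fixed-ratio model
  with multiplicative noise of a chosen CV. Whole-stalk truths are retained
  so recovery can be verified.

What the generators deliberately do **not** emulate: ATR penetration-depth
and Mie-scattering physics, instrument line shapes, atmospheric CO₂/water
vapour bands, band shifts with temperature or matrix, multi-tiller plants,
and leaf/sheath biomass. Passing tests therefore demonstrate that the
pipeline's statistical machinery is correct under its own assumptions — not
that a particular real instrument and field protocol will reach the same
error levels.

# Numerical choices and degenerate inputs

* NIPALS/eigen tolerances are fixed (1e-12, max 500 iterations);
  non-convergence is an error, never silently accepted.
* LV ties break toward fewer components; the parsimony tolerance is 1%.
* Grids are stored descending (instrument convention); ascending input is
  flipped once at ingest and the flip recorded. Interpolation between grids
  is linear only — monotone and bounded — and refuses extrapolation.
* Degenerate cases error with specific messages: empty truncation windows,
  EMSC on spectra orthogonal to the reference, constant references in bias
  calibration, empty post-filter models, predictions on grids that do not
  cover the model's wavenumbers, `DW > FW`, inverted frustums, internodes
  extending past the stalk tip. Yield computation flags a bad row and
  continues with the rest; an empty join is an error.

# Problem sizes

The shipped test-suite and acceptance runs use the study-scale sizes: the
216-mixture calibration with a 100-sample independent validation set for
the sugar models; 52 calibration / 38 validation bagasse spectra for
digestibility; 1,000-stalk populations (200 for ratio re-estimation at 5%
noise; 120/60 for the zero-noise digestibility identity, where the
residual EMSC-reference error shrinks as 1/√n). Property checks run over
1,000 random geometries and 100 random regression instances.

# Known limitations

* The frustum extrapolation presumes the sampled internode's chemistry is a
  fixed ratio of the whole stalk's; genotypes violating that (e.g. a
  lower-stem-specific mutation) will be mis-extrapolated, surfacing — at
  best — as outliers.
* Fixed ratios are protocol- and species-specific and must be re-estimated
  outside sweet sorghum.
* PLS models only interpolate: samples outside the calibration
  concentration or digestibility range are flagged as extrapolations and
  should be re-measured and folded into the calibration.
* The digestibility value is specific to the hydrolysis protocol behind the
  reference assay; a model calibrated against one enzyme cocktail and
  pretreatment does not transfer to another.
* Reducing sugar released in digestion is counted 1:1 as fermentable sugar,
  and the digestion duration (default 24 h) is a parameter, not a
  prediction.
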