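# stalkscreen

High-throughput screening of grass biofuel feedstocks (sweet sorghum and
relatives) for **total fermentable sugar yield per stalk**. Breeding programs
need to rank thousands of plants by how much fermentable sugar each stalk can
deliver, but the contributing measurements — juice volume, juice sugar
concentrations, stalk biomass and cell-wall digestibility — are slow and
expensive to obtain by wet chemistry on whole stalks. `stalkscreen`
implements a calculation-based alternative: measure one internode, predict
its chemistry from FTIR-ATR spectra, and extrapolate to the whole stalk
through a geometric taper model.

The yield decomposition at the core of the package is

```
V·[S] + B·D = total fermentable sugar yield
```

where `V` is juice volume per stalk (mL), `[S]` total soluble sugar
(g/100 mL), `B` dry biomass (g DW) and `D` enzymatic cell-wall digestibility
(μg reducing sugar·mgDW⁻¹·h⁻¹, over a 24-h cellulase digestion).

Three model components feed that equation:

1. **Stalk geometry.** A stalk is treated as a conical frustum:
   `V_WS = πH/3·(r² + rR + R²)` from height `H` and base/top radii `R`, `r`.
   The sampled internode's volume follows from the linear taper, and the
   volumetric ratio `V_ratio = V_SI/V_WS` extrapolates internode
   measurements to whole stalks (extensive quantities divide by `V_ratio`;
   concentrations and rates use fixed internode/whole-stalk ratios, shipped
   as `defaultFixedRatios()` and re-estimable with `estimateFixedRatios()`).
2. **Juice sugar chemometrics.** Sucrose, glucose and fructose (mM) are
   predicted from mid-IR juice spectra by per-sugar NIPALS PLS regressions:
   truncation to the 1,180–900 cm⁻¹ window, 9-point Savitzky–Golay
   smoothing, mean centering, leave-one-out cross-validation, and an
   offset/slope bias correction estimated from the cross-validation
   predictions.
3. **Digestibility chemometrics.** Cell-wall digestibility is predicted from
   bagasse spectra: 1,800–850 cm⁻¹ window, 9-point Savitzky–Golay second
   derivative, extended multiplicative scatter correction (EMSC),
   wide-kernel PLS with the latent-variable count chosen by cross-validation
   and a 90% jackknife confidence-interval filter on the regression
   coefficients.

A synthetic-data subsystem (`makeComponentLibrary()`,
`simulateJuiceSpectra()`, `simulateBagasseSet()`,
`simulateStalkPopulation()`) generates spectra and stalk populations with
the statistical structure the pipeline assumes, so every stage is testable
without instrument or field data.

## Worked example

Calibrate sugar models on a simulated 216-mixture set, predict a juice
sample, and compute a stalk's yield:

```r
library(stalkscreen)

lib    <- makeComponentLibrary(seed = 1)
cal    <- simulateJuiceSpectra(factorialDesign(), lib, seed = 1)
models <- calibrateSugarModels(cal)
attr(models, "metrics")
#>     target nLv nVars RMSEC R2 RMSECV
#> 1  sucrose   6    63 0.179  1  0.207
#> 2  glucose   9    63 0.253  1  0.321
#> 3 fructose   6    63 0.387  1  0.461

## a juice sample at 120/52/22 mM (a typical 'low' juice)
juice <- simulateJuiceSpectra(
  data.frame(sucrose = 120, glucose = 52, fructose = 22), lib, seed = 7)
sapply(models, function(m) predictSpectra(m, juice)[1, 1])
#>  sucrose  glucose fructose
#>    119.8     51.9     22.4
```

RMSEC/RMSECV are in mM: the models recover the design concentrations to a
few tenths of a millimolar at the default noise level, and the predicted
concentrations match the known sample within the cross-validation error.
Combining predictions with field geometry (heights in cm, internode
fresh/dry weight in g):

```r
ft <- data.frame(sample_id = "s1", H = 300, R = 1.1, r = 0.8,
                 HB = 60, LSI = 25, FW = 55, DW = 14)
sp <- data.frame(sample_id = "s1", sucrose = 119.8, glucose = 51.9,
                 fructose = 22.4)
dp <- data.frame(sample_id = "s1", digestibility = 6.4)
computeStalkYields(ft, sp, dp)
#>   sample_id  V_mL S_g_per_100mL B_gDW     D soluble_g cell_wall_g total_g
#> 1        s1 480.3         5.534 144.8 4.961     26.58       17.24   43.82
```

This stalk would deliver ≈ 44 g of fermentable sugar: 26.6 g from the juice
fraction (480 mL at 5.5 g/100 mL) and 17.2 g from 24-h cellulase digestion
of 145 g of dry biomass at 5.0 μg·mgDW⁻¹·h⁻¹.

The same stages are scriptable from a shell via the thin CLI at
`system.file("scripts", "stalkscreen.R", package = "stalkscreen")`, with
subcommands `simulate | calibrate | predict | yield` driven by a YAML
config.

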