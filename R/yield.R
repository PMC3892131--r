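## Total fermentable sugar yield: V.[S] + B.D. Soluble sugars come from the
## juice fraction (volume V in mL, total sugar [S] in g/100 mL); cell-wall
## sugars from enzymatic digestion of the dry biomass (B in g DW) at rate D
## (ug reducing sugar per mg DW per hour) over a 24-h digestion.

.MOLAR_MASS <- c(sucrose = 342.30, glucose = 180.16, fructose = 180.16)

#' Convert a molar sugar concentration to g/100 mL
#'
#' `g/100 mL = conc(mM) * M(g/mol) / 10000`, with molar masses
#' sucrose 342.30, glucose 180.16, fructose 180.16 g/mol.
#'
#' @param conc concentration in mM (>= 0).
#' @param analyte one of `"sucrose"`, `"glucose"`, `"fructose"`.
#' @return concentration in g/100 mL.
#' @examples
#' molarToMassConc(100, "sucrose")  # 3.4230
#' @export
molarToMassConc <- function(conc, analyte) {
  analyte <- match.arg(analyte, names(.MOLAR_MASS))
  if (any(conc < 0)) stop("negative concentration")
  conc * .MOLAR_MASS[[analyte]] / 1e4
}

#' Total soluble sugar concentration
#'
#' Sum of sucrose, glucose and fructose after conversion to g/100 mL.
#'
#' @param sucrose,glucose,fructose concentrations in mM.
#' @return total sugars in g/100 mL.
#' @export
totalSugarConc <- function(sucrose, glucose, fructose) {
  molarToMassConc(sucrose, "sucrose") + molarToMassConc(glucose, "glucose") +
    molarToMassConc(fructose, "fructose")
}

#' Juice volume from fresh and dry weight
#'
#' The pressed-juice volume per stalk is taken as the whole-stalk water
#' content, `FW - DW` grams at a density of `density` g/mL (default 1). The
#' density (or an effective extraction-efficiency factor folded into it) is
#' overridable.
#'
#' @param FW,DW whole-stalk fresh and dry weight (g), `FW >= DW`.
#' @param density g water per mL of juice.
#' @return juice volume in mL.
#' @export
juiceVolumeEstimate <- function(FW, DW, density = 1) {
  if (any(DW > FW)) stop("DW exceeds FW")
  if (any(FW < 0) || any(DW < 0)) stop("negative weight")
  (FW - DW) / density
}

#' Cell-wall fermentable sugar mass from digestibility
#'
#' `g = D (ug.mgDW-1.h-1) * B (g -> mg) * hours * 1e-6 (ug -> g)`; released
#' reducing sugar is counted 1:1 as fermentable sugar.
#'
#' @param B whole-stalk dry biomass (g DW).
#' @param D digestibility (ug reducing sugar per mg DW per hour).
#' @param hours digestion time; the standard cellulase assay digestion is
#'   24 h.
#' @return grams of cell-wall-derived sugar.
#' @export
cellWallSugarYield <- function(B, D, hours = 24) {
  if (any(B < 0) || any(D < 0) || any(hours < 0)) stop("negative input")
  D * (B * 1000) * hours * 1e-6
}

#' Total fermentable sugar yield per stalk
#'
#' `soluble = V/100 * S_total`; `cellWall = cellWallSugarYield(B, D, hours)`;
#' `total = soluble + cellWall`.
#'
#' @param V juice volume (mL).
#' @param S_total total soluble sugar concentration (g/100 mL).
#' @param B dry biomass (g DW).
#' @param D digestibility (ug.mgDW-1.h-1).
#' @param hours digestion time (h).
#' @return data.frame with `soluble_g`, `cell_wall_g`, `total_g` (vectorized
#'   over stalks).
#' @examples
#' totalFermentableYield(V = 400, S_total = 10, B = 100, D = 5)  # 52 g
#' @export
totalFermentableYield <- function(V, S_total, B, D, hours = 24) {
  if (any(V < 0) || any(S_total < 0)) stop("negative input")
  soluble <- V / 100 * S_total
  cw <- cellWallSugarYield(B, D, hours)
  data.frame(soluble_g = soluble, cell_wall_g = cw, total_g = soluble + cw)
}
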