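## Conical-frustum stalk model. A grass stalk is treated as a frustum of a
## cone with base radius R, top radius r and height H; the sampled internode
## is the segment [H_B, H_B + L_SI] of the linear taper. All lengths in cm,
## volumes in cm^3. Functions are vectorized over stalks.

.checkGeometry <- function(H, R, r, HB = NULL, LSI = NULL) {
  if (any(H <= 0)) stop("H must be positive")
  if (any(R <= 0) || any(r <= 0)) stop("radii must be positive")
  if (any(R < r)) stop("inverted taper (R < r) is not supported")
  if (!is.null(HB)) {
    if (any(HB < 0) || any(LSI <= 0)) stop("H_B >= 0 and L_SI > 0 required")
    if (any(HB + LSI > H + 1e-9)) stop("internode extends beyond stalk top")
  }
  invisible(TRUE)
}

#' Whole-stalk volume under the conical-frustum model
#'
#' `V_WS = pi * H / 3 * (r^2 + r*R + R^2)`.
#'
#' @param H stalk height (cm).
#' @param R base radius (cm).
#' @param r top radius (cm), `r <= R`.
#' @return volume in cm^3 (vectorized).
#' @examples
#' wholeStalkVolume(3, 1, 1)  # cylinder limit: 3*pi
#' @export
wholeStalkVolume <- function(H, R, r) {
  .checkGeometry(H, R, r)
  pi * H / 3 * (r^2 + r * R + R^2)
}

#' Radii at the ends of the sampled internode
#'
#' Linear taper: `R_I = R - H_B*(R - r)/H` at the internode base and
#' `r_I = R - (H_B + L_SI)*(R - r)/H` at its top.
#'
#' @inheritParams wholeStalkVolume
#' @param HB height from stalk base to internode base (cm).
#' @param LSI internode length (cm); `HB + LSI <= H`.
#' @return list with elements `RI` and `rI` (cm).
#' @export
internodeRadii <- function(H, R, r, HB, LSI) {
  .checkGeometry(H, R, r, HB, LSI)
  slope <- (R - r) / H
  list(RI = R - HB * slope, rI = R - (HB + LSI) * slope)
}

#' Volume of the sampled internode
#'
#' Frustum formula on the internode segment:
#' `V_SI = pi * L_SI / 3 * (R_I^2 + r_I*R_I + r_I^2)`.
#'
#' @inheritParams internodeRadii
#' @return volume in cm^3.
#' @export
internodeVolume <- function(H, R, r, HB, LSI) {
  ri <- internodeRadii(H, R, r, HB, LSI)
  pi * LSI / 3 * (ri$RI^2 + ri$rI * ri$RI + ri$rI^2)
}

#' Volumetric ratio of sampled internode to whole stalk
#'
#' `V_ratio = V_SI / V_WS`, in (0, 1]. Dividing an extensive internode
#' measurement by `V_ratio` extrapolates it to the whole stalk.
#'
#' @inheritParams internodeRadii
#' @return dimensionless fraction.
#' @export
volumetricRatio <- function(H, R, r, HB, LSI) {
  internodeVolume(H, R, r, HB, LSI) / wholeStalkVolume(H, R, r)
}

#' Default internode-to-whole-stalk fixed-ratio table
#'
#' Fixed ratios of extrapolated fourth-internode measurements to whole-stalk
#' measurements for field-grown sweet sorghum, with standard errors, and a
#' flag for whether the analyte is extensive (an amount — extrapolation
#' divides by `V_ratio` and then by the ratio) or intensive (a concentration
#' or rate — only the fixed ratio applies). These ratios are species-specific
#' and should be re-estimated (see [estimateFixedRatios()]) for other crops.
#'
#' @return data.frame with columns `analyte`, `ratio`, `se`, `extensive`.
#' @export
defaultFixedRatios <- function() {
  data.frame(
    analyte = c("FW", "DW", "sucrose", "glucose", "fructose",
                "digestibility"),
    ratio = c(0.91, 1.00, 0.97, 1.05, 0.97, 1.29),
    se = c(0.02, 0.02, 0.02, 0.02, 0.02, 0.05),
    extensive = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
}

#' Extrapolate an internode measurement to the whole stalk
#'
#' Extensive quantities (fresh/dry weight, sugar mass) scale with volume:
#' estimate = `value / vRatio / fixedRatio`. Intensive quantities
#' (concentrations, digestibility rates) do not: estimate =
#' `value / fixedRatio`.
#'
#' @param value measured value on the sampled internode.
#' @param vRatio volumetric ratio from [volumetricRatio()], in (0, 1].
#' @param fixedRatio internode-to-whole-stalk fixed ratio (> 0).
#' @param extensive logical; is the quantity an amount (TRUE) or a
#'   concentration/rate (FALSE)?
#' @return whole-stalk estimate in the same units.
#' @export
extrapolateToWholeStalk <- function(value, vRatio, fixedRatio,
                                    extensive = TRUE) {
  if (any(vRatio <= 0) || any(vRatio > 1)) stop("vRatio must be in (0, 1]")
  if (any(fixedRatio <= 0)) stop("fixedRatio must be positive")
  if (extensive) value / vRatio / fixedRatio else value / fixedRatio
}

#' Estimate fixed ratios from paired internode / whole-stalk measurements
#'
#' For each analyte column present in both the internode table (`in_` prefix)
#' and the whole-stalk table (`ws_` prefix): extrapolates the internode value
#' through `V_ratio` (extensive analytes only), then reports the mean
#' internode/whole-stalk ratio, its standard error, the Pearson correlation,
#' and the prediction error of ratio-adjusted estimates as a percentage of
#' the whole-stalk mean (RMSEP%).
#'
#' @param paired data.frame with geometry columns `H`, `R`, `r`, `HB`, `LSI`
#'   plus `in_<analyte>` and `ws_<analyte>` columns; >= 3 rows.
#' @param extensive named logical; which analytes are extensive (defaults
#'   from [defaultFixedRatios()], unknown analytes intensive).
#' @return data.frame: `analyte`, `ratio`, `se`, `r` (correlation),
#'   `rmsep_pct`, `extensive`.
#' @export
estimateFixedRatios <- function(paired, extensive = NULL) {
  vr <- volumetricRatio(paired$H, paired$R, paired$r, paired$HB, paired$LSI)
  analytes <- sub("^in_", "", grep("^in_", names(paired), value = TRUE))
  analytes <- intersect(analytes,
                        sub("^ws_", "", grep("^ws_", names(paired),
                                             value = TRUE)))
  if (length(analytes) == 0) stop("no paired in_/ws_ analyte columns")
  def <- defaultFixedRatios()
  ext <- stats::setNames(def$extensive, def$analyte)
  if (!is.null(extensive)) ext[names(extensive)] <- extensive
  out <- lapply(analytes, function(a) {
    inv <- paired[[paste0("in_", a)]]
    wsv <- paired[[paste0("ws_", a)]]
    ok <- !is.na(inv) & !is.na(wsv)
    if (sum(ok) < 3) stop("need at least 3 paired samples for ", a)
    isExt <- isTRUE(unname(ext[a]))  # unknown analytes treated as intensive
    extv <- if (isExt) inv[ok] / vr[ok] else inv[ok]
    ratios <- extv / wsv[ok]
    ratio <- mean(ratios)
    adj <- extv / ratio
    data.frame(analyte = a, ratio = ratio,
               se = stats::sd(ratios) / sqrt(sum(ok)),
               r = stats::cor(extv, wsv[ok]),
               rmsep_pct = sqrt(mean((adj - wsv[ok])^2)) /
                 mean(wsv[ok]) * 100,
               extensive = isExt)
  })
  do.call(rbind, out)
}

#' Read a field measurement table
#'
#' Field sheets record stalk height, base and top *diameters*, internode
#' position/length and internode fresh/dry weight. Diameters are halved once
#' at ingest; everything downstream works in radii (cm).
#'
#' @param path CSV with columns `sample_id`, `H_cm`, `base_diameter_cm`,
#'   `top_diameter_cm`, `HB_cm`, `LSI_cm`, `FW_g`, `DW_g` and optional
#'   analyte columns.
#' @return data.frame with columns `sample_id`, `H`, `R`, `r`, `HB`, `LSI`,
#'   `FW`, `DW` plus any extra columns unchanged.
#' @export
readFieldTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path)
  need <- c("sample_id", "H_cm", "base_diameter_cm", "top_diameter_cm",
            "HB_cm", "LSI_cm", "FW_g", "DW_g")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  out <- data.frame(sample_id = as.character(df$sample_id),
                    H = df$H_cm,
                    R = df$base_diameter_cm / 2,
                    r = df$top_diameter_cm / 2,
                    HB = df$HB_cm, LSI = df$LSI_cm,
                    FW = df$FW_g, DW = df$DW_g)
  extra <- setdiff(names(df), need)
  for (nm in extra) out[[nm]] <- df[[nm]]
  out
}
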