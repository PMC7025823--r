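#' Background-corrected fluorescence ratio
#'
#' \eqn{R = (F_{num} - bg_{num}) / (F_{den} - bg_{den})} — the 490/440
#' excitation ratio for BCECF, or the 475/405 emission-509 ratio for
#' pHluorin (which this package reports only as a monotone intracellular-pH
#' proxy, never converted to absolute pH). Points whose corrected
#' denominator falls at or below a floor are flagged `background_dominated`
#' and their ratio is `NA`.
#'
#' @param fNum,fDen signal series (numerator/denominator channels).
#' @param bgNum,bgDen aligned background series (dye-free wells) or scalars.
#' @param denFloor flag threshold on the corrected denominator; default 2%
#'   of its maximum.
#' @return a `data.frame` with columns `ratio` and `flag`
#'   (`"ok"`/`"background_dominated"`).
#' @export
computeRatio <- function(fNum, fDen, bgNum = 0, bgDen = 0, denFloor = NULL) {
  n <- length(fNum)
  if (length(fDen) != n ||
      (length(bgNum) != 1 && length(bgNum) != n) ||
      (length(bgDen) != 1 && length(bgDen) != n))
    cocultolStop("lengthMismatchError", "signal and background series misaligned")
  num <- fNum - bgNum
  den <- fDen - bgDen
  if (is.null(denFloor)) denFloor <- 0.02 * max(den, 0)
  bad <- den <= denFloor
  data.frame(ratio = ifelse(bad, NA_real_, num / den),
             flag = ifelse(bad, "background_dominated", "ok"))
}

#' Fit a ratiometric dye calibration curve
#'
#' Least-squares fit of the four-parameter log-logistic
#' \eqn{R(pH) = R_{min} + (R_{max}-R_{min}) / (1 + 10^{n_H (pK'_a - pH)})}
#' to (known pH, measured ratio) standards. The valid range is the pH
#' interval on which R stays at least delta = 2% of the span away from both
#' plateaus; outside it, inversion is refused (censored), never
#' extrapolated.
#'
#' @param knownPh pH of the standards (>= 4 distinct values spanning the
#'   sigmoid).
#' @param ratio measured ratios.
#' @param delta plateau margin as a fraction of the span.
#' @return a [CalibrationCurve-class].
#' @export
fitCalibration <- function(knownPh, ratio, delta = 0.02) {
  if (length(knownPh) != length(ratio))
    cocultolStop("lengthMismatchError", "standards must be (pH, ratio) pairs")
  if (diff(range(ratio)) < 1e-6 || diff(range(knownPh)) < 1e-6)
    cocultolStop("degenerateSpanError",
                 "standards do not span the calibration sigmoid")
  if (length(unique(knownPh)) < 4)
    cocultolStop("insufficientStandardsError",
                 "need >= 4 standards at distinct pH values")
  start <- list(rMin = min(ratio), rMax = max(ratio),
                pKa = knownPh[which.min(abs(ratio - mean(range(ratio))))],
                nH = 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      ratio ~ rMin + (rMax - rMin) / (1 + 10^(nH * (pKa - knownPh))),
      start = start,
      lower = c(rMin = 0, rMax = 1e-6, pKa = 0, nH = 1e-3),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      cocultolStop("calibrationFitError",
                   paste0("calibration fit failed: ", conditionMessage(e))))
  cf <- coef(fit)
  span <- cf[["rMax"]] - cf[["rMin"]]
  if (span <= 0)
    cocultolStop("degenerateSpanError", "fitted span is not positive")
  halfWidth <- log10(1 / delta - 1) / cf[["nH"]]
  rmse <- sqrt(mean((ratio - (cf[["rMin"]] + span /
    (1 + 10^(cf[["nH"]] * (cf[["pKa"]] - knownPh)))))^2))
  new("CalibrationCurve", rMin = cf[["rMin"]], rMax = cf[["rMax"]],
      pKa = cf[["pKa"]], hillSlope = cf[["nH"]],
      validRange = c(cf[["pKa"]] - halfWidth, cf[["pKa"]] + halfWidth),
      rmse = rmse)
}

#' Invert ratios to pH through a calibration curve
#'
#' Closed-form inversion
#' \eqn{pH = pK'_a - (1/n_H) \log_{10}((R_{max}-R_{min})/(R-R_{min}) - 1)}.
#' Ratios within delta (2% of span) of either plateau are censored with
#' `below_range` / `above_range`; `NA` ratios (background-dominated) are
#' flagged `background_dominated`. Censored points carry `NA` pH.
#'
#' @param ratio ratio series (optionally the `data.frame` from
#'   [computeRatio()], whose flags are propagated).
#' @param curve a [CalibrationCurve-class].
#' @param time_h optional time vector carried into the result.
#' @param delta plateau margin as a fraction of the span.
#' @return a `data.frame` with columns `time_h` (if given), `ph`, `flag`
#'   (`ok`, `below_range`, `above_range`, `background_dominated`).
#' @export
invertToPh <- function(ratio, curve, time_h = NULL, delta = 0.02) {
  inFlag <- NULL
  if (is.data.frame(ratio)) {
    inFlag <- ratio$flag
    ratio <- ratio$ratio
  }
  span <- curve@rMax - curve@rMin
  lo <- curve@rMin + delta * span
  hi <- curve@rMax - delta * span
  flag <- rep("ok", length(ratio))
  flag[!is.na(ratio) & ratio <= lo] <- "below_range"
  flag[!is.na(ratio) & ratio >= hi] <- "above_range"
  flag[is.na(ratio)] <- "background_dominated"
  if (!is.null(inFlag)) flag[inFlag == "background_dominated"] <- "background_dominated"
  ph <- rep(NA_real_, length(ratio))
  ok <- flag == "ok"
  ph[ok] <- curve@pKa - log10(span / (ratio[ok] - curve@rMin) - 1) / curve@hillSlope
  out <- data.frame(ph = ph, flag = flag)
  if (!is.null(time_h)) out <- cbind(data.frame(time_h = time_h), out)
  out
}

#' Henderson-Hasselbalch protonated fraction
#'
#' Fraction of a weak acid in its protonated (membrane-permeant) form:
#' \eqn{1 / (1 + 10^{pH - pK_a})}. Lactate (pKa 3.86) is almost fully
#' dissociated at pH 7 but substantially protonated once an Lp monoculture
#' has driven the medium toward pH 3.7.
#'
#' @param ph pH value(s).
#' @param pKa acid dissociation constant; default lactate, 3.86.
#' @return fraction in \[0, 1\].
#' @export
fractionProtonated <- function(ph, pKa = 3.86) {
  if (any(!is.finite(ph))) cocultolStop("invalidPhError", "pH must be finite")
  1 / (1 + 10^(ph - pKa))
}

#' Infer a pH time series from a plate's BCECF channels
#'
#' Convenience pipeline: background series from the condition's dye-free
#' control well (or the plate's dye-free wells), [computeRatio()] on the
#' 490/440 channels, then [invertToPh()].
#'
#' @param pts a [PlateTimeSeries-class] with `F490_535`/`F440_535` assays.
#' @param well sample well to convert.
#' @param curve a [CalibrationCurve-class].
#' @return a `pHTrace` `data.frame` (time_h, ph, flag).
#' @export
inferPhTrace <- function(pts, well, curve) {
  map <- plateMap(pts)
  row <- map[map$well == well, ]
  if (nrow(row) == 0)
    cocultolStop("unmappedWellError", paste0("well not present: ", well))
  ctrl <- map$well[map$role == "dye_free_control" &
                   map$condition == row$condition]
  if (length(ctrl) == 0) ctrl <- map$well[map$role == "dye_free_control"]
  if (length(ctrl) == 0)
    cocultolStop("missingControlError", "no dye-free control wells on the plate")
  bg490 <- colMeans(channelValues(pts, "F490_535")[ctrl, , drop = FALSE])
  bg440 <- colMeans(channelValues(pts, "F440_535")[ctrl, , drop = FALSE])
  r <- computeRatio(channelValues(pts, "F490_535", well),
                    channelValues(pts, "F440_535", well),
                    bgNum = bg490, bgDen = bg440)
  invertToPh(r, curve, time_h = timePoints(pts))
}

#' Generate calibration standards from the forward model
#'
#' Emulates a calibration plate: MRS set to known pH values read through
#' the BCECF forward model, with optional ratio noise.
#'
#' @param ph pH values of the standards.
#' @param params a [communityParams()] list.
#' @param sigma Gaussian noise SD on the ratios.
#' @param seed integer RNG seed.
#' @return a `data.frame` with `known_ph` and `ratio`.
#' @export
simulateCalibrationStandards <- function(ph = seq(4, 9, by = 0.5),
                                         params = communityParams(),
                                         sigma = 0, seed = NULL) {
  withSeed(seed, data.frame(
    known_ph = ph,
    ratio = bcecfRatio(ph, params) + rnorm(length(ph), 0, sigma)))
}
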