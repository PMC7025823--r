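#' Multi-channel plate-reader time series
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding one
#' well-by-timepoint matrix per optical channel (absorbance `OD600` and the
#' dual-excitation fluorescence channels `F440_535`, `F490_535`, `F405_509`,
#' `F475_509`). Rows are wells, columns are timepoints; the plate map lives in
#' `rowData()` and the time grid (hours) in `colData()$time_h`.
#'
#' @slot .Data inherited SummarizedExperiment structure.
#' @export
setClass("PlateTimeSeries", contains = "SummarizedExperiment")

setValidity("PlateTimeSeries", function(object) {
  msg <- character(0)
  tm <- SummarizedExperiment::colData(object)$time_h
  if (is.null(tm)) msg <- c(msg, "colData must contain 'time_h'")
  else {
    if (length(tm) < 2L) msg <- c(msg, "time vector must have length >= 2")
    if (any(diff(tm) <= 0)) msg <- c(msg, "time vector must be strictly increasing")
  }
  an <- SummarizedExperiment::assayNames(object)
  if (length(an) == 0L) msg <- c(msg, "at least one channel assay required")
  bad <- setdiff(an, knownChannels)
  if (length(bad)) msg <- c(msg, paste0("unknown channel(s): ", paste(bad, collapse = ", ")))
  if ("OD600" %in% an && !all(is.finite(SummarizedExperiment::assay(object, "OD600"))))
    msg <- c(msg, "OD600 values must all be finite")
  if (anyDuplicated(rownames(object))) msg <- c(msg, "well ids must be unique")
  if (length(msg)) msg else TRUE
})

#' Gompertz growth-curve fit
#'
#' Parameters of the modified (Zwietering) Gompertz model
#' \eqn{y(t) = A \exp(-\exp(\mu_{max} e / A \cdot (\lambda - t) + 1))}
#' fitted to ln-fold growth curves, with fit diagnostics. Degenerate
#' (no-growth) fits carry `muMax = 0` and `lag = NA`.
#'
#' @slot A asymptotic ln-fold increase (dimensionless).
#' @slot muMax maximal specific growth rate (1/h).
#' @slot lag lag time \eqn{\lambda} (h); `NA` for degenerate fits.
#' @slot rmse root-mean-square residual of the fit.
#' @slot converged logical; optimizer convergence.
#' @slot degenerate logical; TRUE when the curve never exceeds the
#'   no-growth threshold.
#' @slot window numeric(2), time window (h) used for the fit.
#' @export
setClass("GrowthFit", representation(
  A = "numeric", muMax = "numeric", lag = "numeric", rmse = "numeric",
  converged = "logical", degenerate = "logical", window = "numeric"))

setValidity("GrowthFit", function(object) {
  msg <- character(0)
  if (object@degenerate) {
    if (object@muMax != 0) msg <- c(msg, "degenerate fits must have muMax = 0")
    if (!is.na(object@lag)) msg <- c(msg, "degenerate fits carry no lag")
  } else if (object@converged) {
    if (object@A < 0 || object@muMax < 0 || (!is.na(object@lag) && object@lag < 0))
      msg <- c(msg, "A, muMax, lag must be non-negative for converged fits")
  }
  if (length(msg)) msg else TRUE
})

#' Ratiometric dye calibration curve
#'
#' Four-parameter log-logistic calibration
#' \eqn{R(pH) = R_{min} + (R_{max}-R_{min}) / (1 + 10^{n_H (pK'_a - pH)})}
#' relating a background-corrected fluorescence excitation ratio (490/440 for
#' BCECF) to medium pH, together with the pH range on which the closed-form
#' inversion is trusted.
#'
#' @slot rMin,rMax ratio plateaus; `rMax > rMin`.
#' @slot pKa apparent midpoint pH.
#' @slot hillSlope Hill slope \eqn{n_H > 0}.
#' @slot validRange numeric(2), pH interval where R is at least 2% of the
#'   span away from both plateaus.
#' @slot rmse calibration fit RMSE (ratio units).
#' @export
setClass("CalibrationCurve", representation(
  rMin = "numeric", rMax = "numeric", pKa = "numeric", hillSlope = "numeric",
  validRange = "numeric", rmse = "numeric"))

setValidity("CalibrationCurve", function(object) {
  msg <- character(0)
  if (object@rMax <= object@rMin) msg <- c(msg, "rMax must exceed rMin")
  if (object@hillSlope <= 0) msg <- c(msg, "hillSlope must be positive")
  if (length(object@validRange) != 2L || diff(object@validRange) <= 0)
    msg <- c(msg, "validRange must be an increasing pH interval")
  if (length(msg)) msg else TRUE
})

#' Dose-response MIC call
#'
#' Result of the endpoint MIC rule: a concentration is scored "no growth"
#' when its mean endpoint OD is within two standard deviations of the media
#' blanks; the MIC is the lowest no-growth concentration on the two-fold
#' ladder. `censor` records off-ladder outcomes, and `monotonicityFlag` is
#' set when growth reappears above a no-growth concentration.
#'
#' @slot ladder increasing concentration ladder (ug/mL).
#' @slot odMean,odSd per-concentration endpoint OD mean and SD.
#' @slot blankMean,blankSd media-blank statistics.
#' @slot mic called MIC (ug/mL), `NA` when censored.
#' @slot censor one of "none", "gt_max", "le_min".
#' @slot monotonicityFlag logical.
#' @export
setClass("DoseResponseResult", representation(
  ladder = "numeric", odMean = "numeric", odSd = "numeric",
  blankMean = "numeric", blankSd = "numeric", mic = "numeric",
  censor = "character", monotonicityFlag = "logical"))

setValidity("DoseResponseResult", function(object) {
  msg <- character(0)
  if (any(diff(object@ladder) <= 0)) msg <- c(msg, "ladder must be strictly increasing")
  if (!object@censor %in% c("none", "gt_max", "le_min"))
    msg <- c(msg, "censor must be none/gt_max/le_min")
  if (object@censor == "none" && !(object@mic %in% object@ladder))
    msg <- c(msg, "uncensored MIC must be a ladder member")
  if (length(msg)) msg else TRUE
})

#' Time-kill curve fit
#'
#' Fit of normalized survival to the delayed exponential killing model
#' \eqn{S(t) = \exp(-k \max(0, t - d))}. The delay is retained only when a
#' free-delay fit improves the sum of squares at an F-test level of 0.05.
#' `mdk99` is the minimum duration for 99% killing, \eqn{d + \ln(100)/k},
#' `NA` (censored) when no killing is detected.
#'
#' @slot k kill rate (1/h), >= 0.
#' @slot delay killing delay d (h), >= 0.
#' @slot mdk99 minimum duration for 99% killing (h), `NA` if censored.
#' @slot model "delayed", "immediate", or "none" (no detectable killing).
#' @slot rmse RMSE on log10 survival over the fitted points.
#' @slot nCensored number of below-detection points excluded from fitting.
#' @slot violations fitted curve predictions exceeding a below-LOD bound.
#' @slot converged logical.
#' @export
setClass("KillCurveFit", representation(
  k = "numeric", delay = "numeric", mdk99 = "numeric", model = "character",
  rmse = "numeric", nCensored = "integer", violations = "integer",
  converged = "logical"))

setValidity("KillCurveFit", function(object) {
  msg <- character(0)
  if (object@k < 0 || object@delay < 0) msg <- c(msg, "k and delay must be >= 0")
  if (!is.na(object@mdk99) && object@k > 0) {
    if (abs(object@mdk99 - (object@delay + log(100) / object@k)) > 1e-8)
      msg <- c(msg, "mdk99 must equal delay + ln(100)/k when uncensored")
  }
  if (length(msg)) msg else TRUE
})

#' Additive-model interaction score
#'
#' Per-replicate interaction scores
#' \eqn{\alpha = (OD_{co} - (OD_{Lp} + OD_A)) / (OD_{Lp} OD_A)} with their
#' mean, dispersion, a two-sided one-sample t-test against 0, and the
#' resulting classification: synergy (significantly positive), antagonism
#' (significantly negative), neutral, or indeterminate (n < 2).
#'
#' @slot alpha per-replicate scores.
#' @slot mean,sd,n summary statistics.
#' @slot pValue two-sided p versus 0 (`NA` when indeterminate).
#' @slot label "synergy", "antagonism", "neutral" or "indeterminate".
#' @export
setClass("InteractionScore", representation(
  alpha = "numeric", mean = "numeric", sd = "numeric", n = "integer",
  pValue = "numeric", label = "character"))

setValidity("InteractionScore", function(object) {
  ok <- c("synergy", "antagonism", "neutral", "indeterminate")
  if (!object@label %in% ok) return("unknown label")
  TRUE
})

#' Resistance-versus-tolerance verdict
#'
#' Comparison of a treatment condition against a reference: resistance is a
#' MIC shift of at least two two-fold steps (ratio >= 4); tolerance is an
#' unchanged MIC (ratio < 4) with an MDK99 ratio >= 2, i.e. killing takes at
#' least twice as long without a change in the inhibitory concentration.
#'
#' @slot micRatio treatment/reference MIC ratio.
#' @slot mdkRatio treatment/reference MDK99 ratio.
#' @slot label "resistance", "tolerance", "neither" or "indeterminate".
#' @export
setClass("ToleranceCall", representation(
  micRatio = "numeric", mdkRatio = "numeric", label = "character"))

setValidity("ToleranceCall", function(object) {
  if (!object@label %in% c("resistance", "tolerance", "neither", "indeterminate"))
    return("unknown label")
  if (object@label == "resistance" && !is.na(object@micRatio) && object@micRatio < 4)
    return("resistance requires micRatio >= 4")
  if (object@label == "tolerance" &&
      (!is.na(object@micRatio) && object@micRatio >= 4 ||
       !is.na(object@mdkRatio) && object@mdkRatio < 2))
    return("tolerance requires micRatio < 4 and mdkRatio >= 2")
  TRUE
})

#' Community simulation trajectory
#'
#' Deterministic solution of the lactate cross-feeding consumer-resource
#' model for one culture condition: biomass of L. plantarum (`B_Lp`) and of
#' the Acetobacter partner (`B_Ax`) in OD-equivalent units, glucose `G` and
#' lactate `L` (mM), the Baranyi physiological state `q` of Lp, the medium
#' `pH` (an algebraic image of accumulated lactate through a saturating
#' buffering map), and the instantaneous specific growth rates.
#'
#' @slot time time grid (h).
#' @slot state matrix with columns `B_Lp`, `B_Ax`, `G`, `L`, `q`, `pH`.
#' @slot rates matrix with columns `mu_Lp`, `mu_Ax` (1/h).
#' @slot condition condition label.
#' @slot species species present (subset of c("Lp","Ax")).
#' @export
setClass("Trajectory", representation(
  time = "numeric", state = "matrix", rates = "matrix",
  condition = "character", species = "character"))

setValidity("Trajectory", function(object) {
  msg <- character(0)
  need <- c("B_Lp", "B_Ax", "G", "L", "q", "pH")
  if (!all(need %in% colnames(object@state)))
    msg <- c(msg, "state matrix must have columns B_Lp, B_Ax, G, L, q, pH")
  else {
    if (nrow(object@state) != length(object@time))
      msg <- c(msg, "state rows must match time grid")
    st <- object@state
    if (any(st[, c("B_Lp", "B_Ax", "G", "L", "q")] < -1e-9))
      msg <- c(msg, "state variables must be non-negative")
    if (any(st[, "pH"] < 2 | st[, "pH"] > 9)) msg <- c(msg, "pH out of [2, 9]")
    if (any(diff(st[, "G"]) > 1e-9)) msg <- c(msg, "glucose must be non-increasing")
  }
  if (length(msg)) msg else TRUE
})
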