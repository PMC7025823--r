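#' Call the MIC from an endpoint dose-response plate
#'
#' Applies the two-standard-deviation blank rule: a concentration counts as
#' "no growth" iff its mean endpoint OD is at most the media-blank mean plus
#' two blank standard deviations. The MIC is the minimum no-growth
#' concentration on the ladder. If growth reappears above a no-growth
#' concentration the response is non-monotone: the flag is set and the MIC
#' is the lowest concentration above which everything is no-growth. Growth
#' everywhere censors the MIC as `> max`; no growth anywhere as `<= min`.
#' The call is invariant to well order and to duplicated identical blanks.
#'
#' @param endpoint a `data.frame` with columns `conc_ug_ml` and `od` for
#'   sample wells (e.g. from [simulateDoseResponse()]; rows with
#'   `role == "media_blank"` are used as blanks when `blanks` is NULL).
#' @param blanks numeric vector of blank-well ODs (>= 2), or NULL to take
#'   them from `endpoint`.
#' @return a [DoseResponseResult-class].
#' @export
callMic <- function(endpoint, blanks = NULL) {
  if (is.null(blanks)) {
    if (!"role" %in% names(endpoint))
      cocultolStop("missingBlanksError", "no blanks given and no role column")
    blanks <- endpoint$od[endpoint$role == "media_blank"]
    endpoint <- endpoint[endpoint$role != "media_blank", ]
  }
  if (length(blanks) < 2)
    cocultolStop("insufficientBlanksError",
                 "need >= 2 blank wells to estimate the blank SD")
  ladder <- sort(unique(endpoint$conc_ug_ml))
  if (length(ladder) < 3)
    cocultolStop("insufficientLadderError", "need a ladder of >= 3 concentrations")
  odMean <- vapply(ladder, function(cc)
    mean(endpoint$od[endpoint$conc_ug_ml == cc]), numeric(1))
  odSd <- vapply(ladder, function(cc)
    sd(endpoint$od[endpoint$conc_ug_ml == cc]), numeric(1))
  # population SD: the blank set is the complete population of media
  # controls on the plate, and this makes the call invariant to duplicating
  # identical blank wells
  bm <- mean(blanks); bs <- sqrt(mean((blanks - bm)^2))
  noGrowth <- odMean <= bm + 2 * bs

  if (!any(noGrowth)) {
    mic <- NA_real_; censor <- "gt_max"; flag <- FALSE
  } else if (all(noGrowth)) {
    mic <- NA_real_; censor <- "le_min"; flag <- FALSE
  } else {
    censor <- "none"
    lastGrowth <- max(which(!noGrowth))
    naiveMic <- ladder[min(which(noGrowth))]
    if (lastGrowth == length(ladder)) {
      # growth at the top of the ladder above some no-growth wells
      mic <- NA_real_; censor <- "gt_max"; flag <- TRUE
    } else {
      mic <- ladder[lastGrowth + 1L]
      flag <- mic != naiveMic
    }
  }
  new("DoseResponseResult", ladder = ladder, odMean = odMean, odSd = odSd,
      blankMean = bm, blankSd = bs, mic = mic, censor = censor,
      monotonicityFlag = flag)
}

#' Fold-MIC of a treatment concentration
#'
#' @param conc drug concentration (ug/mL).
#' @param mic MIC as a number or an uncensored [DoseResponseResult-class].
#' @return `conc / mic` (dimensionless fold).
#' @export
foldMic <- function(conc, mic) {
  if (is(mic, "DoseResponseResult")) {
    if (mic@censor != "none")
      cocultolStop("censoredMicError", "cannot compute fold of a censored MIC")
    mic <- mic@mic
  }
  if (!is.finite(mic) || mic <= 0)
    cocultolStop("censoredMicError", "MIC must be positive and uncensored")
  conc / mic
}

#' Normalized survival from a CFU table
#'
#' \eqn{S(t) = CFU(t) / CFU(0)} per condition (replicates pooled by their
#' own t = 0 counts). Below-LOD records propagate as upper bounds
#' `S(t) < LOD / CFU(0)` with `censored = TRUE`, never as zeros.
#'
#' @param cfu a validated CFU `data.frame` (see [readCfuTable()]).
#' @param condition condition label to extract.
#' @return a `data.frame` with columns `condition, replicate, time_h,
#'   survival, censored, bound`; class attribute `"SurvivalSeries"`.
#' @export
survivalSeries <- function(cfu, condition = NULL) {
  if (!is.null(condition)) cfu <- cfu[cfu$condition == condition, ]
  if (nrow(cfu) == 0)
    cocultolStop("missingConditionError", "no records for requested condition")
  out <- do.call(rbind, lapply(split(cfu, cfu$replicate), function(rep_) {
    t0 <- rep_[rep_$time_h == 0 & !rep_$below_lod, ]
    if (nrow(t0) == 0)
      cocultolStop("missingT0Error",
                   "need a t = 0 record with positive CFU for normalization")
    cfu0 <- mean(t0$cfu_per_ml)
    data.frame(condition = rep_$condition, replicate = rep_$replicate,
               time_h = rep_$time_h,
               survival = ifelse(rep_$below_lod, NA_real_, rep_$cfu_per_ml / cfu0),
               censored = rep_$below_lod,
               bound = ifelse(rep_$below_lod, rep_$lod / cfu0, NA_real_))
  }))
  rownames(out) <- NULL
  class(out) <- c("SurvivalSeries", "data.frame")
  out
}

#' Fit a time-kill curve
#'
#' Least squares of log survival on the delayed exponential model
#' \eqn{S(t) = \exp(-k \max(0, t-d))}. The immediate model (d = 0) has the
#' closed-form slope; the delay is profiled on a grid and retained only when
#' the free-delay fit improves the SSE at an F-test level
#' `delayTestLevel`. Censored (below-LOD) points are excluded from the fit
#' but any fitted prediction exceeding a censored bound is counted as a
#' violation. `MDK99 = d + ln(100)/k`, censored (`NA`) when k = 0.
#'
#' @param series a `SurvivalSeries` from [survivalSeries()].
#' @param delayTestLevel F-test level for keeping a free delay.
#' @param delayGrid resolution (h) of the delay profile grid.
#' @return a [KillCurveFit-class].
#' @export
fitKillCurve <- function(series, delayTestLevel = 0.05, delayGrid = 0.05) {
  pts <- series[!series$censored & is.finite(series$survival) & series$survival > 0, ]
  cens <- series[series$censored, ]
  nUnc <- sum(pts$time_h > 0)
  if (nUnc < 3)
    return(new("KillCurveFit", k = 0, delay = 0, mdk99 = NA_real_,
               model = "none", rmse = NA_real_,
               nCensored = nrow(cens), violations = 0L, converged = FALSE))
  t_ <- pts$time_h
  y <- log(pts$survival)  # natural log; model y = -k * max(0, t - d)

  sseFor <- function(d) {
    x <- pmax(0, t_ - d)
    sxx <- sum(x^2)
    k <- if (sxx == 0) 0 else max(0, -sum(x * y) / sxx)
    c(sse = sum((y + k * x)^2), k = k)
  }
  f0 <- sseFor(0)
  grid <- seq(0, max(t_) - delayGrid, by = delayGrid)
  prof <- vapply(grid, function(d) sseFor(d)["sse"], numeric(1))
  dBest <- grid[which.min(prof)]
  f1 <- sseFor(dBest)
  n <- length(y)
  useDelay <- FALSE
  if (dBest > 0 && f1["sse"] < f0["sse"] && n > 2) {
    if (f1["sse"] < 1e-12) {
      useDelay <- TRUE  # perfect delayed fit
    } else {
      fStat <- (f0["sse"] - f1["sse"]) / (f1["sse"] / (n - 2))
      useDelay <- pf(fStat, 1, n - 2, lower.tail = FALSE) < delayTestLevel
    }
  }
  if (useDelay) { d <- dBest; k <- unname(f1["k"]); sse <- f1["sse"] }
  else { d <- 0; k <- unname(f0["k"]); sse <- f0["sse"] }
  model <- if (k == 0) "none" else if (d > 0) "delayed" else "immediate"
  mdk <- if (k > 0) d + log(100) / k else NA_real_
  viol <- 0L
  if (nrow(cens) > 0 && k > 0) {
    pred <- exp(-k * pmax(0, cens$time_h - d))
    viol <- sum(pred > cens$bound)
  }
  rmse <- sqrt(sse / n) / log(10)  # report on log10 S scale
  new("KillCurveFit", k = k, delay = d, mdk99 = mdk, model = model,
      rmse = unname(rmse), nCensored = nrow(cens), violations = as.integer(viol),
      converged = TRUE)
}

#' Classify a treatment as resistance, tolerance, or neither
#'
#' Resistance: MIC ratio (treatment/reference) of at least 4 (two two-fold
#' steps). Tolerance: MIC ratio below 4 with an MDK99 ratio of at least 2 —
#' the population takes at least twice as long to kill without an MIC
#' change. Censored MICs or unconverged kill fits give "indeterminate".
#'
#' @param referenceMic,treatmentMic MICs as numbers or
#'   [DoseResponseResult-class] objects.
#' @param referenceKill,treatmentKill [KillCurveFit-class] objects.
#' @param resistanceFold MIC-ratio threshold for resistance.
#' @param toleranceFold MDK99-ratio threshold for tolerance.
#' @return a [ToleranceCall-class].
#' @export
classifyResponse <- function(referenceMic, referenceKill,
                             treatmentMic, treatmentKill,
                             resistanceFold = 4, toleranceFold = 2) {
  getMic <- function(m) {
    if (is(m, "DoseResponseResult")) {
      if (m@censor != "none") return(NA_real_)
      m@mic
    } else m
  }
  rm_ <- getMic(referenceMic); tm_ <- getMic(treatmentMic)
  if (!is.finite(rm_) || !is.finite(tm_) ||
      !referenceKill@converged || !treatmentKill@converged)
    return(new("ToleranceCall", micRatio = NA_real_, mdkRatio = NA_real_,
               label = "indeterminate"))
  micRatio <- tm_ / rm_
  mdkRatio <- if (is.na(treatmentKill@mdk99) || is.na(referenceKill@mdk99))
    NA_real_ else treatmentKill@mdk99 / referenceKill@mdk99
  label <- if (micRatio >= resistanceFold) "resistance"
    else if (!is.na(mdkRatio) && mdkRatio >= toleranceFold) "tolerance"
    else if (is.na(mdkRatio)) "indeterminate"
    else "neither"
  new("ToleranceCall", micRatio = micRatio, mdkRatio = mdkRatio, label = label)
}
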