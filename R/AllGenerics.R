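#' @name cocultol-accessors
#' @title Accessors for cocultol result classes
#' @description Slot accessors; user code should use these rather than `@`.
#' @param x a cocultol S4 object.
#' @param ... unused.
NULL

#' @rdname cocultol-accessors
#' @export
setGeneric("timePoints", function(x, ...) standardGeneric("timePoints"))
#' @rdname cocultol-accessors
#' @export
setMethod("timePoints", "PlateTimeSeries", function(x, ...)
  SummarizedExperiment::colData(x)$time_h)
#' @rdname cocultol-accessors
#' @export
setMethod("timePoints", "Trajectory", function(x, ...) x@time)

#' @rdname cocultol-accessors
#' @export
setGeneric("plateMap", function(x, ...) standardGeneric("plateMap"))
#' @rdname cocultol-accessors
#' @export
setMethod("plateMap", "PlateTimeSeries", function(x, ...) {
  df <- as.data.frame(SummarizedExperiment::rowData(x))
  df$well <- rownames(x)
  rownames(df) <- NULL
  df[c("well", setdiff(names(df), "well"))]
})

#' @rdname cocultol-accessors
#' @export
setGeneric("channelNames", function(x, ...) standardGeneric("channelNames"))
#' @rdname cocultol-accessors
#' @export
setMethod("channelNames", "PlateTimeSeries", function(x, ...)
  SummarizedExperiment::assayNames(x))

#' Extract one channel matrix or one well trace
#'
#' @param x a `PlateTimeSeries`.
#' @param channel channel name, e.g. `"OD600"`.
#' @param well optional well id; when given, returns the numeric time series
#'   for that well instead of the full matrix.
#' @return wells-by-time matrix, or a numeric vector when `well` is given.
#' @export
channelValues <- function(x, channel, well = NULL) {
  stopifnot(is(x, "PlateTimeSeries"))
  if (!channel %in% channelNames(x))
    cocultolStop("unknownChannelError", paste0("channel not present: ", channel))
  m <- SummarizedExperiment::assay(x, channel)
  if (is.null(well)) return(m)
  if (!well %in% rownames(m))
    cocultolStop("unmappedWellError", paste0("well not present: ", well))
  m[well, ]
}

#' @rdname cocultol-accessors
#' @export
setGeneric("lagTime", function(x, ...) standardGeneric("lagTime"))
#' @rdname cocultol-accessors
#' @export
setMethod("lagTime", "GrowthFit", function(x, ...) x@lag)

#' @rdname cocultol-accessors
#' @export
setGeneric("muMax", function(x, ...) standardGeneric("muMax"))
#' @rdname cocultol-accessors
#' @export
setMethod("muMax", "GrowthFit", function(x, ...) x@muMax)

#' @rdname cocultol-accessors
#' @export
setGeneric("carryingCapacity", function(x, ...) standardGeneric("carryingCapacity"))
#' @rdname cocultol-accessors
#' @export
setMethod("carryingCapacity", "GrowthFit", function(x, ...) x@A)

#' @rdname cocultol-accessors
#' @export
setGeneric("micValue", function(x, ...) standardGeneric("micValue"))
#' @rdname cocultol-accessors
#' @export
setMethod("micValue", "DoseResponseResult", function(x, ...) x@mic)

#' @rdname cocultol-accessors
#' @export
setGeneric("micCensor", function(x, ...) standardGeneric("micCensor"))
#' @rdname cocultol-accessors
#' @export
setMethod("micCensor", "DoseResponseResult", function(x, ...) x@censor)

#' @rdname cocultol-accessors
#' @export
setGeneric("mdk99", function(x, ...) standardGeneric("mdk99"))
#' @rdname cocultol-accessors
#' @export
setMethod("mdk99", "KillCurveFit", function(x, ...) x@mdk99)

#' @rdname cocultol-accessors
#' @export
setGeneric("killRate", function(x, ...) standardGeneric("killRate"))
#' @rdname cocultol-accessors
#' @export
setMethod("killRate", "KillCurveFit", function(x, ...) x@k)

#' @rdname cocultol-accessors
#' @export
setGeneric("killDelay", function(x, ...) standardGeneric("killDelay"))
#' @rdname cocultol-accessors
#' @export
setMethod("killDelay", "KillCurveFit", function(x, ...) x@delay)

#' @rdname cocultol-accessors
#' @export
setGeneric("interactionLabel", function(x, ...) standardGeneric("interactionLabel"))
#' @rdname cocultol-accessors
#' @export
setMethod("interactionLabel", "InteractionScore", function(x, ...) x@label)
#' @rdname cocultol-accessors
#' @export
setMethod("interactionLabel", "ToleranceCall", function(x, ...) x@label)

#' @rdname cocultol-accessors
#' @export
setGeneric("trajectoryState", function(x, ...) standardGeneric("trajectoryState"))
#' @rdname cocultol-accessors
#' @export
setMethod("trajectoryState", "Trajectory", function(x, ...) {
  df <- data.frame(time_h = x@time, x@state, check.names = FALSE)
  cbind(df, x@rates)
})

setMethod("show", "PlateTimeSeries", function(object) {
  tm <- timePoints(object)
  cat("PlateTimeSeries:", nrow(object), "wells x", length(tm), "timepoints\n")
  cat("  channels:", paste(channelNames(object), collapse = ", "), "\n")
  cat(sprintf("  time: %.2f .. %.2f h\n", min(tm), max(tm)))
  roles <- table(SummarizedExperiment::rowData(object)$role)
  cat("  roles:", paste(names(roles), roles, sep = "=", collapse = ", "), "\n")
})

setMethod("show", "GrowthFit", function(object) {
  if (object@degenerate) {
    cat("GrowthFit: degenerate (no growth); muMax = 0\n")
  } else {
    cat(sprintf("GrowthFit: A = %.3f ln-fold, muMax = %.4f /h, lag = %.3f h\n",
                object@A, object@muMax, object@lag))
    cat(sprintf("  rmse = %.4g, converged = %s\n", object@rmse, object@converged))
  }
})

setMethod("show", "CalibrationCurve", function(object) {
  cat(sprintf("CalibrationCurve: R in [%.3f, %.3f], pK'a = %.3f, nH = %.3f\n",
              object@rMin, object@rMax, object@pKa, object@hillSlope))
  cat(sprintf("  valid pH range: [%.2f, %.2f], rmse = %.4g\n",
              object@validRange[1], object@validRange[2], object@rmse))
})

setMethod("show", "DoseResponseResult", function(object) {
  micTxt <- switch(object@censor,
    none = sprintf("%.4g ug/mL", object@mic),
    gt_max = sprintf("> %.4g ug/mL (censored)", max(object@ladder)),
    le_min = sprintf("<= %.4g ug/mL (censored)", min(object@ladder)))
  cat("DoseResponseResult: MIC =", micTxt, "\n")
  if (object@monotonicityFlag) cat("  warning: non-monotone dose response\n")
})

setMethod("show", "KillCurveFit", function(object) {
  cat(sprintf("KillCurveFit (%s): k = %.4f /h, delay = %.3f h\n",
              object@model, object@k, object@delay))
  cat(sprintf("  MDK99 = %s h, rmse(log10 S) = %.4g, censored pts = %d\n",
              ifelse(is.na(object@mdk99), "censored", sprintf("%.3f", object@mdk99)),
              object@rmse, object@nCensored))
})

setMethod("show", "InteractionScore", function(object) {
  cat(sprintf("InteractionScore: mean alpha = %.4f (sd %.4f, n = %d) -> %s\n",
              object@mean, object@sd, object@n, object@label))
  if (!is.na(object@pValue)) cat(sprintf("  two-sided p vs 0: %.4g\n", object@pValue))
})

setMethod("show", "ToleranceCall", function(object) {
  cat(sprintf("ToleranceCall: MIC ratio = %.3g, MDK99 ratio = %.3g -> %s\n",
              object@micRatio, object@mdkRatio, object@label))
})

setMethod("show", "Trajectory", function(object) {
  st <- object@state
  cat(sprintf("Trajectory '%s' (%s): %d points over %.1f h\n",
              object@condition, paste(object@species, collapse = "+"),
              length(object@time), max(object@time)))
  cat(sprintf("  final: B_Lp = %.3f, B_Ax = %.3f, G = %.2f mM, L = %.2f mM, pH = %.2f\n",
              st[nrow(st), "B_Lp"], st[nrow(st), "B_Ax"], st[nrow(st), "G"],
              st[nrow(st), "L"], st[nrow(st), "pH"]))
})
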