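#' Centered mean-filter smoothing
#'
#' Moving mean with an odd window (default 5 timepoints, as used for
#' plate-reader ln(OD) traces). At the edges the window shrinks
#' symmetrically so output length equals input length and linear trends are
#' preserved everywhere.
#'
#' @param x numeric series (NAs are preserved and ignored within windows).
#' @param window odd window size >= 1, at most `length(x)`.
#' @return smoothed series of the same length.
#' @export
smoothSeries <- function(x, window = 5) {
  if (window < 1 || window %% 2 == 0)
    cocultolStop("invalidWindowError", "window must be odd and >= 1")
  n <- length(x)
  if (window > n)
    cocultolStop("invalidWindowError", "window larger than series")
  h <- (window - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    hh <- min(h, i - 1L, n - i)
    if (is.na(x[i])) return(NA_real_)
    mean(x[(i - hh):(i + hh)], na.rm = TRUE)
  }, numeric(1))
}

#' Natural-log normalization of an OD series
#'
#' \eqn{y(t) = \ln((OD(t) - blank) / (OD(t_0) - blank))}: the ln-fold
#' increase relative to the reference point. Points where OD does not
#' exceed the blank are masked (`NA`), never clipped.
#'
#' @param od OD series.
#' @param blank blank OD to subtract (default 0).
#' @param ref index of the reference timepoint (default 1, i.e. t = 0).
#' @return ln-fold series with masked sub-blank points.
#' @export
logNormalize <- function(od, blank = 0, ref = 1L) {
  if (od[ref] <= blank)
    cocultolStop("referenceBelowBlankError",
                 "reference OD must exceed the blank")
  y <- rep(NA_real_, length(od))
  ok <- od > blank
  y[ok] <- log((od[ok] - blank) / (od[ref] - blank))
  y
}

#' Instantaneous growth rate d(ln OD)/dt
#'
#' Central differences in the interior, one-sided differences at the two
#' endpoints, on an (ideally smoothed) ln-fold series.
#'
#' @param time strictly increasing time vector (h).
#' @param y ln-fold series of the same length (length >= 3).
#' @return a `data.frame` with columns `time_h` and `rate` (1/h).
#' @export
instantaneousRate <- function(time, y) {
  n <- length(time)
  if (n != length(y) || n < 3)
    cocultolStop("lengthMismatchError", "need matched series of length >= 3")
  if (any(diff(time) <= 0))
    cocultolStop("nonMonotoneTimeError", "time must be strictly increasing")
  rate <- numeric(n)
  rate[1] <- (y[2] - y[1]) / (time[2] - time[1])
  rate[n] <- (y[n] - y[n - 1]) / (time[n] - time[n - 1])
  idx <- 2:(n - 1)
  rate[idx] <- (y[idx + 1] - y[idx - 1]) / (time[idx + 1] - time[idx - 1])
  data.frame(time_h = time, rate = rate)
}

#' Modified Gompertz model
#'
#' Zwietering parameterization of the Gompertz law on ln-fold growth:
#' \eqn{y(t) = A \exp(-\exp(\mu_{max} e / A \cdot (\lambda - t) + 1))}.
#' Its analytic properties: \eqn{y(\infty) = A}; the maximum of dy/dt equals
#' \eqn{\mu_{max}}, attained at \eqn{t^* = \lambda + A/(\mu_{max} e)}; and
#' the tangent at \eqn{t^*} crosses y = 0 at \eqn{t = \lambda}.
#'
#' @param t time (h).
#' @param A asymptotic ln-fold increase.
#' @param muMax maximal specific growth rate (1/h).
#' @param lag lag time (h).
#' @return model value(s).
#' @export
gompertz <- function(t, A, muMax, lag) {
  A * exp(-exp(muMax * exp(1) / A * (lag - t) + 1))
}

#' Fit the modified Gompertz model to a ln-fold growth curve
#'
#' Nonlinear least squares (Levenberg-Marquardt) with deterministic
#' initialization: `A0 = max(y)`, `muMax0` the steepest central-difference
#' slope, `lag0` the tangent-intercept estimate at the steepest point
#' (clipped to >= 0); non-negativity bounds on all three parameters and up
#' to 10 jittered restarts on non-convergence. Curves that never exceed
#' `degenerateThreshold` ln-fold are declared degenerate (no growth,
#' `muMax = 0`, no lag) without fitting. Optimizer failure returns a
#' non-converged fit, never an error.
#'
#' @param time strictly increasing time vector (h).
#' @param y ln-fold series; masked (`NA`) points are excluded.
#' @param degenerateThreshold no-growth threshold on max(y) (ln-fold).
#' @param restarts maximum jittered restarts.
#' @return a [GrowthFit-class].
#' @export
fitGompertz <- function(time, y, degenerateThreshold = 0.05, restarts = 10) {
  keep <- is.finite(y)
  t_ <- time[keep]; y_ <- y[keep]
  win <- range(t_)
  if (length(y_) < 4 || max(y_) < degenerateThreshold)
    return(new("GrowthFit", A = max(c(y_, 0)), muMax = 0, lag = NA_real_,
               rmse = NA_real_, converged = TRUE, degenerate = TRUE,
               window = win))
  a0 <- max(y_)
  slopes <- diff(y_) / diff(t_)
  iMax <- which.max(slopes)
  mu0 <- max(slopes[iMax], 1e-3)
  tMaxSlope <- (t_[iMax] + t_[iMax + 1]) / 2
  yMaxSlope <- (y_[iMax] + y_[iMax + 1]) / 2
  lag0 <- max(0, tMaxSlope - yMaxSlope / mu0)
  start <- c(A = a0, muMax = mu0, lag = lag0)

  fitOnce <- function(st) {
    tryCatch(
      minpack.lm::nlsLM(
        y_ ~ gompertz(t_, A, muMax, lag),
        start = as.list(st),
        lower = c(A = 1e-8, muMax = 1e-8, lag = 0),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  }
  fit <- fitOnce(start)
  tries <- 0L
  jitterFactors <- function(i) exp(0.2 * sin(1e3 * i + c(1, 2, 3)))  # deterministic
  while (is.null(fit) && tries < restarts) {
    tries <- tries + 1L
    fit <- fitOnce(start * jitterFactors(tries))
  }
  if (is.null(fit))
    return(new("GrowthFit", A = a0, muMax = mu0, lag = lag0, rmse = NA_real_,
               converged = FALSE, degenerate = FALSE, window = win))
  cf <- coef(fit)
  rmse <- sqrt(mean((y_ - gompertz(t_, cf["A"], cf["muMax"], cf["lag"]))^2))
  new("GrowthFit", A = unname(cf["A"]), muMax = unname(cf["muMax"]),
      lag = unname(cf["lag"]), rmse = rmse, converged = TRUE,
      degenerate = FALSE, window = win)
}

#' Fit growth curves for every sample well of a plate
#'
#' Per sample well: blank-subtract (mean of media-blank wells at each
#' timepoint, or a scalar), ln-normalize to the first timepoint, smooth with
#' the window-5 mean filter, and fit the modified Gompertz model.
#'
#' @param pts a [PlateTimeSeries-class] with an `OD600` assay.
#' @param blank `"auto"` (mean of `media_blank` wells), a scalar, or 0.
#' @param window mean-filter window.
#' @param ... passed to [fitGompertz()].
#' @return a `data.frame` with one row per sample well: well, condition,
#'   replicate, A, muMax, lag, rmse, converged, degenerate.
#' @export
fitGrowthCurves <- function(pts, blank = "auto", window = 5, ...) {
  od <- channelValues(pts, "OD600")
  map <- plateMap(pts)
  tm <- timePoints(pts)
  if (identical(blank, "auto")) {
    bw <- map$well[map$role == "media_blank"]
    blank <- if (length(bw)) mean(od[bw, , drop = FALSE]) else 0
  }
  wells <- map$well[map$role == "sample"]
  rows <- lapply(wells, function(w) {
    y <- smoothSeries(logNormalize(od[w, ], blank = blank), window = window)
    f <- fitGompertz(tm, y, ...)
    data.frame(well = w, condition = map$condition[map$well == w],
               replicate = map$replicate[map$well == w],
               A = f@A, muMax = f@muMax, lag = f@lag, rmse = f@rmse,
               converged = f@converged, degenerate = f@degenerate)
  })
  do.call(rbind, rows)
}
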