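test_that("mean filter smooths with symmetric shrinking edges", {
  expect_equal(smoothSeries(rep(2, 7)), rep(2, 7))
  expect_equal(smoothSeries(c(0, 0, 1, 0, 0))[3], 0.2)
  # linear series unchanged in the interior (and at shrunk edges)
  x <- 1:10 * 0.5
  expect_equal(smoothSeries(x), x)
  expect_error(smoothSeries(1:3, window = 5), class = "invalidWindowError")
  expect_error(smoothSeries(1:10, window = 4), class = "invalidWindowError")
})

test_that("log normalization masks sub-blank points and errors on bad reference", {
  od <- rep(0.2, 5)
  expect_equal(logNormalize(od), rep(0, 5))
  expect_equal(logNormalize(c(0.1, 0.2))[2], log(2))
  odBlank <- c(0.1, 0.05, 0.2)
  y <- logNormalize(odBlank, blank = 0.06)
  expect_true(is.na(y[2]))
  expect_false(anyNA(y[c(1, 3)]))
  expect_error(logNormalize(c(0.05, 0.2), blank = 0.05),
               class = "referenceBelowBlankError")
})

test_that("instantaneous rate is exact for linear series and near-exact for Gompertz", {
  tm <- seq(0, 10, by = 0.5)
  expect_equal(instantaneousRate(tm, rep(1, length(tm)))$rate, rep(0, length(tm)))
  r <- instantaneousRate(tm, 0.5 * tm)$rate
  expect_equal(r, rep(0.5, length(tm)))
  # sampled Gompertz at 8.3-min spacing: max rate within 2% of muMax
  tg <- seq(0, 48, by = 8.3 / 60)
  y <- gompertz(tg, A = 3, muMax = 0.5, lag = 5)
  expect_lt(abs(max(instantaneousRate(tg, y)$rate) - 0.5) / 0.5, 0.02)
  expect_error(instantaneousRate(c(0, 2, 1), 1:3), class = "nonMonotoneTimeError")
})

test_that("Gompertz fit recovers noiseless parameters and declares no-growth", {
  tm <- seq(0, 48, by = 8.3 / 60)
  f <- fitGompertz(tm, gompertz(tm, 3, 0.5, 5))
  expect_true(f@converged)
  expect_lt(abs(carryingCapacity(f) - 3) / 3, 0.01)
  expect_lt(abs(muMax(f) - 0.5) / 0.5, 0.01)
  expect_lt(abs(lagTime(f) - 5) / 5, 0.01)
  # oracle: regenerate the curve from the fitted parameters
  expect_lt(max(abs(gompertz(tm, f@A, f@muMax, f@lag) - gompertz(tm, 3, 0.5, 5))),
            1e-6)
  flat <- fitGompertz(tm, rep(0, length(tm)))
  expect_true(flat@degenerate)
  expect_equal(muMax(flat), 0)
  expect_true(is.na(lagTime(flat)))
})

test_that("converged fits satisfy the analytic Gompertz identities", {
  tm <- seq(0, 48, by = 8.3 / 60)
  for (pars in list(c(2, 0.3, 4), c(3, 0.8, 8), c(4, 0.5, 2))) {
    f <- fitGompertz(tm, gompertz(tm, pars[1], pars[2], pars[3]))
    tFine <- seq(0, 48, by = 1e-3)
    yFine <- gompertz(tFine, f@A, f@muMax, f@lag)
    dy <- diff(yFine) / diff(tFine)
    expect_lt(abs(max(dy) - f@muMax), 1e-4)                     # max slope = muMax
    tStar <- f@lag + f@A / (f@muMax * exp(1))
    expect_lt(abs(tFine[which.max(dy)] - tStar), 1e-2)           # attained at t*
    yStar <- gompertz(tStar, f@A, f@muMax, f@lag)
    expect_lt(abs((tStar - yStar / f@muMax) - f@lag), 1e-6)      # tangent crosses at lag
    expect_lt(abs(gompertz(1e6, f@A, f@muMax, f@lag) - f@A), 1e-9)  # y(inf) = A
  }
})

test_that("fits are time-shift equivariant", {
  tm <- seq(0, 48, by = 8.3 / 60)
  y <- gompertz(tm, 3, 0.5, 5)
  f0 <- fitGompertz(tm, y)
  f2 <- fitGompertz(tm + 2, y)
  expect_equal(lagTime(f2), lagTime(f0) + 2, tolerance = 1e-4)
  expect_equal(muMax(f2), muMax(f0), tolerance = 1e-6)
})

test_that("noisy recovery stays within 10% median relative error", {
  tm <- seq(0, 48, by = 8.3 / 60)
  truth <- gompertz(tm, 3, 0.5, 5)
  errs <- t(vapply(1:25, function(s) {
    y <- truth + cocultol:::withSeed(s, rnorm(length(tm), 0, 0.02))
    f <- fitGompertz(tm, smoothSeries(y))
    c(abs(lagTime(f) - 5) / 5, abs(muMax(f) - 0.5) / 0.5)
  }, numeric(2)))
  expect_lt(median(errs[, 1]), 0.10)
  expect_lt(median(errs[, 2]), 0.10)
})

test_that("plate-level fitting blank-corrects and labels wells", {
  params <- communityParams()
  des <- experimentDesign(list(list(name = "neutral", species = "Lp", parentPh = 7)),
                          duration = 24, replicates = 2)
  tr <- simulateCommunity(params, des)
  pl <- observePlate(tr, params, des, seed = 3)
  fits <- fitGrowthCurves(pl)
  expect_equal(nrow(fits), 2)
  expect_true(all(fits$converged))
  expect_true(all(fits$muMax > 0.2))
})
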