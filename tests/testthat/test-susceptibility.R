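ladder5 <- c(0.3125, 0.625, 1.25, 2.5, 5)
blanks2sd <- 0.05 + c(-1, 1) * 0.005  # mean 0.05, population SD 0.005

test_that("MIC rule: within two blank SDs of the media controls", {
  ep <- data.frame(conc_ug_ml = ladder5,
                   od = c(0.90, 0.50, 0.058, 0.052, 0.051))
  res <- callMic(ep, blanks = blanks2sd)
  expect_equal(micValue(res), 1.25)
  expect_equal(micCensor(res), "none")
  expect_false(res@monotonicityFlag)

  allGrow <- data.frame(conc_ug_ml = ladder5, od = rep(0.9, 5))
  expect_equal(micCensor(callMic(allGrow, blanks2sd)), "gt_max")
  noGrow <- data.frame(conc_ug_ml = ladder5, od = rep(0.051, 5))
  expect_equal(micCensor(callMic(noGrow, blanks2sd)), "le_min")

  nonMono <- data.frame(conc_ug_ml = ladder5,
                        od = c(0.05, 0.50, 0.05, 0.05, 0.05))
  resNM <- callMic(nonMono, blanks2sd)
  expect_equal(micValue(resNM), 1.25)
  expect_true(resNM@monotonicityFlag)

  expect_error(callMic(ep, blanks = 0.05), class = "insufficientBlanksError")
  expect_error(callMic(ep[1:2, ], blanks2sd), class = "insufficientLadderError")
})

test_that("MIC call is invariant to well order and duplicated blanks", {
  ep <- data.frame(conc_ug_ml = rep(ladder5, each = 3),
                   od = rep(c(0.90, 0.50, 0.058, 0.052, 0.051), each = 3))
  base <- callMic(ep, blanks2sd)
  withr::local_seed(2)
  shuf <- callMic(ep[sample(nrow(ep)), ], blanks2sd)
  expect_equal(micValue(shuf), micValue(base))
  expect_equal(shuf@odMean, base@odMean)
  dupBlanks <- callMic(ep, rep(blanks2sd, 3))
  expect_equal(micValue(dupBlanks), micValue(base))
})

test_that("fold-MIC arithmetic matches the treatment descriptions", {
  expect_equal(foldMic(20, 1.25), 16)
  expect_equal(foldMic(50, 1.25), 40)
  expect_equal(foldMic(1.25, 1.25), 1)
  cens <- new("DoseResponseResult", ladder = ladder5, odMean = rep(0.9, 5),
              odSd = rep(0, 5), blankMean = 0.05, blankSd = 0.005,
              mic = NA_real_, censor = "gt_max", monotonicityFlag = FALSE)
  expect_error(foldMic(20, cens), class = "censoredMicError")
})

test_that("survival normalizes to t = 0 and keeps LOD records as bounds", {
  cfu <- validateCfuTable(data.frame(
    condition = "c", replicate = 1L, time_h = c(0, 24, 18),
    dilution = c(1e-1, 1, 1e-1), volume_ml = 0.003,
    colonies = c(120, 12, 0)))
  # CFU(0) = 4e5, CFU(24) = 4e3 -> S = 1e-2
  sv <- survivalSeries(cfu)
  expect_equal(sv$survival[sv$time_h == 0], 1)
  expect_equal(sv$survival[sv$time_h == 24], 1e-2)
  bound <- sv$bound[sv$time_h == 18]
  expect_true(sv$censored[sv$time_h == 18])
  expect_equal(bound, (1 / (0.003 * 0.1)) / 4e5, tolerance = 1e-9)  # ~8.3e-3
  expect_true(is.na(sv$survival[sv$time_h == 18]))

  noT0 <- cfu[cfu$time_h != 0, ]
  expect_error(survivalSeries(noT0), class = "missingT0Error")
})

test_that("kill-curve fit recovers (k, d) and the closed-form MDK99", {
  f <- fitKillCurve(exactSurvival(0.5, 4))
  expect_equal(f@model, "delayed")
  expect_lt(abs(killRate(f) - 0.5) / 0.5, 0.01)
  expect_lt(abs(killDelay(f) - 4) / 4, 0.01)
  expect_lt(abs(mdk99(f) - (4 + log(100) / 0.5)), 0.14)  # ~13.21 h
  flat <- fitKillCurve(exactSurvival(0, 0))
  expect_equal(killRate(flat), 0)
  expect_true(is.na(mdk99(flat)))
  expect_equal(flat@model, "none")
})

test_that("delay-free fits reduce to log-linear regression (grid oracle)", {
  tm <- seq(0, 20, by = 2)
  withr::local_seed(5)
  for (i in 1:5) {
    k <- runif(1, 0.2, 1)
    sv <- exactSurvival(k, 0, tm)
    sv$survival <- sv$survival * exp(rnorm(length(tm), 0, 0.05))
    sv$survival[1] <- 1
    f <- fitKillCurve(sv)
    # oracle: brute-force grid over (k, d)
    kGrid <- seq(0.05, 1.5, by = 0.002)
    sse <- function(kk, dd) sum((log(sv$survival) + kk * pmax(0, tm - dd))^2)
    sse0 <- vapply(kGrid, sse, numeric(1), dd = 0)
    kHat <- kGrid[which.min(sse0)]
    expect_lt(abs(killRate(f) - kHat), 0.01)
    # and equivalence with ordinary no-intercept regression on max(0, t)
    lmFit <- -unname(coef(lm(log(sv$survival) ~ 0 + tm)))
    if (f@model == "immediate") expect_equal(killRate(f), lmFit, tolerance = 1e-9)
  }
})

test_that("MDK99 survives Poisson plating noise", {
  params <- communityParams()
  truth <- params$kill$rifampin
  kTrue <- truth$k0 * (1 + truth$theta * 1)
  mdkTrue <- truth$d0 + log(100) / kTrue
  errs <- vapply(1:30, function(s) {
    cfu <- simulateKillExperiment(s = 1, drug = "rifampin", conc = 50,
                                  params = params, seed = s)
    f <- fitKillCurve(survivalSeries(cfu))
    abs(mdk99(f) - mdkTrue) / mdkTrue
  }, numeric(1))
  expect_lt(median(errs), 0.10)
})

test_that("response classification follows the MIC/MDK99 taxonomy", {
  killRef <- fitKillCurve(exactSurvival(0.9, 2))
  killTol <- fitKillCurve(exactSurvival(0.3, 2))   # MDK ratio ~ 2.9
  killSame <- fitKillCurve(exactSurvival(0.82, 2)) # MDK ratio ~ 1.1
  tol <- classifyResponse(1.25, killRef, 1.25, killTol)
  expect_equal(interactionLabel(tol), "tolerance")
  expect_equal(tol@micRatio, 1)
  res <- classifyResponse(1.25, killRef, 10, killRef)
  expect_equal(interactionLabel(res), "resistance")
  nei <- classifyResponse(1.25, killRef, 1.25, killSame)
  expect_equal(interactionLabel(nei), "neither")
  cens <- new("DoseResponseResult", ladder = ladder5, odMean = rep(0.9, 5),
              odSd = rep(0, 5), blankMean = 0.05, blankSd = 0.005,
              mic = NA_real_, censor = "gt_max", monotonicityFlag = FALSE)
  ind <- classifyResponse(cens, killRef, 1.25, killTol)
  expect_equal(interactionLabel(ind), "indeterminate")
})
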