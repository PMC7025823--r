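params <- communityParams()

test_that("zero inoculum gives null dynamics", {
  des <- experimentDesign(list(list(name = "empty", species = character(0))),
                          duration = 48)
  tr <- simulateCommunity(params, des)[[1]]
  st <- tr@state
  expect_true(all(abs(st[, "B_Lp"]) < 1e-12))
  expect_true(all(abs(st[, "G"] - params$glucose0) < 1e-6))
  expect_true(all(abs(st[, "L"]) < 1e-9))
  expect_equal(unname(st[, "pH"]), rep(6.75, nrow(st)), tolerance = 1e-9)
})

test_that("frozen defaults reproduce the monoculture acidification anchors", {
  tr <- simulateCommunity(params, scenarioDesign("monoculture_Lp"))[[1]]
  n <- nrow(tr@state)
  expect_gte(tr@state[n, "pH"], 3.6)
  expect_lte(tr@state[n, "pH"], 3.9)
  expect_lt(tr@rates[n, "mu_Lp"], 1e-3)
  # pH monotone non-increasing without a lactate consumer
  expect_true(all(diff(tr@state[, "pH"]) <= 1e-9))
  # refinement stability: re-solve at 10x tighter tolerance
  tr10 <- simulateCommunity(params, scenarioDesign("monoculture_Lp"),
                            rtol = 1e-9, atol = 1e-11)[[1]]
  expect_lt(max(abs(tr@state - tr10@state) / (abs(tr10@state) + 1)), 1e-6)
})

test_that("co-culture consumes lactate and recovers pH before 48 h", {
  tr <- simulateCommunity(params, scenarioDesign("coculture_Lp_Ap"))[[1]]
  st <- tr@state; n <- nrow(st); ph <- st[, "pH"]
  expect_lt(st[n, "L"], 2)                      # < 2 mM lactate at 48 h
  i20 <- which.min(abs(tr@time - 20))
  expect_gt(ph[n], ph[i20])                     # terminal pH rise
  expect_lt(tr@time[which.min(ph)], 48)         # minimum attained before 48 h
  expect_gt(ph[n], min(ph))
  mono <- simulateCommunity(params, scenarioDesign("monoculture_Lp"))[[1]]
  expect_gte(st[n, "B_Lp"], mono@state[nrow(mono@state), "B_Lp"])
})

test_that("lactate bookkeeping conserves the glucose-derived pool", {
  for (scn in c("monoculture_Lp", "coculture_Lp_Ap")) {
    tr <- simulateCommunity(params, scenarioDesign(scn))[[1]]
    produced <- params$yLG * (params$glucose0 - tr@state[, "G"])
    # present lactate can never exceed cumulative production
    expect_true(all(produced - tr@state[, "L"] > -1e-6))
    if (scn == "monoculture_Lp")  # equality without a consumer
      expect_lt(max(abs(produced - tr@state[, "L"])), 1e-6)
  }
})

test_that("pH-history coupling orders the Baranyi state and the lag", {
  expect_gt(historyState(7, params), historyState(3.77, params))
  expect_gt(acidState(3.77, params), 0.9)
  expect_lt(acidState(7, params), 0.1)
  des <- experimentDesign(list(
    list(name = "neutral", species = "Lp", parentPh = 7),
    list(name = "acid", species = "Lp", parentPh = 3.77)), duration = 24)
  tr <- simulateCommunity(params, des)
  # time to reach half the final ln-fold biomass is earlier for neutral history
  halfTime <- function(t) {
    y <- log(t@state[, "B_Lp"] / t@state[1, "B_Lp"])
    t@time[min(which(y >= max(y) / 2))]
  }
  expect_lt(halfTime(tr$neutral), halfTime(tr$acid))
})

test_that("observePlate implements the forward optics and is seed-deterministic", {
  des <- experimentDesign(list(list(name = "const", species = "Lp")),
                          duration = 1, interval = 0.25, replicates = 2)
  # zero biomass: OD at blank level in every well
  trajs <- list(const = constantTrajectory(ph = 6.98, biomass = 0))
  noiseless <- communityParams(sigmaOd = 0, sigmaF = 0)
  pl <- observePlate(trajs, noiseless, des, seed = 1)
  expect_true(all(abs(channelValues(pl, "OD600") - noiseless$blankOd) < 1e-12))
  # pH at the dye pKa: corrected channel ratio is the sigmoid midpoint
  w <- plateMap(pl)$well[plateMap(pl)$role == "sample"][1]
  r <- (channelValues(pl, "F490_535", w) - noiseless$bgF490) /
       (channelValues(pl, "F440_535", w) - noiseless$bgF440)
  expect_equal(unname(r), rep((noiseless$rMin + noiseless$rMax) / 2, 5),
               tolerance = 1e-12)
  # determinism with noise on
  p1 <- observePlate(trajs, params, des, seed = 42)
  p2 <- observePlate(trajs, params, des, seed = 42)
  expect_identical(SummarizedExperiment::assays(p1), SummarizedExperiment::assays(p2))
  expect_error(observePlate(list(), params, des), class = "missingTrajectoryError")
})

test_that("dose-response generator suppresses growth at and above the true MIC", {
  ladder <- 0.3125 * 2^(0:4)
  noiseless <- communityParams(sigmaOd = 0)
  dr <- simulateDoseResponse(1.25, ladder, params = noiseless, seed = 1)
  smp <- dr[dr$role == "sample", ]
  odAt <- function(cc) mean(smp$od[smp$conc_ug_ml == cc])
  for (cc in ladder[ladder >= 1.25])
    expect_lt(odAt(cc) - noiseless$blankOd, 0.002)
  for (cc in ladder[ladder < 1.25])
    expect_gt(odAt(cc) - noiseless$blankOd, 0.5)
  # MIC above the ladder: growth everywhere
  drHigh <- simulateDoseResponse(40, ladder, params = noiseless, seed = 1)
  smpH <- drHigh[drHigh$role == "sample", ]
  expect_true(all(smpH$od - noiseless$blankOd > 0.5))
  expect_identical(simulateDoseResponse(1.25, ladder, seed = 9),
                   simulateDoseResponse(1.25, ladder, seed = 9))
  expect_error(simulateDoseResponse(1, numeric(0)), class = "emptyLadderError")
  expect_error(simulateDoseResponse(1, c(1, 3)), class = "invalidLadderError")
})

test_that("kill experiments follow the acid-state coupling", {
  # theta chosen so k vanishes: survival ~ 1 at all times up to Poisson noise
  pz <- communityParams()
  pz$kill$erythromycin$theta <- 1
  cfu <- simulateKillExperiment(s = 1, drug = "erythromycin", conc = 2,
                                params = pz, seed = 5)
  sv <- survivalSeries(cfu)
  # ~190 expected colonies per spot: survival ratios fluctuate by ~10%
  expect_true(all(abs(sv$survival - 1) < 0.35))
  expect_lt(abs(mean(sv$survival) - 1), 0.1)
  # closed-form time to S = 1e-2 is strictly smaller for acid-adapted (rif)
  kFor <- function(s) params$kill$rifampin$k0 * (1 + params$kill$rifampin$theta * s)
  d0 <- params$kill$rifampin$d0
  expect_lt(d0 + log(100) / kFor(1), d0 + log(100) / kFor(0))
  expect_error(simulateKillExperiment(s = 1.5, drug = "rifampin", conc = 50),
               class = "invalidAcidStateError")
  expect_error(simulateKillExperiment(drug = "rifampin", conc = 0.1),
               class = "subMicConcentrationError")
  expect_identical(simulateKillExperiment(3.77, "rifampin", 50, seed = 1),
                   simulateKillExperiment(3.77, "rifampin", 50, seed = 1))
})

test_that("plating emulation is Poisson with a countable dilution choice", {
  traj <- constantTrajectory(biomass = 0)
  cfu0 <- plateCfu(traj, times = c(0, 1), seed = 1)
  expect_true(all(cfu0$below_lod))
  expect_true(all(cfu0$colonies == 0))
  # Poisson property: mean ~ variance at fixed expected count
  b <- 1e-4  # expected CFU/mL = 4e4; undiluted 3 uL spot -> 120 colonies
  traj3 <- constantTrajectory(biomass = b)
  reps <- plateCfu(traj3, times = 0, seed = 2, replicates = 1000)
  expected <- params$cfuPerOd * b * 0.003 * reps$dilution[1]
  m <- mean(reps$colonies); v <- var(reps$colonies)
  expect_lt(abs(m - expected), 3 * sqrt(expected / 1000))
  expect_lt(abs(v / m - 1), 0.2)
  expect_true(all(reps$colonies <= 400))
  expect_error(plateCfu(traj3, times = 99), class = "timeRangeError")
})

test_that("cell-track generator matches the observed morphology", {
  tr <- simulateCellTracks(c(Lp = 500, Ap = 500), seed = 31)
  first <- tr[tr$frame == 0, ]
  lenLp <- first$length_um[first$true_species == "Lp"]
  expect_lt(abs(mean(lenLp) - 2.46), 3 * 0.78 / sqrt(500))
  lenAp <- first$length_um[first$true_species == "Ap"]
  expect_lt(abs(mean(lenAp) - 1.66), 3 * 0.38 / sqrt(500))
  # aspect-ratio spread matches the observed distributions
  ratioLp <- lenLp / first$width_um[first$true_species == "Lp"]
  expect_lt(abs(sd(ratioLp) - 0.91), 0.2)
  # zero noise, zero growth: constant traces
  pz <- communityParams(trackNoiseSd = 0, elongRateLp = 0, elongRateAp = 0)
  tc <- simulateCellTracks(c(Lp = 3, Ap = 0), params = pz, seed = 1)
  perCell <- tapply(tc$length_um, tc$cell_id, function(x) diff(range(x)))
  expect_true(all(perCell < 1e-12))
  expect_identical(simulateCellTracks(5, seed = 8), simulateCellTracks(5, seed = 8))
  expect_error(simulateCellTracks(-1), class = "invalidCountError")
})
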