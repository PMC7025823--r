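test_that("track filtering applies the length and timepoint rules", {
  tooLong <- constantTrack("long", 3, nFrames = 20)
  tooLong$length_um[10] <- 7               # any raw frame > 6 um removes the cell
  tooShort <- constantTrack("short", 3, nFrames = 10)
  border <- constantTrack("border", 3, nFrames = 15)   # exactly 15: removed (> 15 required)
  keep <- constantTrack("keep", 3, nFrames = 20)
  keep$length_um <- pmin(keep$length_um * 1.9, 5.9)    # max 5.9 um: retained
  tracks <- validateCellTracks(rbind(tooLong, tooShort, border, keep))
  out <- filterTracks(tracks)
  expect_equal(unique(out$cell_id), "keep")
  expect_equal(unname(attr(out, "removed")["over_length"]), 1L)
  expect_equal(unname(attr(out, "removed")["too_few_timepoints"]), 2L)
})

test_that("aspect-ratio calls match the printed species morphologies", {
  # log10(3.41) = 0.533 > 0.375 -> Lp; log10(1.87) = 0.272 -> Ap
  tracks <- validateCellTracks(rbind(constantTrack("lp", 3.41),
                                     constantTrack("ap", 1.87)))
  feats <- classifySpecies(tracks)
  calls <- setNames(feats$cells$call, feats$cells$cell_id)
  expect_equal(unname(calls["lp"]), "Lp")
  expect_equal(unname(calls["ap"]), "Ap")
  # exactly at threshold counts as above (tie rule)
  tie <- constantTrack("tie", 10^0.375)
  featsTie <- classifySpecies(validateCellTracks(tie))
  expect_equal(featsTie$cells$call, "Lp")
  expect_equal(featsTie$cells$fracAbove, 1)
  # alternate equally above/below: ambiguous
  alt <- constantTrack("alt", 3.41, nFrames = 20)
  alt$length_um[seq(1, 20, by = 2)] <- 1.0   # half the frames far below
  featsAlt <- classifySpecies(validateCellTracks(alt), classifierConfig(window = 1))
  expect_equal(featsAlt$cells$call, "ambiguous")
})

test_that("classification uses the fraction rule, invariant to frame order and time scale", {
  withr::local_seed(9)
  tr <- simulateCellTracks(c(Lp = 20, Ap = 20), seed = 12)
  f1 <- classifySpecies(tr)
  # uniform time rescaling changes nothing in the fraction-based call
  tr2 <- tr; tr2$time_h <- tr2$time_h * 3
  f2 <- classifySpecies(tr2)
  expect_equal(f1$cells$call, f2$cells$call)
  # raising the required fraction only shrinks the set of confident calls
  fracs <- c(0.7, 0.8, 0.9, 1.0)
  nCalled <- vapply(fracs, function(q) {
    f <- classifySpecies(tr, classifierConfig(traceFraction = q))
    sum(f$cells$call != "ambiguous")
  }, numeric(1))
  expect_true(all(diff(nCalled) <= 0))
})

test_that("noiseless one-sided tracks classify exactly by threshold sign (brute force)", {
  withr::local_seed(21)
  for (i in 1:10) {
    ratio <- exp(runif(1, log(1.2), log(4)))
    if (abs(log10(ratio) - 0.375) < 0.02) next
    tr <- validateCellTracks(constantTrack(paste0("c", i), ratio))
    call <- classifySpecies(tr)$cells$call
    truth <- if (log10(ratio) >= 0.375) "Lp" else "Ap"
    expect_equal(call, truth)
  }
})

test_that("elongation-rate summaries: constant cells 0, exponential cells at rate", {
  const <- validateCellTracks(rbind(constantTrack("a", 3.41),
                                    constantTrack("b", 3.0)))
  featsC <- classifySpecies(const)
  ratesC <- elongationRates(featsC)
  expect_true(all(abs(ratesC$mean_rate) < 1e-12))
  expect_true(all(ratesC$se < 1e-12))

  expGrow <- constantTrack("g", 3.41, nFrames = 20)
  expGrow$length_um <- expGrow$length_um * exp(0.5 * expGrow$time_h)
  featsG <- classifySpecies(validateCellTracks(expGrow), classifierConfig(window = 1))
  ratesG <- elongationRates(featsG)
  expect_true(all(abs(ratesG$mean_rate - 0.5) < 1e-9))
})

test_that("lag differences between conditions appear as earlier rate rises", {
  pz <- communityParams(trackNoiseSd = 0.01)
  co <- simulateCellTracks(c(Lp = 40), list(lagMeanLp = 1, lagSdLp = 0.1,
                                            label = "co"), pz, seed = 3,
                           nFrames = 40)
  mono <- simulateCellTracks(c(Lp = 40), list(lagMeanLp = 3, lagSdLp = 0.1,
                                              label = "mono"), pz, seed = 4,
                             nFrames = 40)
  rateAt <- function(tracks, t) {
    r <- elongationRates(classifySpecies(filterTracks(tracks, classifierConfig(maxLength = 99)),
                                         classifierConfig(maxLength = 99)))
    r <- r[r$call == "Lp", ]
    r$mean_rate[which.min(abs(r$time_h - t))]
  }
  expect_gt(rateAt(co, 2), rateAt(mono, 2) + 0.1)
})

test_that("classification error against truth is computed on confident calls only", {
  perfect <- validateCellTracks(rbind(
    constantTrack("lp1", 3.41, species = "Lp"),
    constantTrack("lp2", 3.2, species = "Lp"),
    constantTrack("ap1", 1.87, species = "Ap")))
  ce <- classificationError(classifySpecies(perfect))
  expect_equal(ce$error, 0)
  expect_equal(ce$nCalled, 3)

  amb <- constantTrack("x", 3.41, species = "Lp", nFrames = 20)
  amb$length_um[seq(1, 20, 2)] <- 1
  ceA <- classificationError(classifySpecies(validateCellTracks(amb),
                                             classifierConfig(window = 1)))
  expect_true(is.na(ceA$error))
  expect_equal(ceA$nAmbiguous, 1)

  noLab <- constantTrack("y", 3.41)
  expect_error(classificationError(classifySpecies(validateCellTracks(noLab))),
               class = "noLabelsError")
})
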