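#' Simulate mono- and co-culture dynamics
#'
#' Integrates the deterministic consumer-resource model for every condition
#' in the design. Lp grows on glucose (Monod), modulated by the Rosso
#' cardinal-pH factor and its Baranyi physiological state `q`; each mM of
#' glucose consumed yields `yLG` mM lactate; the Acetobacter partner grows
#' on and consumes lactate; the medium pH is the algebraic image of lactate
#' through the saturating buffering map. No observation noise is added at
#' this stage; trajectories are pure functions of (params, design).
#'
#' @param params a [communityParams()] list.
#' @param design an [experimentDesign()] list.
#' @param rtol,atol solver tolerances (adaptive solver; halving `rtol`
#'   changes states by < 1e-6 relative).
#' @return a named list of [Trajectory-class] objects, one per condition.
#' @export
simulateCommunity <- function(params = communityParams(),
                              design = scenarioDesign("coculture_Lp_Ap"),
                              rtol = 1e-8, atol = 1e-10) {
  grid <- seq(0, design$duration, by = design$interval)
  out <- lapply(design$conditions, function(cnd) {
    q0 <- if (cnd$inoculumLp > 0) historyState(cnd$parentPh, params) else params$qLo
    # fresh medium pH can be set by the protocol; shift the buffering map
    # intercept so pH(lactate0) = startPh for this condition
    ph0 <- cnd$startPh + params$dPhMax * cnd$lactate0 / (cnd$lactate0 + params$kBuf)
    pLoc <- params; pLoc$ph0 <- ph0
    y0 <- c(B_Lp = cnd$inoculumLp, B_Ax = cnd$inoculumAx,
            G = params$glucose0, L = cnd$lactate0, q = q0)
    sol <- deSolve::ode(y = y0, times = grid, func = communityRhs,
                        parms = pLoc, method = "lsoda",
                        rtol = rtol, atol = atol, maxsteps = 50000)
    if (any(!is.finite(sol))) {
      bad <- grid[which(rowSums(!is.finite(sol)) > 0)[1]]
      cocultolStop("nonFiniteStateError",
                   sprintf("non-finite state first at t = %.3f h (condition %s)",
                           bad, cnd$name))
    }
    st <- pmax(sol[, c("B_Lp", "B_Ax", "G", "L", "q")], 0)
    st <- cbind(st, pH = bufferedPh(st[, "L"], pLoc))
    mu <- cbind(
      mu_Lp = pLoc$muMaxLp * st[, "G"] / (st[, "G"] + pLoc$kG) *
        cardinalPh(st[, "pH"], pLoc$phMinLp, pLoc$phOptLp, pLoc$phMaxLp) *
        st[, "q"] / (1 + st[, "q"]),
      mu_Ax = pLoc$muMaxAx * st[, "L"] / (st[, "L"] + pLoc$kL) *
        cardinalPh(st[, "pH"], pLoc$phMinAx, pLoc$phOptAx, pLoc$phMaxAx))
    new("Trajectory", time = grid, state = st, rates = mu,
        condition = cnd$name, species = cnd$species)
  })
  names(out) <- vapply(design$conditions, `[[`, character(1), "name")
  out
}

communityRhs <- function(t, y, p) {
  bLp <- max(y[["B_Lp"]], 0); bAx <- max(y[["B_Ax"]], 0)
  g <- max(y[["G"]], 0); l <- max(y[["L"]], 0); q <- max(y[["q"]], 0)
  ph <- p$ph0 - p$dPhMax * l / (l + p$kBuf)
  gLp <- cardinalPh(ph, p$phMinLp, p$phOptLp, p$phMaxLp)
  gAx <- cardinalPh(ph, p$phMinAx, p$phOptAx, p$phMaxAx)
  muLp <- p$muMaxLp * g / (g + p$kG) * gLp * q / (1 + q)
  muAx <- p$muMaxAx * l / (l + p$kL) * gAx
  dBLp <- muLp * bLp
  dG <- -muLp * bLp / p$yieldG
  uptake <- p$vA * bAx * l / (l + p$kL)
  dL <- p$yLG * (-dG) - uptake
  dBAx <- muAx * bAx
  # q is the adjustment state of the present Lp population only; cap its
  # exponential growth once saturated (q/(1+q) ~ 1) to keep the system tame
  dq <- if (bLp > 0 && q < 1e6) p$muMaxLp * gLp * q else 0
  list(c(dBLp, dBAx, dG, dL, dq))
}

#' Generate plate-reader observations from trajectories
#'
#' Forward observation model: `OD600` is biomass plus the blank offset with
#' Gaussian noise; the BCECF channels are generated from the trajectory pH
#' through the forward sigmoid \eqn{R(pH)} split into a 440-excited channel
#' (intensity scale + background) and a 490-excited channel (scale x ratio
#' + background), each with per-channel noise. Each condition gets
#' `replicates` dye-loaded sample wells and one dye-free control well
#' (background fluorescence only); two media blanks are appended. Identical
#' seeds give bit-identical plates.
#'
#' @param trajs list of [Trajectory-class] from [simulateCommunity()].
#' @param params a [communityParams()] list.
#' @param design the [experimentDesign()] used for the simulation.
#' @param seed integer RNG seed (NULL for ambient RNG).
#' @return a [PlateTimeSeries-class].
#' @export
observePlate <- function(trajs, params = communityParams(),
                         design = scenarioDesign("coculture_Lp_Ap"),
                         seed = NULL) {
  condNames <- vapply(design$conditions, `[[`, character(1), "name")
  missing <- setdiff(condNames, names(trajs))
  if (length(missing))
    cocultolStop("missingTrajectoryError",
                 paste0("no trajectory for condition(s): ",
                        paste(missing, collapse = ", ")))
  tm <- trajs[[condNames[1]]]@time
  nT <- length(tm)

  rows <- list(); odL <- list(); f440L <- list(); f490L <- list()
  addWell <- function(cond, rep_, role, species, traj) {
    i <- length(rows) + 1L
    rows[[i]] <<- data.frame(
      well = sprintf("%s%d", LETTERS[(i - 1L) %/% 12L + 1L], (i - 1L) %% 12L + 1L),
      condition = cond, species = species, role = role, drug = "none",
      conc_ug_ml = 0, start_ph = NA, replicate = rep_, known_ph = NA)
    if (is.null(traj)) {
      biomass <- rep(0, nT); ratio <- NULL
    } else {
      biomass <- traj@state[, "B_Lp"] + traj@state[, "B_Ax"]
      ratio <- bcecfRatio(traj@state[, "pH"], params)
    }
    odL[[i]] <<- params$odPerBiomass * biomass + params$blankOd +
      rnorm(nT, 0, params$sigmaOd)
    if (role == "sample" && !is.null(ratio)) {
      f440L[[i]] <<- params$intensityScale + params$bgF440 + rnorm(nT, 0, params$sigmaF)
      f490L[[i]] <<- params$intensityScale * ratio + params$bgF490 +
        rnorm(nT, 0, params$sigmaF)
    } else {
      f440L[[i]] <<- params$bgF440 + rnorm(nT, 0, params$sigmaF)
      f490L[[i]] <<- params$bgF490 + rnorm(nT, 0, params$sigmaF)
    }
  }

  withSeed(seed, {
    for (cnd in design$conditions) {
      sp <- paste(cnd$species, collapse = "+")
      spLabel <- gsub("Ax", "Ap", sp)  # plate-map codes use species names
      for (r in seq_len(design$replicates))
        addWell(cnd$name, r, "sample", spLabel, trajs[[cnd$name]])
      addWell(cnd$name, 1L, "dye_free_control", spLabel, trajs[[cnd$name]])
    }
    addWell("blank", 1L, "media_blank", "", NULL)
    addWell("blank", 2L, "media_blank", "", NULL)
  })

  map <- do.call(rbind, rows)
  mk <- function(lst) {
    m <- do.call(rbind, lst); rownames(m) <- map$well; m
  }
  PlateTimeSeries(list(OD600 = mk(odL), F440_535 = mk(f440L), F490_535 = mk(f490L)),
                  tm, map)
}

#' BCECF forward model: pH to excitation ratio
#'
#' \eqn{R(pH) = R_{min} + (R_{max}-R_{min}) / (1 + 10^{n_H (pK'_a - pH)})},
#' the forward sigmoid inverted by [invertToPh()].
#'
#' @param ph pH value(s).
#' @param params a [communityParams()] list (uses rMin, rMax, pKaBcecf, nH).
#' @return ratio value(s).
#' @export
bcecfRatio <- function(ph, params = communityParams()) {
  params$rMin + (params$rMax - params$rMin) /
    (1 + 10^(params$nH * (params$pKaBcecf - ph)))
}

#' Simulate an endpoint dose-response plate
#'
#' 24-h endpoint ODs over a two-fold antibiotic ladder: growth is suppressed
#' to the blank level for concentrations at or above the true MIC through a
#' steep Hill factor on the carrying capacity (midpoint at
#' `trueMic`/sqrt(2), i.e. between the ladder points below and at the MIC).
#' Media-blank wells with the stated SD are included.
#'
#' @param trueMic true MIC (ug/mL); should lie on or between ladder points.
#' @param ladder increasing two-fold concentration series (ug/mL).
#' @param hillSlope steepness of the suppression factor.
#' @param params a [communityParams()] list (`blankOd`, `sigmaOd`).
#' @param seed integer RNG seed.
#' @param growthOd asymptotic drug-free endpoint OD above blank.
#' @param replicates sample wells per concentration.
#' @param nBlanks number of media-blank wells (>= 2).
#' @return a `data.frame` with columns `well, role, conc_ug_ml, replicate, od`.
#' @export
simulateDoseResponse <- function(trueMic, ladder, hillSlope = 40,
                                 params = communityParams(), seed = NULL,
                                 growthOd = 2.0, replicates = 4, nBlanks = 12) {
  if (length(ladder) == 0)
    cocultolStop("emptyLadderError", "concentration ladder is empty")
  if (any(diff(ladder) <= 0))
    cocultolStop("invalidLadderError", "ladder must be strictly increasing")
  if (length(ladder) > 1 && any(abs(ladder[-1] / ladder[-length(ladder)] - 2) > 0.01))
    cocultolStop("invalidLadderError", "ladder must be a two-fold series")
  withSeed(seed, {
    sample_ <- expand.grid(replicate = seq_len(replicates), conc_ug_ml = ladder)
    factor_ <- 1 / (1 + (sample_$conc_ug_ml * sqrt(2) / trueMic)^hillSlope)
    sample_$od <- params$blankOd + growthOd * factor_ +
      rnorm(nrow(sample_), 0, params$sigmaOd)
    sample_$role <- "sample"
    blanks <- data.frame(replicate = seq_len(nBlanks), conc_ug_ml = 0,
                         od = params$blankOd + rnorm(nBlanks, 0, params$sigmaOd),
                         role = "media_blank")
    out <- rbind(sample_, blanks)
    out$well <- sprintf("%s%d", LETTERS[(seq_len(nrow(out)) - 1L) %/% 12L + 1L],
                        (seq_len(nrow(out)) - 1L) %% 12L + 1L)
    out[c("well", "role", "conc_ug_ml", "replicate", "od")]
  })
}

#' Simulate a time-kill CFU experiment
#'
#' Ground-truth survival follows the delayed exponential killing model
#' \eqn{S(t) = \exp(-k \max(0, t-d))}. The kill rate is coupled to the
#' culture's acid-adaptation state s (from its parent-culture final pH):
#' rifampin kills acid-adapted cultures faster, \eqn{k = k_0(1+\theta s)};
#' erythromycin protects them, \eqn{k = k_0(1-\theta s)}. Plating is
#' emulated per timepoint: an automatic choice of the serial dilution giving
#' an expected colony count in the countable band, then Poisson-distributed
#' colonies; zero-colony spots are below the limit of detection.
#'
#' @param parentPh final pH of the parent culture (sets s); ignored when `s`
#'   is given directly.
#' @param drug `"rifampin"` or `"erythromycin"`.
#' @param conc drug concentration (ug/mL); must exceed the drug's MIC.
#' @param params a [communityParams()] list.
#' @param times CFU sampling times (h), starting at 0.
#' @param seed integer RNG seed.
#' @param s acid-adaptation state in \[0, 1\] (overrides `parentPh`).
#' @param inoculumOd starting density in OD-equivalents (CFU(0) =
#'   `cfuPerOd * inoculumOd`).
#' @param dilutions candidate serial-dilution factors (< 1).
#' @param volume plated spot volume (mL).
#' @param condition condition label for the output table.
#' @param replicates biological replicates.
#' @return a validated CFU `data.frame` (see [readCfuTable()]).
#' @export
simulateKillExperiment <- function(parentPh = 3.77, drug = "rifampin", conc = 50,
                                   params = communityParams(),
                                   times = seq(0, 24, by = 2), seed = NULL,
                                   s = NULL, inoculumOd = 0.1,
                                   dilutions = 5^-(0:9), volume = 0.003,
                                   condition = NULL, replicates = 1) {
  if (!drug %in% names(params$kill))
    cocultolStop("unknownDrugError", paste0("no kill parameters for drug: ", drug))
  if (conc <= params$trueMic[[drug]])
    cocultolStop("subMicConcentrationError",
                 "kill experiments require a concentration above the MIC")
  if (is.null(s)) s <- acidState(parentPh, params)
  if (s < 0 || s > 1)
    cocultolStop("invalidAcidStateError", "acid state s must lie in [0, 1]")
  kp <- params$kill[[drug]]
  k <- if (drug == "erythromycin") kp$k0 * (1 - kp$theta * s)
       else kp$k0 * (1 + kp$theta * s)
  k <- max(k, 0)
  if (is.null(condition))
    condition <- sprintf("%s_parentPh%.2f", drug, if (is.null(parentPh)) NA else parentPh)
  cfu0 <- params$cfuPerOd * inoculumOd
  surv <- exp(-k * pmax(0, times - kp$d0))
  withSeed(seed, {
    recs <- lapply(seq_len(replicates), function(r) {
      expected <- cfu0 * surv
      dil <- vapply(expected, pickDilution, numeric(1),
                    dilutions = dilutions, volume = volume)
      colonies <- rpois(length(times), expected * volume * dil)
      data.frame(condition = condition, replicate = r, time_h = times,
                 dilution = dil, volume_ml = volume, colonies = colonies)
    })
    validateCfuTable(do.call(rbind, recs))
  })
}

# choose the serial dilution whose expected colony count is countable
# (3..300), preferring the most colonies for precision; fall back to the
# nearest feasible end of the ladder
pickDilution <- function(expectedCfu, dilutions = 5^-(0:9), volume = 0.003) {
  counts <- expectedCfu * volume * dilutions
  inBand <- counts >= 3 & counts <= 300
  if (any(inBand)) return(dilutions[inBand][which.max(counts[inBand])])
  if (all(counts > 300)) return(min(dilutions))
  max(dilutions)
}

#' Plate CFUs from a simulated trajectory
#'
#' Expected CFU/mL is `cfuPerOd` times total biomass at the requested times
#' (linear interpolation on the trajectory grid); colonies are Poisson draws
#' after the automatic dilution choice of [simulateKillExperiment()].
#'
#' @param traj a [Trajectory-class].
#' @param times sampling times (h), within the trajectory range.
#' @inheritParams simulateKillExperiment
#' @return a validated CFU `data.frame`.
#' @export
plateCfu <- function(traj, times, params = communityParams(), seed = NULL,
                     dilutions = 5^-(0:9), volume = 0.003, replicates = 1) {
  if (any(times < min(traj@time) | times > max(traj@time)))
    cocultolStop("timeRangeError", "sampling times outside the trajectory range")
  biomass <- stats::approx(traj@time, traj@state[, "B_Lp"] + traj@state[, "B_Ax"],
                           xout = times)$y
  expected <- params$cfuPerOd * biomass
  withSeed(seed, {
    recs <- lapply(seq_len(replicates), function(r) {
      dil <- vapply(expected, pickDilution, numeric(1),
                    dilutions = dilutions, volume = volume)
      data.frame(condition = traj@condition, replicate = r, time_h = times,
                 dilution = dil, volume_ml = volume,
                 colonies = rpois(length(times), expected * volume * dil))
    })
    validateCfuTable(do.call(rbind, recs))
  })
}

#' Simulate single-cell tracks
#'
#' Generates per-cell length/width time series matching the observed
#' morphology of the two species: Lp birth lengths ~ Normal(2.46, 0.78) um
#' and widths ~ Normal(0.72, 0.12) um; Ap ~ Normal(1.66, 0.38) and
#' Normal(0.90, 0.09) um (truncated positive). Each cell draws a lag from a
#' condition-dependent Normal, then elongates exponentially at its species
#' rate; every frame gets independent multiplicative measurement noise. The
#' true species is recorded for classifier validation.
#'
#' @param nPerSpecies cells per species; a single number or a named vector
#'   `c(Lp = ..., Ap = ...)`.
#' @param condition list with `lagMeanLp`, `lagSdLp` (h) controlling the Lp
#'   lag distribution (co-culture histories have shorter lags), plus an
#'   optional `label`.
#' @param params a [communityParams()] list.
#' @param seed integer RNG seed.
#' @param nFrames frames per cell.
#' @param frameInterval frame spacing (h); default 5 min.
#' @return a validated track `data.frame` (see [readCellTracks()]).
#' @export
simulateCellTracks <- function(nPerSpecies = 100,
                               condition = list(lagMeanLp = 1, lagSdLp = 0.3,
                                                label = "coculture"),
                               params = communityParams(), seed = NULL,
                               nFrames = 30, frameInterval = 5 / 60) {
  if (length(nPerSpecies) == 1L && is.null(names(nPerSpecies)))
    nPerSpecies <- c(Lp = nPerSpecies, Ap = nPerSpecies)
  if (any(nPerSpecies < 0))
    cocultolStop("invalidCountError", "cell counts must be >= 0")
  tm <- (seq_len(nFrames) - 1L) * frameInterval
  morph <- list(
    Lp = list(len = params$morphLenLp, wid = params$morphWidLp,
              corr = params$morphCorrLp, rate = params$elongRateLp),
    Ap = list(len = params$morphLenAp, wid = params$morphWidAp,
              corr = params$morphCorrAp, rate = params$elongRateAp))
  withSeed(seed, {
    recs <- list()
    for (sp in names(nPerSpecies)) {
      n <- nPerSpecies[[sp]]
      if (n == 0) next
      m <- morph[[sp]]
      for (i in seq_len(n)) {
        # correlated (length, width) so the aspect-ratio spread matches the
        # observed distributions, not just the marginals
        repeat {
          z1 <- rnorm(1); z2 <- rnorm(1)
          l0 <- m$len[1] + m$len[2] * z1
          w0 <- m$wid[1] + m$wid[2] * (m$corr * z1 + sqrt(1 - m$corr^2) * z2)
          if (l0 > 0.2 && w0 > 0.1) break
        }
        lagMean <- if (sp == "Lp") condition$lagMeanLp else 2 * condition$lagMeanLp
        lagSd <- if (sp == "Lp") condition$lagSdLp else condition$lagSdLp
        lag <- rnormTrunc(1, lagMean, lagSd, lower = 0)
        len <- l0 * exp(m$rate * pmax(0, tm - lag)) *
          (1 + rnorm(nFrames, 0, params$trackNoiseSd))
        wid <- w0 * (1 + rnorm(nFrames, 0, params$trackNoiseSd))
        recs[[length(recs) + 1L]] <- data.frame(
          cell_id = sprintf("%s_%04d", sp, i), frame = seq_len(nFrames) - 1L,
          time_h = tm, length_um = pmax(len, 0.05), width_um = pmax(wid, 0.05),
          true_species = sp,
          condition = if (is.null(condition$label)) NA_character_ else condition$label)
      }
    }
    validateCellTracks(do.call(rbind, recs))
  })
}

rnormTrunc <- function(n, mean, sd, lower = 0) {
  x <- rnorm(n, mean, sd)
  while (any(x <= lower)) x[x <= lower] <- rnorm(sum(x <= lower), mean, sd)
  x
}
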