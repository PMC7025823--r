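#' Classifier configuration
#'
#' Settings of the aspect-ratio species classifier: cells are called Lp when
#' at least `traceFraction` (default 90%) of their frames have
#' log10(length/width) at or above `logRatioThreshold` (default 0.375), Ap
#' when at least that fraction lie below, and ambiguous otherwise. Cells
#' whose raw length ever exceeds `maxLength` (segmentation artifacts) or
#' with at most `minTimepoints` frames are removed before classification;
#' length (and width) traces are smoothed with a `window`-point mean filter.
#'
#' @param logRatioThreshold log10 aspect-ratio decision boundary.
#' @param traceFraction required fraction of frames on one side, in (0.5, 1].
#' @param maxLength raw-length filter (um).
#' @param minTimepoints strict minimum frames (> 15 keeps a cell).
#' @param window mean-filter window (odd).
#' @param smoothWidth also smooth widths before the ratio (default TRUE).
#' @return a named list with class `"ClassifierConfig"`.
#' @export
classifierConfig <- function(logRatioThreshold = 0.375, traceFraction = 0.90,
                             maxLength = 6, minTimepoints = 15, window = 5,
                             smoothWidth = TRUE) {
  if (traceFraction <= 0.5 || traceFraction > 1)
    cocultolStop("invalidConfigError", "traceFraction must be in (0.5, 1]")
  if (window %% 2 == 0)
    cocultolStop("invalidConfigError", "smoothing window must be odd")
  structure(list(logRatioThreshold = logRatioThreshold,
                 traceFraction = traceFraction, maxLength = maxLength,
                 minTimepoints = minTimepoints, window = window,
                 smoothWidth = smoothWidth),
            class = c("ClassifierConfig", "list"))
}

#' Filter single-cell tracks
#'
#' Removes cells whose maximum raw length exceeds the segmentation cutoff
#' (default 6 um) and cells with too few timepoints (strictly more than 15
#' are required). Counts removed per rule are attached as the
#' `"removed"` attribute.
#'
#' @param tracks a validated track `data.frame` (see [readCellTracks()]).
#' @param cfg a [classifierConfig()].
#' @return the filtered track `data.frame`.
#' @export
filterTracks <- function(tracks, cfg = classifierConfig()) {
  maxLen <- tapply(tracks$length_um, tracks$cell_id, max)
  nFrames <- tapply(tracks$frame, tracks$cell_id, length)
  tooLong <- names(maxLen)[maxLen > cfg$maxLength]
  tooShort <- names(nFrames)[nFrames <= cfg$minTimepoints]
  keep <- !(tracks$cell_id %in% union(tooLong, tooShort))
  out <- tracks[keep, ]
  rownames(out) <- NULL
  attr(out, "removed") <- c(over_length = length(tooLong),
                            too_few_timepoints = length(setdiff(tooShort, tooLong)))
  out
}

#' Classify cells by aspect ratio
#'
#' Smooths each cell's length (and width) trace with the window-5 mean
#' filter, computes per-frame log10(length/width), and calls the species
#' from the fraction of frames at or above the 0.375 threshold (ties count
#' as above): Lp when the fraction is at least 90%, Ap when at most 10%,
#' otherwise ambiguous. Per-frame elongation rates d(ln L)/dt (central
#' differences on the smoothed lengths) are attached for
#' [elongationRates()].
#'
#' @param tracks a filtered track `data.frame` (see [filterTracks()]).
#' @param cfg a [classifierConfig()].
#' @return a list with class `"TrackFeatures"`: `cells` (one row per cell:
#'   cell_id, call, fracAbove, nFrames, true_species, condition) and
#'   `frames` (per-frame smoothed traces, log-ratio, elongation rate).
#' @export
classifySpecies <- function(tracks, cfg = classifierConfig()) {
  perCell <- lapply(split(tracks, tracks$cell_id), function(tc) {
    tc <- tc[order(tc$frame), ]
    len <- smoothSeries(tc$length_um, min(cfg$window, oddBelow(nrow(tc))))
    wid <- if (cfg$smoothWidth)
      smoothSeries(tc$width_um, min(cfg$window, oddBelow(nrow(tc))))
      else tc$width_um
    logRatio <- log10(len / wid)
    # ties at the threshold count as above; tolerance guards float round-off
    fracAbove <- mean(logRatio - cfg$logRatioThreshold >= -1e-12)
    call <- if (fracAbove >= cfg$traceFraction) "Lp"
      else if (fracAbove <= 1 - cfg$traceFraction) "Ap"
      else "ambiguous"
    rate <- instantaneousRate(tc$time_h, log(len))$rate
    list(cell = data.frame(cell_id = tc$cell_id[1], call = call,
                           fracAbove = fracAbove, nFrames = nrow(tc),
                           true_species = tc$true_species[1],
                           condition = tc$condition[1]),
         frames = data.frame(cell_id = tc$cell_id, frame = tc$frame,
                             time_h = tc$time_h, length_sm = len,
                             width_sm = wid, log_ratio = logRatio,
                             elong_rate = rate, call = call))
  })
  out <- list(cells = do.call(rbind, lapply(perCell, `[[`, "cell")),
              frames = do.call(rbind, lapply(perCell, `[[`, "frames")))
  rownames(out$cells) <- rownames(out$frames) <- NULL
  class(out) <- c("TrackFeatures", "list")
  out
}

oddBelow <- function(n) if (n %% 2 == 1) n else n - 1L

#' Per-species population elongation rates
#'
#' Mean and standard error of the single-cell elongation rates
#' d(ln L)/dt at each timepoint, per species call; ambiguous cells are
#' excluded and species absent at a timepoint are omitted (never
#' zero-filled).
#'
#' @param features a `TrackFeatures` list from [classifySpecies()].
#' @return a `data.frame` with columns `call, time_h, mean_rate, se, n`.
#' @export
elongationRates <- function(features) {
  fr <- features$frames[features$frames$call %in% c("Lp", "Ap"), ]
  if (nrow(fr) == 0)
    cocultolStop("noClassifiedCellsError", "no non-ambiguous cells to summarize")
  agg <- lapply(split(fr, list(fr$call, fr$time_h), drop = TRUE), function(g) {
    n <- nrow(g)
    data.frame(call = g$call[1], time_h = g$time_h[1],
               mean_rate = mean(g$elong_rate),
               se = if (n > 1) sd(g$elong_rate) / sqrt(n) else 0, n = n)
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$call, out$time_h), ]
  rownames(out) <- NULL
  out
}

#' Classification error against ground truth
#'
#' Fraction of non-ambiguous species calls disagreeing with the recorded
#' true species (synthetic tracks or tagged-strain experiments); ambiguous
#' calls are reported separately, never counted as errors.
#'
#' @param features a `TrackFeatures` list from [classifySpecies()].
#' @return a list: `error` (NA when no cell was called), `nCalled`,
#'   `nAmbiguous`, `nLabeled`.
#' @export
classificationError <- function(features) {
  cells <- features$cells[!is.na(features$cells$true_species), ]
  if (nrow(cells) == 0)
    cocultolStop("noLabelsError", "no cells carry a true-species label")
  called <- cells[cells$call %in% c("Lp", "Ap"), ]
  err <- if (nrow(called) == 0) NA_real_
         else mean(called$call != called$true_species)
  list(error = err, nCalled = nrow(called),
       nAmbiguous = sum(cells$call == "ambiguous"), nLabeled = nrow(cells))
}
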