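# fixtures built in code; no binary data on disk

tinyPlateMap <- function() {
  data.frame(
    well = c("A1", "A2", "H12"),
    condition = c("mono", "co", "blank"),
    species = c("Lp", "Lp+Ap", ""),
    role = c("sample", "sample", "media_blank"),
    drug = "none", conc_ug_ml = 0, start_ph = 6.75,
    replicate = 1L, known_ph = NA)
}

# long-format OD table over the given wells/times from a value function
tinyTimeSeriesCsv <- function(path, wells = c("A1", "A2", "H12"),
                              times = seq(0, 1.5, length.out = 10),
                              value = function(w, t) 0.1 + 0.01 * t) {
  df <- expand.grid(well = wells, time_h = times, stringsAsFactors = FALSE)
  df$channel <- "OD600"
  df$value <- mapply(value, df$well, df$time_h)
  df <- df[order(df$well, df$time_h), c("time_h", "well", "channel", "value")]
  write.csv(df, path, row.names = FALSE)
  df
}

constantTrajectory <- function(ph = 6.98, biomass = 0, duration = 1,
                               interval = 0.25, condition = "const") {
  tm <- seq(0, duration, by = interval)
  st <- cbind(B_Lp = rep(biomass, length(tm)), B_Ax = 0, G = 110, L = 0,
              q = 1, pH = ph)
  new("Trajectory", time = tm, state = st,
      rates = cbind(mu_Lp = rep(0, length(tm)), mu_Ax = 0),
      condition = condition, species = "Lp")
}

# survival table for a known (k, d), noiseless, as a SurvivalSeries
exactSurvival <- function(k, d, times = seq(0, 30, by = 2)) {
  out <- data.frame(condition = "x", replicate = 1L, time_h = times,
                    survival = exp(-k * pmax(0, times - d)),
                    censored = FALSE, bound = NA_real_)
  class(out) <- c("SurvivalSeries", "data.frame")
  out
}

# constant-morphology noiseless track table
constantTrack <- function(cellId, ratio, width = 1, nFrames = 20,
                          species = NA_character_) {
  data.frame(cell_id = cellId, frame = seq_len(nFrames) - 1L,
             time_h = (seq_len(nFrames) - 1L) * 5 / 60,
             length_um = ratio * width, width_um = width,
             true_species = species, condition = NA_character_)
}
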