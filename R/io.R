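#' Read a plate map
#'
#' The plate map declares, for every well, its condition label, species
#' composition (`+`-separated codes among Lp, Lb, Ap, At, Ao, Ai, Aa; empty
#' for blanks), role (`sample`, `media_blank`, `dye_free_control`,
#' `calibration_standard`), drug and concentration (ug/mL), starting pH,
#' replicate index and — for calibration standards — the known pH.
#' CSV (columns `well,condition,species,role,drug,conc_ug_ml,start_ph,
#' replicate,known_ph`) and YAML (a list of the same records) are accepted.
#' Missing `role` defaults to `sample`, missing `drug` to `none`, missing
#' `replicate` to 1.
#'
#' @param path path to a `.csv` or `.yaml`/`.yml` file.
#' @return a validated `data.frame` with one row per well.
#' @export
readPlateMap <- function(path) {
  if (!file.exists(path))
    cocultolStop("fileNotFoundError", paste0("no such file: ", path))
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      cocultolStop("missingPackageError", "YAML plate maps need the 'yaml' package")
    recs <- yaml::read_yaml(path)
    df <- do.call(rbind, lapply(recs, function(r)
      as.data.frame(r[!vapply(r, is.null, logical(1))], stringsAsFactors = FALSE)))
    df <- as.data.frame(df)
  } else {
    df <- read.csv(path, stringsAsFactors = FALSE)
  }
  validatePlateMap(df)
}

#' @rdname readPlateMap
#' @param map a candidate plate-map `data.frame` to validate/normalize.
#' @export
validatePlateMap <- function(map) {
  need <- c("well", "condition", "species")
  miss <- setdiff(need, names(map))
  if (length(miss))
    cocultolStop("missingColumnsError",
                 paste0("plate map missing column(s): ", paste(miss, collapse = ", ")))
  for (col in c("role", "drug", "conc_ug_ml", "start_ph", "replicate", "known_ph"))
    if (!col %in% names(map)) map[[col]] <- NA
  map$role[is.na(map$role) | map$role == ""] <- "sample"
  map$drug[is.na(map$drug) | map$drug == ""] <- "none"
  map$replicate[is.na(map$replicate)] <- 1L
  map$conc_ug_ml[is.na(map$conc_ug_ml)] <- 0
  map$species[is.na(map$species)] <- ""

  if (anyDuplicated(map$well))
    cocultolStop("duplicateWellError",
                 paste0("duplicated well id(s): ",
                        paste(unique(map$well[duplicated(map$well)]), collapse = ", ")))
  if (!all(grepl("^[A-P][0-9]+$", map$well)))
    cocultolStop("wellFormatError",
                 "well ids must be a row letter followed by a column number, e.g. A1")
  if (!all(map$role %in% plateRoles))
    cocultolStop("unknownRoleError",
                 paste0("unknown role(s): ",
                        paste(setdiff(map$role, plateRoles), collapse = ", ")))
  spl <- lapply(map$species, parseSpecies)
  bad <- setdiff(unique(unlist(spl)), speciesCodes)
  if (length(bad))
    cocultolStop("unknownSpeciesError",
                 paste0("unknown species code(s): ", paste(bad, collapse = ", ")))
  blank <- map$role == "media_blank"
  if (any(lengths(spl[blank]) > 0))
    cocultolStop("blankSpeciesError", "media blanks must have an empty species set")
  if (any(map$conc_ug_ml < 0))
    cocultolStop("negativeConcentrationError", "drug concentrations must be >= 0")
  rep_ <- map$replicate
  if (any(rep_ <= 0) || any(rep_ != as.integer(rep_)))
    cocultolStop("replicateIndexError", "replicate indices must be positive integers")
  map$replicate <- as.integer(map$replicate)
  rownames(map) <- NULL
  map
}

#' @rdname readPlateMap
#' @param path output path (CSV).
#' @export
writePlateMap <- function(map, path) {
  write.csv(validatePlateMap(map), path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a long-format plate-reader time series
#'
#' Reads a tidy CSV with columns `time_h,well,channel,value` (channels among
#' `OD600,F440_535,F490_535,F405_509,F475_509`) plus a plate map, and
#' assembles a validated [PlateTimeSeries-class]. Within each well/channel
#' trace the time column must be strictly increasing as written; every well
#' appearing in the data must be present in the plate map.
#'
#' @param path path to the long-format CSV.
#' @param platemap a plate-map `data.frame` (from [readPlateMap()]) or a
#'   path to one.
#' @return a `PlateTimeSeries`.
#' @export
readPlateTimeSeries <- function(path, platemap) {
  if (is.character(platemap)) platemap <- readPlateMap(platemap)
  platemap <- validatePlateMap(platemap)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_h", "well", "channel", "value")
  miss <- setdiff(need, names(df))
  if (length(miss))
    cocultolStop("missingColumnsError",
                 paste0("time series missing column(s): ", paste(miss, collapse = ", ")))
  badCh <- setdiff(unique(df$channel), knownChannels)
  if (length(badCh))
    cocultolStop("unknownChannelError",
                 paste0("unknown channel(s): ", paste(badCh, collapse = ", ")))
  key <- paste(df$time_h, df$well, df$channel)
  if (anyDuplicated(key))
    cocultolStop("duplicateRecordError",
                 "duplicated (time, well, channel) record(s) in time series")
  unmapped <- setdiff(unique(df$well), platemap$well)
  if (length(unmapped))
    cocultolStop("unmappedWellError",
                 paste0("well(s) absent from plate map: ", paste(unmapped, collapse = ", ")))
  mono <- vapply(split(df$time_h, paste(df$well, df$channel)),
                 function(t) all(diff(t) > 0), logical(1))
  if (!all(mono))
    cocultolStop("nonMonotoneTimeError",
                 "time must be strictly increasing within each well/channel trace")

  times <- sort(unique(df$time_h))
  wells <- unique(df$well)
  assays <- lapply(split(df, df$channel), function(ch) {
    m <- matrix(NA_real_, nrow = length(wells), ncol = length(times),
                dimnames = list(wells, NULL))
    m[cbind(match(ch$well, wells), match(ch$time_h, times))] <- ch$value
    if (anyNA(m))
      cocultolStop("incompleteGridError",
                   paste0("channel ", ch$channel[1],
                          " does not cover the full well x time grid"))
    m
  })
  PlateTimeSeries(assays, times, platemap[match(wells, platemap$well), ])
}

#' Construct a PlateTimeSeries from channel matrices
#'
#' @param assays named list of wells-by-time matrices (names are channels).
#' @param time_h time grid in hours.
#' @param platemap plate-map `data.frame` covering the assay rows.
#' @return a validated `PlateTimeSeries`.
#' @export
PlateTimeSeries <- function(assays, time_h, platemap) {
  platemap <- validatePlateMap(platemap)
  wells <- rownames(assays[[1]])
  rd <- platemap[match(wells, platemap$well), setdiff(names(platemap), "well"),
                 drop = FALSE]
  rownames(rd) <- wells
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays,
    rowData = S4Vectors::DataFrame(rd),
    colData = S4Vectors::DataFrame(time_h = time_h))
  new("PlateTimeSeries", se)
}

#' @rdname readPlateTimeSeries
#' @param x a `PlateTimeSeries` to write.
#' @export
writePlateTimeSeries <- function(x, path) {
  stopifnot(is(x, "PlateTimeSeries"))
  tm <- timePoints(x)
  out <- do.call(rbind, lapply(channelNames(x), function(ch) {
    m <- channelValues(x, ch)
    data.frame(time_h = rep(tm, each = nrow(m)),
               well = rep(rownames(m), length(tm)),
               channel = ch, value = as.vector(m))
  }))
  out <- out[order(out$channel, out$well, out$time_h), ]
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a CFU dilution-plating table
#'
#' Reads `condition,replicate,time_h,dilution,volume_ml,colonies` records.
#' The dilution is the multiplicative factor < 1 actually applied (e.g.
#' `2e-5`). CFU/mL is derived as `colonies / (volume_ml * dilution)`;
#' zero-colony records are flagged below the limit of detection with
#' `LOD = 1 / (volume_ml * dilution)`, the density at which a single colony
#' would have been expected.
#'
#' @param path CSV path.
#' @return a `data.frame` with derived columns `cfu_per_ml`, `below_lod`,
#'   `lod`.
#' @export
readCfuTable <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  validateCfuTable(df)
}

#' @rdname readCfuTable
#' @param df a candidate CFU `data.frame`.
#' @export
validateCfuTable <- function(df) {
  need <- c("condition", "replicate", "time_h", "dilution", "volume_ml", "colonies")
  miss <- setdiff(need, names(df))
  if (length(miss))
    cocultolStop("missingColumnsError",
                 paste0("CFU table missing column(s): ", paste(miss, collapse = ", ")))
  if (any(df$colonies < 0))
    cocultolStop("negativeCountError", "colony counts must be >= 0")
  if (any(df$dilution <= 0) || any(df$volume_ml <= 0))
    cocultolStop("zeroVolumeError", "dilution and volume must be positive")
  if (any(df$dilution > 1))
    cocultolStop("dilutionConventionError",
                 "dilution must be the applied factor <= 1 (e.g. 2e-5)")
  df$cfu_per_ml <- df$colonies / (df$volume_ml * df$dilution)
  df$below_lod <- df$colonies == 0
  df$lod <- 1 / (df$volume_ml * df$dilution)
  df
}

#' @rdname readCfuTable
#' @export
writeCfuTable <- function(df, path) {
  keep <- c("condition", "replicate", "time_h", "dilution", "volume_ml", "colonies")
  write.csv(df[keep], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a single-cell track table
#'
#' Reads `cell_id,frame,time_h,length_um,width_um[,true_species][,condition]`
#' records from time-lapse segmentation. Frames are returned sorted within
#' each cell (with a notice if reordering was needed); duplicate
#' (cell, frame) pairs and non-positive dimensions are rejected.
#'
#' @param path CSV path.
#' @return a validated `data.frame`.
#' @export
readCellTracks <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  validateCellTracks(df)
}

#' @rdname readCellTracks
#' @param df a candidate track `data.frame`.
#' @export
validateCellTracks <- function(df) {
  need <- c("cell_id", "frame", "time_h", "length_um", "width_um")
  miss <- setdiff(need, names(df))
  if (length(miss))
    cocultolStop("missingColumnsError",
                 paste0("track table missing column(s): ", paste(miss, collapse = ", ")))
  if (anyDuplicated(paste(df$cell_id, df$frame)))
    cocultolStop("duplicateRecordError", "duplicated (cell_id, frame) pair(s)")
  if (any(df$length_um <= 0) || any(df$width_um <= 0))
    cocultolStop("nonPositiveDimensionError", "length and width must be positive")
  if (!"true_species" %in% names(df)) df$true_species <- NA_character_
  if (!"condition" %in% names(df)) df$condition <- NA_character_
  unsorted <- vapply(split(df$frame, df$cell_id), is.unsorted, logical(1))
  if (any(unsorted)) {
    message("readCellTracks: frames out of order for ",
            sum(unsorted), " cell(s); returned sorted")
    df <- df[order(df$cell_id, df$frame), ]
  }
  rownames(df) <- NULL
  df
}

#' @rdname readCellTracks
#' @export
writeCellTracks <- function(df, path) {
  keep <- intersect(c("cell_id", "frame", "time_h", "length_um", "width_um",
                      "true_species", "condition"), names(df))
  write.csv(df[keep], path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
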