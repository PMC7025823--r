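#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assays assayNames rowData colData
#' @importFrom stats pt sd rnorm rpois pf coef nls.control fitted median qt
#' @importFrom utils read.csv write.csv head
NULL

# classed condition so callers can catch specific validation failures with
# expect_error(class = ...) / tryCatch(...)
cocultolStop <- function(class, msg, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "cocultolError")))
}

# Run `expr` with a temporary RNG seed, restoring the caller's RNG state.
# All generators route their randomness through this so that identical
# (params, design, seed) triples give bit-identical output.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    cocultolStop("invalidSeedError", "'seed' must be a single finite number")
  hasSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hasSeed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (hasSeed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}

# derive a distinct but reproducible sub-seed for a named sub-draw
subSeed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) + as.integer(offset)) %% .Machine$integer.max
}

speciesCodes <- c("Lp", "Lb", "Ap", "At", "Ao", "Ai", "Aa")

plateRoles <- c("sample", "media_blank", "dye_free_control", "calibration_standard")

knownChannels <- c("OD600", "F440_535", "F490_535", "F405_509", "F475_509")

# "Lp+Ap" -> c("Lp","Ap"); "" -> character(0)
parseSpecies <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  trimws(strsplit(x, "[+;,]")[[1]])
}
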