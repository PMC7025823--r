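#' Additive-model interaction score
#'
#' \eqn{\alpha = (OD_{co} - (OD_{Lp} + OD_A)) / (OD_{Lp} \cdot OD_A)}:
#' the deviation of the co-culture's final OD from the additive expectation,
#' scaled by the product of the monoculture ODs. \eqn{\alpha > 0} indicates
#' synergy, \eqn{\alpha < 0} antagonism.
#'
#' Note the scale caution: multiplying all three ODs by c > 0 multiplies
#' alpha by 1/c, so scores are only comparable across experiments measured
#' on the same OD scale (rescale diluted endpoint reads to undiluted OD
#' first; see `dilution` in [scoreReplicates()]).
#'
#' @param odCo co-culture final OD (blank- and dilution-corrected).
#' @param odLp,odA monoculture final ODs (> 0).
#' @return alpha (vectorized).
#' @export
interactionScore <- function(odCo, odLp, odA) {
  if (any(odLp <= 0) || any(odA <= 0))
    cocultolStop("nonPositiveOdError", "monoculture ODs must be positive")
  (odCo - (odLp + odA)) / (odLp * odA)
}

#' Score and classify replicate interaction measurements
#'
#' Computes a per-replicate alpha (replicate i of the co-culture paired with
#' replicate i of each monoculture), then a two-sided one-sample Student's
#' t-test of alpha against 0. The pair is labelled synergy (significant,
#' mean > 0), antagonism (significant, mean < 0), neutral, or indeterminate
#' when fewer than two replicates are available. The significance threshold
#' is `alphaLevel / nComparisons` (Bonferroni across the species pairs
#' tested in the experiment).
#'
#' @param odCo,odLp,odA replicate-matched endpoint ODs.
#' @param dilution dilution factor (< 1) at which the endpoint ODs were
#'   read, e.g. 1/30 for a 1:30 read; ODs are rescaled to undiluted values
#'   before scoring. Default 1 (already undiluted).
#' @param alphaLevel family significance level (default 0.05).
#' @param nComparisons number of species pairs in the Bonferroni family.
#' @return an [InteractionScore-class].
#' @export
scoreReplicates <- function(odCo, odLp, odA, dilution = 1,
                            alphaLevel = 0.05, nComparisons = 1) {
  if (dilution <= 0 || dilution > 1)
    cocultolStop("dilutionConventionError",
                 "dilution must be the applied factor in (0, 1]")
  n <- length(odCo)
  if (length(odLp) != n || length(odA) != n)
    cocultolStop("lengthMismatchError", "replicate vectors must be matched")
  a <- interactionScore(odCo / dilution, odLp / dilution, odA / dilution)
  if (n < 2)
    return(new("InteractionScore", alpha = a, mean = mean(a), sd = NA_real_,
               n = as.integer(n), pValue = NA_real_, label = "indeterminate"))
  sdA <- sd(a)
  if (sdA == 0 && mean(a) == 0) {
    p <- 1
  } else if (sdA == 0) {
    p <- 0  # all replicates identical and nonzero
  } else {
    tt <- mean(a) / (sdA / sqrt(n))
    p <- 2 * pt(-abs(tt), df = n - 1)
  }
  thr <- bonferroniThreshold(alphaLevel, nComparisons)
  label <- if (p < thr && mean(a) > 0) "synergy"
           else if (p < thr && mean(a) < 0) "antagonism"
           else "neutral"
  new("InteractionScore", alpha = a, mean = mean(a), sd = sdA,
      n = as.integer(n), pValue = p, label = label)
}
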