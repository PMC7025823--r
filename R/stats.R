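#' Pairwise Student's two-sided t-test with star tiers
#'
#' Pooled-variance (Student's) two-sample t-test, two-sided, with
#' df = n_x + n_y - 2 (Welch's correction available behind `welch = TRUE`).
#' The star tier follows the Bonferroni-corrected convention used
#' throughout the package's figure-style reporting: `*` for
#' p < 0.05/n, `**` for p < 0.01/n, `***` for p < 0.001/n, where n is the
#' number of comparisons in the experiment's family.
#'
#' @param x,y numeric groups, each with at least 2 values.
#' @param nComparisons Bonferroni family size n (default 1, uncorrected).
#' @param welch use Welch's unequal-variance test instead of pooled.
#' @return a list with class `"TTestResult"`: `t`, `df`, `p`, group sizes,
#'   `nComparisons`, the corrected thresholds, and `tier`
#'   (`"NS"`, `"*"`, `"**"`, `"***"`).
#' @export
ttestTwoSample <- function(x, y, nComparisons = 1, welch = FALSE) {
  if (length(x) < 2 || length(y) < 2)
    cocultolStop("insufficientDataError", "each group needs >= 2 values")
  if (sd(x) == 0 && sd(y) == 0)
    cocultolStop("zeroVarianceError", "both groups have zero variance")
  ht <- stats::t.test(x, y, var.equal = !welch, alternative = "two.sided")
  p <- unname(ht$p.value)
  res <- list(nX = length(x), nY = length(y),
              t = unname(ht$statistic), df = unname(ht$parameter), p = p,
              nComparisons = nComparisons,
              thresholds = bonferroniThreshold(c(0.05, 0.01, 0.001), nComparisons),
              tier = starTier(p, nComparisons))
  class(res) <- c("TTestResult", "list")
  res
}

#' @export
print.TTestResult <- function(x, ...) {
  cat(sprintf("Student's two-sided t-test: t = %.4f, df = %g, p = %.4g [%s]\n",
              x$t, x$df, x$p, x$tier))
  if (x$nComparisons > 1)
    cat(sprintf("  Bonferroni family n = %d (thresholds %s)\n", x$nComparisons,
                paste(signif(x$thresholds, 2), collapse = "/")))
  invisible(x)
}

#' Bonferroni-corrected significance threshold
#'
#' `familyLevel / nComparisons`. The display variant rounds to one
#' significant figure, matching figure-legend conventions (0.05/12 is
#' displayed as 4e-3).
#'
#' @param familyLevel family-wise level(s), e.g. 0.05.
#' @param nComparisons number of comparisons n >= 1.
#' @param display round to one significant figure for display.
#' @return threshold(s).
#' @export
bonferroniThreshold <- function(familyLevel, nComparisons, display = FALSE) {
  if (nComparisons < 1)
    cocultolStop("invalidFamilyError", "nComparisons must be >= 1")
  thr <- familyLevel / nComparisons
  if (display) signif(thr, 1) else thr
}

#' Star tier of a p-value under Bonferroni correction
#'
#' @param p p-value(s).
#' @param nComparisons Bonferroni family size.
#' @return `"***"`, `"**"`, `"*"` or `"NS"` (vectorized).
#' @export
starTier <- function(p, nComparisons = 1) {
  thr <- bonferroniThreshold(c(0.05, 0.01, 0.001), nComparisons)
  ifelse(p < thr[3], "***", ifelse(p < thr[2], "**",
    ifelse(p < thr[1], "*", "NS")))
}

#' Family of pairwise comparisons with star reporting
#'
#' Runs every requested pairwise Student's t-test within one experiment
#' family, Bonferroni-corrected over the number of comparisons actually
#' performed (as printed in per-panel figure legends).
#'
#' @param values long `data.frame` with columns `group` and `value`.
#' @param reference reference group compared against every other group;
#'   NULL for all pairwise comparisons.
#' @param welch use Welch's test.
#' @return a `data.frame`: group1, group2, t, df, p, tier, nComparisons.
#' @export
compareFamily <- function(values, reference = NULL, welch = FALSE) {
  groups <- unique(values$group)
  pairs <- if (is.null(reference)) {
    cmb <- utils::combn(groups, 2)
    lapply(seq_len(ncol(cmb)), function(i) cmb[, i])
  } else {
    lapply(setdiff(groups, reference), function(g) c(reference, g))
  }
  nComp <- length(pairs)
  out <- do.call(rbind, lapply(pairs, function(pr) {
    r <- ttestTwoSample(values$value[values$group == pr[1]],
                        values$value[values$group == pr[2]],
                        nComparisons = nComp, welch = welch)
    data.frame(group1 = pr[1], group2 = pr[2], t = r$t, df = r$df, p = r$p,
               tier = r$tier, nComparisons = nComp)
  }))
  rownames(out) <- NULL
  out
}
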