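## Summary statistics conventions: two-level grand mean +/- SEM (time averages
## per subunit, averaged per run, SEM across runs) and the Welch unpaired
## t-test used for all per-residue significance calls.

#' Grand mean and SEM with two-level averaging
#'
#' Values (already time-averaged per subunit and run) are first averaged over
#' the subunits of each run; the grand mean is the mean of the run means and
#' the SEM is computed across runs. With a single run the SEM is returned as
#' NA.
#'
#' @param values numeric vector.
#' @param subunit,run grouping vectors (same length as values).
#' @return named numeric: mean, sem, nRuns.
#' @export
grandMeanSem <- function(values, subunit, run) {
  stopifnot(length(values) == length(subunit),
            length(values) == length(run))
  if (!length(values)) stop("need at least one group")
  subMeans <- tapply(values, list(run = run, subunit = subunit), mean)
  runMeans <- rowMeans(subMeans, na.rm = TRUE)
  nRuns <- length(runMeans)
  c(mean = mean(runMeans),
    sem = if (nRuns > 1L) sd(runMeans) / sqrt(nRuns) else NA_real_,
    nRuns = nRuns)
}

#' Two-sided unpaired t-test (Welch)
#'
#' Unequal-variance two-sample test; returns p = 1 when both groups have zero
#' variance and equal means (no evidence of a difference).
#'
#' @param groupA,groupB numeric vectors (length >= 2 each).
#' @return named numeric: t, p.
#' @export
unpairedT <- function(groupA, groupB) {
  if (length(groupA) < 2L || length(groupB) < 2L)
    stop("each group needs >= 2 observations")
  if (sd(groupA) == 0 && sd(groupB) == 0) {
    if (mean(groupA) == mean(groupB)) return(c(t = 0, p = 1))
    return(c(t = Inf, p = 0))
  }
  tt <- t.test(groupA, groupB, var.equal = FALSE)
  c(t = unname(tt$statistic), p = tt$p.value)
}
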