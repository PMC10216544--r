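#' Dunn's test of multiple comparisons using rank sums
#'
#' Nonparametric pairwise post-hoc comparison on the Kruskal-Wallis global
#' ranking. All observations are ranked together with midranks for ties;
#' for each pair of groups the statistic is the difference in mean ranks
#' standardized by `sqrt((N(N+1)/12 - T) * (1/n_a + 1/n_b))` with the tie
#' correction `T = sum(t^3 - t) / (12 (N - 1))` over tie-group sizes `t`.
#' Two-sided p-values come from the standard normal; an optional
#' Bonferroni or Holm adjustment is applied across the pairs (unadjusted
#' by default).
#'
#' @param observations numeric vector of all observations, or a named list
#'   of numeric vectors (one per group, names as labels; then `groups` is
#'   ignored).
#' @param groups group label per observation.
#' @param adjust `"none"` (default), `"bonferroni"` or `"holm"`.
#' @return data.frame with one row per pair: `sample_a`, `sample_b`, `z`,
#'   `p`, `p_adjusted`, plus attribute `adjust`. When all observations are
#'   identical the statistic is undefined and returned as `NA` with a
#'   warning.
#' @examples
#' dunnsTest(list(a = c(1, 2, 3), b = c(4, 5, 6)))
#' @export
dunnsTest <- function(observations, groups = NULL,
                      adjust = c("none", "bonferroni", "holm")) {
  adjust <- match.arg(adjust)
  if (is.list(observations) && !is.data.frame(observations)) {
    if (any(lengths(observations) == 0L)) {
      stop("group with zero observations: ",
           paste(names(observations)[lengths(observations) == 0L],
                 collapse = ", "))
    }
    groups <- rep(names(observations), lengths(observations))
    observations <- unlist(observations, use.names = FALSE)
  }
  stopifnot(length(observations) == length(groups))
  keep <- !is.na(observations)
  observations <- observations[keep]
  groups <- as.character(groups[keep])
  labs <- unique(groups)
  if (length(labs) < 2L) stop("need at least two groups")
  n <- table(factor(groups, levels = labs))
  if (any(n == 0L)) stop("group with zero observations")
  N <- length(observations)
  r <- rank(observations)          # midranks for ties
  meanRank <- tapply(r, factor(groups, levels = labs), mean)
  ties <- table(observations)
  Tcorr <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - Tcorr
  if (s2 <= 0) {
    warning("all observations identical; Dunn statistic undefined")
  }
  pairs <- utils::combn(labs, 2L)
  out <- do.call(rbind, apply(pairs, 2L, function(ab) {
    a <- ab[[1L]]; b <- ab[[2L]]
    se <- sqrt(s2 * (1 / n[[a]] + 1 / n[[b]]))
    z <- if (s2 > 0) (meanRank[[a]] - meanRank[[b]]) / se else NA_real_
    data.frame(sample_a = a, sample_b = b, z = z,
               p = if (is.na(z)) NA_real_ else 2 * stats::pnorm(-abs(z)),
               row.names = NULL)
  }))
  out$p_adjusted <- stats::p.adjust(out$p, method = adjust)
  structure(out, adjust = adjust)
}

#' Compare per-clone frequency distributions across samples
#'
#' Pipeline preset for group comparison: the observations for each sample
#' are its per-clone productive frequencies, compared across all samples of
#' the cohort with [dunnsTest()]. This operationalizes the comparison of
#' clonal-frequency makeup between samples — a sample dominated by expanded
#' clones carries larger frequencies into the global ranking. It is one
#' reasonable reading of an under-specified analysis and is labelled as an
#' interpretation, not a canonical statistic.
#'
#' @param cohort a [CDR3Cohort-class].
#' @inheritParams dunnsTest
#' @inheritParams cloneFrequencies
#' @return as [dunnsTest()].
#' @export
cloneFrequencyComparison <- function(cohort,
                                     adjust = c("none", "bonferroni", "holm"),
                                     productiveOnly = TRUE) {
  obs <- lapply(as.list(repertoires(cohort)), function(rep)
    cloneFrequencies(rep, productiveOnly)$frequency)
  names(obs) <- sampleIds(cohort)
  dunnsTest(obs, adjust = match.arg(adjust))
}
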