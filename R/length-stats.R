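#' CDR3 length distribution of a repertoire
#'
#' Tabulates productive CDR3 lengths, on the nucleotide scale by default
#' (junction lengths in nt, multiples of 3 for in-frame records) or the
#' amino acid scale. Each productive rearrangement contributes its template
#' count; the per-length value is the sum of productive template frequencies
#' (record frequency = templates / total productive templates), so the
#' column sums to 1 whenever productive templates exist.
#'
#' @param repertoire a translated [CDR3Repertoire-class] (translated on the
#'   fly if needed).
#' @param scale `"nt"` (default) or `"aa"`.
#' @return a [S4Vectors::DataFrame] with columns `length`,
#'   `sum_productive_frequency`, `unique_count`, ordered by length, with
#'   `metadata()` entries `scale`, `sample_id`, `min_length`, `max_length`.
#'   Empty (zero rows) with a warning when no productive templates exist.
#' @examples
#' rep <- CDR3Repertoire("s1", c("TGTGCCAGCAGTTTT", "TGTGCCTGGTTT"),
#'                       templates = c(3, 1))
#' lengthDistribution(rep)
#' @export
lengthDistribution <- function(repertoire, scale = c("nt", "aa")) {
  scale <- match.arg(scale)
  df <- rearrangements(repertoire)
  if (!"productive" %in% colnames(df)) {
    df <- rearrangements(translateRepertoire(repertoire, verbose = FALSE))
  }
  df <- df[df$productive & df$templates > 0L, , drop = FALSE]
  empty <- DataFrame(length = integer(), sum_productive_frequency = numeric(),
                     unique_count = integer())
  if (!nrow(df) || sum(df$templates) == 0L) {
    warning("no productive templates in sample ", sampleId(repertoire),
            "; empty length distribution")
    metadata(empty) <- list(scale = scale, sample_id = sampleId(repertoire),
                            min_length = NA_integer_, max_length = NA_integer_)
    return(empty)
  }
  len <- if (scale == "nt") nchar(df$cdr3_nt) else nchar(df$cdr3_aa)
  freq <- df$templates / sum(df$templates)
  key <- sort(unique(len))
  out <- DataFrame(
    length = key,
    sum_productive_frequency = vapply(key, function(l) sum(freq[len == l]),
                                      numeric(1)),
    unique_count = vapply(key, function(l) sum(len == l), integer(1))
  )
  metadata(out) <- list(scale = scale, sample_id = sampleId(repertoire),
                        min_length = min(key), max_length = max(key))
  out
}

#' Moment summary of a CDR3 length distribution
#'
#' Computes mean, variance, skewness and excess kurtosis of the lengths.
#' With `weighted = TRUE` (default) moments are taken against the
#' template-frequency weights (`sum_productive_frequency`), matching an
#' abundance-weighted length profile; with `weighted = FALSE` every unique
#' clone counts once. Population (n-denominator) moments are used; kurtosis
#' is excess (a normal distribution gives 0) and skewness is the
#' standardized third central moment. A distribution with a single distinct
#' length has variance 0 and undefined skewness/kurtosis, returned as `NaN`
#' with a warning.
#'
#' @param dist result of [lengthDistribution()].
#' @param weighted logical, see Details above.
#' @return a data.frame row: `mean`, `variance`, `skewness`, `kurtosis`,
#'   `weighted`.
#' @examples
#' rep <- CDR3Repertoire("s1", c("TGTGCCAGCAGTTTT", "TGTGCCTGGTTT"),
#'                       templates = c(3, 1))
#' lengthSummary(lengthDistribution(rep))
#' @export
lengthSummary <- function(dist, weighted = TRUE) {
  if (!nrow(dist)) stop("empty length distribution")
  w <- if (weighted) dist$sum_productive_frequency
       else dist$unique_count / sum(dist$unique_count)
  w <- w / sum(w)
  l <- dist$length
  m <- sum(w * l)
  v <- sum(w * (l - m)^2)
  if (v == 0) {
    warning("single distinct length; skewness and kurtosis undefined")
    sk <- ku <- NaN
  } else {
    sk <- sum(w * (l - m)^3) / v^1.5
    ku <- sum(w * (l - m)^4) / v^2 - 3
  }
  data.frame(mean = m, variance = v, skewness = sk, kurtosis = ku,
             weighted = weighted)
}

#' Tidy length table across a cohort
#'
#' Stacks [lengthDistribution()] of every sample into one tidy data.frame,
#' ready for export or plotting as grouped per-sample bars.
#'
#' @param cohort a [CDR3Cohort-class].
#' @param scale `"nt"` or `"aa"`.
#' @return data.frame with columns `sample_id`, `group`, `scale`, `length`,
#'   `frequency`, `unique_count`.
#' @export
cohortLengthTable <- function(cohort, scale = c("nt", "aa")) {
  scale <- match.arg(scale)
  do.call(rbind, lapply(as.list(repertoires(cohort)), function(rep) {
    d <- lengthDistribution(rep, scale)
    if (!nrow(d)) return(NULL)
    data.frame(sample_id = sampleId(rep), group = groupLabel(rep),
               scale = scale, length = d$length,
               frequency = d$sum_productive_frequency,
               unique_count = d$unique_count)
  }))
}
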