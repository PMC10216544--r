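#' Productive clone frequencies
#'
#' Frequency of each clonotype as its template count over the total
#' productive template count of the sample. Frequencies are invariant to
#' uniform scaling of template counts and sum to 1.
#'
#' @param repertoire a [CDR3Repertoire-class] (translated on the fly if
#'   needed).
#' @param productiveOnly restrict to productive rearrangements (default
#'   `TRUE`, matching productive clonality; `FALSE` uses all rearrangements
#'   with templates).
#' @return data.frame with `cdr3_nt`, `templates`, `frequency`.
#' @examples
#' rep <- CDR3Repertoire("s1", c("TGTGCCAGCAGTTTT", "TGTGCCTGGTTT"),
#'                       templates = c(3, 1))
#' cloneFrequencies(rep)
#' @export
cloneFrequencies <- function(repertoire, productiveOnly = TRUE) {
  df <- rearrangements(repertoire)
  if (productiveOnly) {
    if (!"productive" %in% colnames(df)) {
      df <- rearrangements(translateRepertoire(repertoire, verbose = FALSE))
    }
    df <- df[df$productive, , drop = FALSE]
  }
  df <- df[df$templates > 0L, , drop = FALSE]
  total <- sum(df$templates)
  if (!nrow(df) || total == 0L) {
    stop("no ", if (productiveOnly) "productive " else "",
         "templates in sample ", sampleId(repertoire))
  }
  data.frame(cdr3_nt = df$cdr3_nt, templates = df$templates,
             frequency = df$templates / total, row.names = NULL)
}

#' Simpson clonality of a frequency vector
#'
#' Simpson's index is the sum of squared clone frequencies; Simpson's
#' diversity is its complement; Simpson clonality is the square root of
#' Simpson's index. Clonality ranges from `1/sqrt(n)` for a perfectly even
#' sample of n clones (approaching 0 for large even repertoires) to 1 for a
#' monoclonal sample. The plug-in formula is used deliberately — clonality
#' here measures the evenness of the sample itself, not an estimate for the
#' underlying pool, which is what makes it comparable across samples with
#' different input amounts.
#'
#' @param frequencies numeric clone frequencies summing to 1 (within 1e-9),
#'   or the data.frame returned by [cloneFrequencies()].
#' @param sample_id optional label stored in the result.
#' @return data.frame row: `sample_id`, `n_clones`, `simpson_index`,
#'   `simpson_diversity`, `clonality`.
#' @examples
#' simpsonClonality(rep(0.25, 4))$clonality  # 0.5
#' @export
simpsonClonality <- function(frequencies, sample_id = NA_character_) {
  p <- if (is.data.frame(frequencies)) frequencies$frequency else frequencies
  if (abs(sum(p) - 1) > 1e-9) {
    stop("clone frequencies must sum to 1 (got ", format(sum(p)), ")")
  }
  if (any(p < 0)) stop("negative clone frequency")
  si <- sum(p^2)
  data.frame(sample_id = sample_id, n_clones = length(p),
             simpson_index = si, simpson_diversity = 1 - si,
             clonality = sqrt(si), row.names = NULL)
}

#' Clonality summary across a cohort
#'
#' @param cohort a [CDR3Cohort-class].
#' @inheritParams cloneFrequencies
#' @return data.frame with one row per sample: `sample_id`, `group`,
#'   `n_clones`, `simpson_index`, `simpson_diversity`, `clonality`.
#' @export
cohortClonality <- function(cohort, productiveOnly = TRUE) {
  do.call(rbind, lapply(as.list(repertoires(cohort)), function(rep) {
    cs <- simpsonClonality(cloneFrequencies(rep, productiveOnly),
                           sample_id = sampleId(rep))
    cbind(cs[1], group = groupLabel(rep), cs[-1])
  }))
}
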