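#' Clustal conservation groups
#'
#' The residue groups used to annotate alignment columns with Clustal-style
#' symbols: "strong" groups (members substitute with score > 0.5 in the
#' Gonnet PAM 250 matrix) and "weak" groups (score in (0, 0.5\]). These are
#' the group lists published with Clustal X / Clustal Omega; both lists are
#' arguments so any variant scheme can be substituted.
#'
#' @return list with character-vector elements `strong` and `weak`, each a
#'   vector of residue-set strings.
#' @examples
#' clustalConservationGroups()$strong
#' @export
clustalConservationGroups <- function() {
  list(
    strong = c("STA", "NEQK", "NHQK", "NDEQ", "QHRK", "MILV", "MILF",
               "HY", "FYW"),
    weak = c("CSA", "ATV", "SAG", "STNK", "STPA", "SGND", "SNDEQK",
             "NDEQHK", "NEQHRK", "FVLIM", "HFY")
  )
}

#' Column conservation symbols for equal-length sequences
#'
#' Annotates each column of a gapless, column-wise alignment of equal-length
#' sequences: `*` for a single fully conserved residue, `:` when all
#' residues of the column fall in one strong conservation group, `.` when
#' they fall in one weak group, and a space otherwise. Sequences of unequal
#' length need a gapped multiple alignment first (e.g. Clustal Omega or
#' MAFFT); only the annotation of already-aligned columns is done here,
#' which covers shared CDR3 sets of a single length.
#'
#' @param sequences character vector of at least two equal-length amino
#'   acid strings.
#' @param scheme conservation groups as from [clustalConservationGroups()].
#' @return single string of symbols, one per column.
#' @examples
#' conservationString(c("CASSF", "CASTF"))
#' @export
conservationString <- function(sequences, scheme = clustalConservationGroups()) {
  if (length(sequences) < 2L) stop("need at least two sequences")
  L <- unique(nchar(sequences))
  if (length(L) != 1L) {
    stop("sequences have unequal lengths; align them with an external ",
         "aligner (e.g. Clustal Omega) before annotation")
  }
  mat <- do.call(rbind, strsplit(sequences, ""))
  strong <- strsplit(scheme$strong, "")
  weak <- strsplit(scheme$weak, "")
  inOneGroup <- function(res, groups) {
    any(vapply(groups, function(g) all(res %in% g), logical(1)))
  }
  sym <- vapply(seq_len(L), function(j) {
    res <- unique(mat[, j])
    if (length(res) == 1L) "*"
    else if (inOneGroup(res, strong)) ":"
    else if (inOneGroup(res, weak)) "."
    else " "
  }, character(1))
  paste(sym, collapse = "")
}

#' Clonotypes shared across samples
#'
#' Finds CDR3 sequences present in two or more samples of a cohort, by
#' exact string match on productive amino acid sequences (the default —
#' convergent recombination makes amino-acid-level sharing broader than
#' nucleotide-level) or on nucleotide sequences with `level = "nt"`.
#'
#' @param cohort a translated [CDR3Cohort-class].
#' @param level `"aa"` (default) or `"nt"`.
#' @return data.frame with `sequence`, `samples` (comma-separated ids),
#'   `n_samples`, `groups` (comma-separated distinct group labels) and
#'   `sharing` (`"within_group"` or `"between_group"`); attributes
#'   `n_within_group` and `n_between_group` carry the two totals. Zero rows
#'   when nothing is shared.
#' @examples
#' coh <- CDR3Cohort(list(
#'   CDR3Repertoire("a", c("TGTGCCAGCAGTTTT", "TGTGCCTGGTTT")),
#'   CDR3Repertoire("b", "TGTGCCAGCAGTTTT")))
#' sharedClones(coh)
#' @export
sharedClones <- function(cohort, level = c("aa", "nt")) {
  level <- match.arg(level)
  reps <- as.list(repertoires(cohort))
  seqsOf <- function(rep) {
    if (level == "aa") unique(productiveSequences(rep))
    else {
      df <- rearrangements(translateRepertoire(rep, verbose = FALSE))
      unique(df$cdr3_nt[df$productive])
    }
  }
  perSample <- lapply(reps, seqsOf)
  ids <- vapply(reps, sampleId, character(1))
  grp <- vapply(reps, groupLabel, character(1))
  long <- data.frame(
    sequence = unlist(perSample, use.names = FALSE),
    sample_id = rep(ids, lengths(perSample)),
    group = rep(grp, lengths(perSample)))
  bySeq <- split(long, long$sequence)
  bySeq <- bySeq[vapply(bySeq, nrow, integer(1)) >= 2L]
  out <- do.call(rbind, lapply(bySeq, function(d) {
    g <- unique(d$group)
    data.frame(sequence = d$sequence[1L],
               samples = paste(sort(d$sample_id), collapse = ","),
               n_samples = nrow(d),
               groups = paste(sort(g), collapse = ","),
               sharing = if (length(g) == 1L) "within_group"
                         else "between_group",
               row.names = NULL)
  }))
  if (is.null(out)) {
    out <- data.frame(sequence = character(), samples = character(),
                      n_samples = integer(), groups = character(),
                      sharing = character())
  }
  rownames(out) <- NULL
  structure(out,
            n_within_group = sum(out$sharing == "within_group"),
            n_between_group = sum(out$sharing == "between_group"))
}

#' Clustal-style text block for a set of equal-length sequences
#'
#' Formats labelled sequences with a final conservation symbol line, the
#' way alignment viewers print shared CDR3 sets.
#'
#' @param sequences equal-length amino acid strings.
#' @param labels one label per sequence.
#' @inheritParams conservationString
#' @return character vector of text lines.
#' @export
alignmentBlock <- function(sequences, labels = names(sequences),
                           scheme = clustalConservationGroups()) {
  if (is.null(labels)) labels <- sprintf("seq%d", seq_along(sequences))
  pad <- max(nchar(labels)) + 2L
  c(sprintf("%-*s%s", pad, labels, sequences),
    sprintf("%-*s%s", pad, "", conservationString(sequences, scheme)))
}
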