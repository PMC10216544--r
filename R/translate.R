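#' Translate CDR3 nucleotide junctions
#'
#' Translates each junction with the standard genetic code, reading complete
#' codons from the first base (the junction starts at the first base of the
#' conserved V-gene cysteine codon). A trailing partial codon is ignored for
#' the amino acid string and recorded as `in_frame = FALSE`. Stop codons
#' appear as `*` in the returned amino acid string and set `has_stop`.
#' `anchors_ok` flags the canonical junction anchors: first residue C
#' (conserved cysteine) and last residue F or W (conserved J-gene
#' phenylalanine/tryptophan).
#'
#' @param cdr3_nt character vector of A/C/G/T junction sequences (case
#'   insensitive).
#' @return a [S4Vectors::DataFrame] with columns `cdr3_aa`, `in_frame`,
#'   `has_stop`, `anchors_ok`, one row per input sequence.
#' @examples
#' translateCdr3(c("TGTGCCAGCAGTTTT", "TGTTAAAGC", "TGTGCCA"))
#' @export
translateCdr3 <- function(cdr3_nt) {
  nt <- toupper(as.character(cdr3_nt))
  if (!length(nt)) {
    return(DataFrame(cdr3_aa = character(), in_frame = logical(),
                     has_stop = logical(), anchors_ok = logical()))
  }
  bad <- which(is.na(nt) | !nzchar(nt) | grepl("[^ACGT]", nt))
  if (length(bad)) {
    stop("non-ACGT or empty sequence at position(s): ",
         paste(utils::head(bad, 10L), collapse = ", "))
  }
  len <- nchar(nt)
  in_frame <- len %% 3L == 0L
  trimmed <- substr(nt, 1L, (len %/% 3L) * 3L)
  aa <- as.character(suppressWarnings(
    Biostrings::translate(Biostrings::DNAStringSet(trimmed),
                          no.init.codon = TRUE)))
  has_stop <- grepl("*", aa, fixed = TRUE)
  nlast <- nchar(aa)
  anchors_ok <- nlast >= 2L &
    substr(aa, 1L, 1L) == "C" &
    substr(aa, nlast, nlast) %in% c("F", "W")
  DataFrame(cdr3_aa = aa, in_frame = in_frame, has_stop = has_stop,
            anchors_ok = anchors_ok)
}

#' @describeIn translateRepertoire translate one repertoire in place
#' @param verbose emit messages about frame-call disagreements between the
#'   source file and the computed translation (default `TRUE`).
#' @details
#' Productivity is defined as in-frame and stop-free. A frame status carried
#' by the source file takes precedence over the recomputed one; disagreements
#' are reported. When the source file supplied an amino acid sequence it is
#' cross-checked against the computed translation and the computed value is
#' used downstream (single source of truth), with a warning on mismatch.
#' Junction anchor conservation (C...F/W) is recorded as a flag but does not
#' affect productivity.
#' @export
setMethod("translateRepertoire", "CDR3Repertoire", function(x, verbose = TRUE) {
  df <- rearrangements(x)
  if (!nrow(df)) {
    for (col in c("in_frame", "has_stop", "anchors_ok", "productive")) {
      df[[col]] <- logical(0)
    }
    x@rearrangements <- df
    return(x)
  }
  tr <- translateCdr3(df$cdr3_nt)
  given_aa <- df$cdr3_aa
  mism <- !is.na(given_aa) & given_aa != tr$cdr3_aa
  if (any(mism) && verbose) {
    warning(sprintf(
      "sample %s: %d input cdr3_aa value(s) disagree with computed translation; using computed",
      sampleId(x), sum(mism)))
  }
  computed_status <- ifelse(!tr$in_frame, "out_of_frame",
                            ifelse(tr$has_stop, "stop", "in_frame"))
  fs <- df$frame_status
  disagree <- !is.na(fs) & fs != computed_status
  if (any(disagree) && verbose) {
    warning(sprintf(
      "sample %s: %d frame-status call(s) from the input file disagree with translation; input takes precedence",
      sampleId(x), sum(disagree)))
  }
  effective <- ifelse(is.na(fs), computed_status, fs)
  df$cdr3_aa <- tr$cdr3_aa
  df$in_frame <- tr$in_frame
  df$has_stop <- tr$has_stop
  df$anchors_ok <- tr$anchors_ok
  df$productive <- effective == "in_frame"
  x@rearrangements <- df
  x
})

#' @describeIn translateRepertoire translate every repertoire of a cohort
#' @export
setMethod("translateRepertoire", "CDR3Cohort", function(x, verbose = TRUE) {
  x@repertoires <- S4Vectors::endoapply(
    x@repertoires, translateRepertoire, verbose = verbose)
  x
})

#' Productivity of each rearrangement
#'
#' Returns the per-rearrangement productive flag (in-frame and stop-free,
#' with file-supplied frame calls taking precedence), translating first if
#' needed.
#'
#' @param repertoire a [CDR3Repertoire-class].
#' @return logical vector, one entry per unique rearrangement.
#' @examples
#' classifyProductive(CDR3Repertoire("s1", c("TGTGCCAGCAGTTTT", "TGTTAAAGC")))
#' @export
classifyProductive <- function(repertoire) {
  df <- rearrangements(repertoire)
  if (!"productive" %in% colnames(df)) {
    repertoire <- translateRepertoire(repertoire, verbose = FALSE)
    df <- rearrangements(repertoire)
  }
  df$productive
}
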