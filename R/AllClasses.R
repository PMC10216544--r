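#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<-
NULL

.FRAME_LEVELS <- c("in_frame", "out_of_frame", "stop")
.GROUP_LEVELS <- c("ARDS", "non_ARDS", "unlabeled")

#' CDR3Repertoire: one sample's rearrangement set
#'
#' Container for the unique TCR-beta CDR3 rearrangements observed in a single
#' sample. Each row of the rearrangement table is one unique CDR3 nucleotide
#' sequence with its template count (the number of input DNA molecules
#' attributed to that clonotype) and frame status. Rows are de-duplicated on
#' the nucleotide sequence at construction time, with template counts merged
#' by summation, so a `CDR3Repertoire` always holds clonotypes, not reads.
#'
#' @slot sampleId single character sample label, unique within a cohort.
#' @slot group clinical group label, one of `"ARDS"`, `"non_ARDS"`,
#'   `"unlabeled"`.
#' @slot rearrangements a [S4Vectors::DataFrame] with columns `cdr3_nt`
#'   (uppercase A/C/G/T junction), `cdr3_aa` (amino acid junction or `NA`
#'   before translation), `templates` (non-negative integer), `frame_status`
#'   (`"in_frame"`, `"out_of_frame"`, `"stop"`, or `NA` when the source file
#'   carried no frame call). Translation adds the logical columns `in_frame`,
#'   `has_stop`, `anchors_ok` and `productive`.
#'
#' @seealso [CDR3Repertoire()] for the user-facing constructor,
#'   [readRearrangements()] to build cohorts from files.
#' @export
setClass("CDR3Repertoire",
  representation(
    sampleId = "character",
    group = "character",
    rearrangements = "DataFrame"
  )
)

setValidity("CDR3Repertoire", function(object) {
  msg <- character()
  if (length(object@sampleId) != 1L || is.na(object@sampleId) ||
      !nzchar(object@sampleId)) {
    msg <- c(msg, "'sampleId' must be a single non-empty string")
  }
  if (length(object@group) != 1L || !object@group %in% .GROUP_LEVELS) {
    msg <- c(msg, sprintf("'group' must be one of %s",
                          paste(sQuote(.GROUP_LEVELS), collapse = ", ")))
  }
  df <- object@rearrangements
  need <- c("cdr3_nt", "cdr3_aa", "templates", "frame_status")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) {
    msg <- c(msg, sprintf("rearrangements lack column(s): %s",
                          paste(miss, collapse = ", ")))
  } else if (nrow(df)) {
    if (anyDuplicated(df$cdr3_nt)) {
      msg <- c(msg, "duplicate cdr3_nt entries; counts must be merged")
    }
    if (any(!nzchar(df$cdr3_nt)) || anyNA(df$cdr3_nt)) {
      msg <- c(msg, "cdr3_nt must be non-empty")
    } else if (any(grepl("[^ACGT]", df$cdr3_nt))) {
      msg <- c(msg, "cdr3_nt contains non-ACGT characters")
    }
    if (anyNA(df$templates) || any(df$templates < 0L)) {
      msg <- c(msg, "templates must be non-negative")
    }
    bad_fs <- !is.na(df$frame_status) & !df$frame_status %in% .FRAME_LEVELS
    if (any(bad_fs)) {
      msg <- c(msg, "frame_status values outside {in_frame, out_of_frame, stop}")
    }
    inf <- !is.na(df$frame_status) & df$frame_status == "in_frame"
    if (any(inf & nchar(df$cdr3_nt) %% 3L != 0L)) {
      msg <- c(msg, "in_frame rearrangements must have nt length divisible by 3")
    }
  }
  if (length(msg)) msg else TRUE
})

#' CDR3Cohort: a collection of repertoires
#'
#' Holds one [CDR3Repertoire-class] per sample together with free-text
#' provenance describing where the cohort came from (file paths or simulation
#' parameters).
#'
#' @slot repertoires a [S4Vectors::SimpleList] of [CDR3Repertoire-class]
#'   objects, names matching their sample ids.
#' @slot provenance free-text character metadata.
#'
#' @seealso [CDR3Cohort()], [readRearrangements()], [simulateCohort()]
#' @export
setClass("CDR3Cohort",
  representation(
    repertoires = "SimpleList",
    provenance = "character"
  )
)

setValidity("CDR3Cohort", function(object) {
  msg <- character()
  reps <- object@repertoires
  if (length(reps) < 1L) msg <- c(msg, "a cohort needs at least one repertoire")
  if (!all(vapply(reps, is, logical(1), "CDR3Repertoire"))) {
    msg <- c(msg, "all elements must be CDR3Repertoire objects")
  } else {
    ids <- vapply(reps, function(r) r@sampleId, character(1))
    if (anyDuplicated(ids)) msg <- c(msg, "sample ids must be unique")
    if (!identical(unname(names(reps)), unname(ids)) && length(reps)) {
      msg <- c(msg, "repertoire list names must equal their sample ids")
    }
  }
  if (length(msg)) msg else TRUE
})

#' ImmunogenicityModel: residue enrichment weights with position importance
#'
#' Encodes the enrichment model behind class I pMHC immunogenicity scoring:
#' a log-enrichment weight per amino acid (residues over-represented among
#' immunogenic peptides score positive) and an importance weight per peptide
#' position on a 9-mer template. Positions 1, 2 and the C-terminal position
#' are anchor/processing positions and carry zero importance (the mask), so
#' only the TCR-facing interior contributes to the score.
#'
#' @slot enrichment named numeric, one weight per standard amino acid.
#' @slot importance numeric length-9 position-importance vector; entries for
#'   masked positions are 0.
#' @slot maskPositions integer positions on the 9-mer template excluded from
#'   scoring (9 denotes the C-terminal position of any peptide).
#' @slot description free-text provenance of the constants.
#'
#' @seealso [defaultImmunogenicityModel()], [scorePeptide()]
#' @export
setClass("ImmunogenicityModel",
  representation(
    enrichment = "numeric",
    importance = "numeric",
    maskPositions = "integer",
    description = "character"
  )
)

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

setValidity("ImmunogenicityModel", function(object) {
  msg <- character()
  miss <- setdiff(.AA20, names(object@enrichment))
  if (length(miss)) {
    msg <- c(msg, sprintf("enrichment weights missing for: %s",
                          paste(miss, collapse = ", ")))
  }
  if (length(object@importance) != 9L) {
    msg <- c(msg, "importance must have one weight per 9-mer position")
  }
  if (any(object@maskPositions < 1L | object@maskPositions > 9L)) {
    msg <- c(msg, "maskPositions must lie in 1..9")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CDR3Repertoire
#'
#' Builds a validated repertoire from parallel vectors. Input nucleotide
#' sequences are uppercased; duplicate nucleotide sequences are merged with
#' template counts summed (the first non-missing amino acid sequence and
#' frame status of each duplicate set are kept).
#'
#' @param sampleId single sample label.
#' @param cdr3_nt character vector of CDR3 nucleotide junctions (A/C/G/T).
#' @param templates non-negative template counts, recycled length-1 allowed.
#' @param group clinical group label (`"ARDS"`, `"non_ARDS"`, `"unlabeled"`).
#' @param cdr3_aa optional amino acid junctions as given by the source file.
#' @param frame_status optional frame calls (`"in_frame"`, `"out_of_frame"`,
#'   `"stop"`, or `NA`).
#' @return a [CDR3Repertoire-class] object.
#' @examples
#' rep <- CDR3Repertoire("s1", c("TGTGCCAGCAGTTTT", "TGTGCCAGCAGTTTT"),
#'                       templates = c(2, 3))
#' rearrangements(rep)$templates  # merged to 5
#' @export
CDR3Repertoire <- function(sampleId, cdr3_nt, templates = 1L,
                           group = "unlabeled", cdr3_aa = NA_character_,
                           frame_status = NA_character_) {
  n <- length(cdr3_nt)
  cdr3_nt <- toupper(as.character(cdr3_nt))
  bad <- grep("[^ACGT]", cdr3_nt)
  if (length(bad)) {
    stop(sprintf("non-ACGT character in cdr3_nt at row(s): %s",
                 paste(bad, collapse = ", ")))
  }
  templates <- rep_len(as.integer(templates), n)
  cdr3_aa <- rep_len(as.character(cdr3_aa), n)
  frame_status <- rep_len(as.character(frame_status), n)
  df <- DataFrame(cdr3_nt = cdr3_nt, cdr3_aa = cdr3_aa,
                  templates = templates, frame_status = frame_status)
  df <- .mergeDuplicates(df)
  new("CDR3Repertoire", sampleId = as.character(sampleId),
      group = as.character(group), rearrangements = df)
}

## merge duplicate cdr3_nt rows: templates summed, first non-NA annotation kept
.mergeDuplicates <- function(df) {
  if (!nrow(df) || !anyDuplicated(df$cdr3_nt)) return(df)
  key <- factor(df$cdr3_nt, levels = unique(df$cdr3_nt))
  idx <- split(seq_len(nrow(df)), key)
  first <- vapply(idx, `[`, integer(1), 1L)
  out <- df[first, , drop = FALSE]
  out$templates <- unname(vapply(idx, function(i) sum(df$templates[i]),
                                 integer(1)))
  firstNonNA <- function(x) {
    x <- x[!is.na(x)]
    if (length(x)) x[[1L]] else NA_character_
  }
  out$cdr3_aa <- unname(vapply(idx, function(i) firstNonNA(df$cdr3_aa[i]),
                               character(1)))
  out$frame_status <- unname(vapply(idx, function(i)
    firstNonNA(df$frame_status[i]), character(1)))
  rownames(out) <- NULL
  out
}

#' Construct a CDR3Cohort
#'
#' @param repertoires a list of [CDR3Repertoire-class] objects.
#' @param provenance free-text metadata.
#' @return a [CDR3Cohort-class] object.
#' @examples
#' r1 <- CDR3Repertoire("s1", "TGTGCCAGCAGTTTT", 3)
#' r2 <- CDR3Repertoire("s2", "TGTGCCTGGTTT", 1)
#' CDR3Cohort(list(r1, r2))
#' @export
CDR3Cohort <- function(repertoires, provenance = character()) {
  reps <- SimpleList(repertoires)
  names(reps) <- vapply(reps, function(r) r@sampleId, character(1))
  new("CDR3Cohort", repertoires = reps, provenance = provenance)
}
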