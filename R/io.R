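## Column maps for the two rearrangement-table dialects in live use:
## a simplified immunoSEQ-style export and the AIRR Rearrangement standard.
.DIALECTS <- list(
  immunoseq = c(cdr3_nt = "rearrangement", cdr3_aa = "amino_acid",
                templates = "templates", frame = "frame_type",
                sample = "sample_id"),
  airr = c(cdr3_nt = "junction", cdr3_aa = "junction_aa",
           templates = "duplicate_count", frame = "productive",
           sample = "sample_id")
)

#' Read a rearrangement table into a CDR3Cohort
#'
#' Parses a tab-separated rearrangement table with one row per unique CDR3
#' nucleotide sequence. Two header dialects are accepted: an immunoSEQ-style
#' export (`rearrangement`, `amino_acid`, `templates`, `frame_type`,
#' `sample_id`) and the AIRR Rearrangement subset (`junction`, `junction_aa`,
#' `duplicate_count`, `productive`, `sample_id`). With `dialect = "auto"` the
#' dialect is resolved from the header names. Nucleotide sequences are
#' uppercased; duplicate sequences within a sample are merged with template
#' counts summed. Group labels are never inferred from sample names: supply
#' them through a two-column metadata file (`sample_id`, `group`).
#'
#' immunoSEQ `frame_type` values In/Out/Stop map to frame status
#' `in_frame`/`out_of_frame`/`stop`. AIRR files carry `productive` (T/F) plus
#' optional `vj_in_frame` and `stop_codon` flags; a productive row is
#' `in_frame`, a non-productive row is `stop` when `stop_codon` is T and
#' `out_of_frame` otherwise.
#'
#' @param path TSV file path.
#' @param dialect `"auto"` (default), `"immunoseq"` or `"airr"`.
#' @param metadata optional path to a tab-separated two-column file
#'   (`sample_id`, `group`) assigning each sample to `"ARDS"`, `"non_ARDS"`
#'   or `"unlabeled"`.
#' @return a [CDR3Cohort-class].
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines(c("rearrangement\tamino_acid\ttemplates\tframe_type\tsample_id",
#'              "TGTGCCAGCAGTTTT\tCASSF\t3\tIn\ts1",
#'              "TGTGCCTGGTTT\tCAWF\t1\tIn\ts1"), tsv)
#' readRearrangements(tsv)
#' @export
readRearrangements <- function(path, dialect = c("auto", "immunoseq", "airr"),
                               metadata = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (!nrow(tab)) stop("empty rearrangement table: ", path)
  if (dialect == "auto") {
    dialect <- if (all(c("junction", "duplicate_count") %in% colnames(tab)) ||
                   "junction" %in% colnames(tab)) {
      if ("rearrangement" %in% colnames(tab))
        stop("ambiguous header (both 'rearrangement' and 'junction' present); ",
             "set dialect explicitly")
      "airr"
    } else if ("rearrangement" %in% colnames(tab)) {
      "immunoseq"
    } else {
      stop("cannot resolve dialect: header has neither 'rearrangement' ",
           "(immunoseq) nor 'junction' (airr)")
    }
  }
  map <- .DIALECTS[[dialect]]
  for (col in map[c("cdr3_nt", "sample")]) {
    if (!col %in% colnames(tab)) {
      stop(sprintf("missing mandatory column '%s' for dialect '%s'",
                   col, dialect))
    }
  }
  nt <- toupper(tab[[map[["cdr3_nt"]]]])
  bad <- which(is.na(nt) | !nzchar(nt) | grepl("[^ACGT]", nt))
  if (length(bad)) {
    stop(sprintf(
      "invalid cdr3_nt (empty or non-ACGT; ambiguity codes are rejected) at data row(s): %s",
      paste(utils::head(bad, 10L), collapse = ", ")))
  }
  if (map[["templates"]] %in% colnames(tab)) {
    templates <- suppressWarnings(as.integer(tab[[map[["templates"]]]]))
    if (anyNA(templates) || any(templates < 0L)) {
      stop("non-numeric or negative template counts in column ",
           sQuote(map[["templates"]]))
    }
  } else {
    warning("no template-count column (", sQuote(map[["templates"]]),
            "); assuming 1 template per row")
    templates <- rep.int(1L, nrow(tab))
  }
  aa <- if (map[["cdr3_aa"]] %in% colnames(tab)) {
    a <- toupper(tab[[map[["cdr3_aa"]]]])
    a[!nzchar(a)] <- NA_character_
    a
  } else rep(NA_character_, nrow(tab))
  frame <- .readFrameStatus(tab, dialect)
  samples <- tab[[map[["sample"]]]]
  groups <- .readGroups(metadata)
  reps <- lapply(unique(samples), function(s) {
    i <- samples == s
    grp <- if (!is.null(groups) && s %in% names(groups)) groups[[s]]
           else "unlabeled"
    CDR3Repertoire(s, nt[i], templates[i], group = grp,
                   cdr3_aa = aa[i], frame_status = frame[i])
  })
  CDR3Cohort(reps, provenance = sprintf("read from %s (dialect %s)",
                                        path, dialect))
}

.readFrameStatus <- function(tab, dialect) {
  n <- nrow(tab)
  if (dialect == "immunoseq") {
    if (!"frame_type" %in% colnames(tab)) return(rep(NA_character_, n))
    f <- tolower(tab$frame_type)
    out <- rep(NA_character_, n)
    out[f %in% c("in", "in_frame", "inframe")] <- "in_frame"
    out[f %in% c("out", "out_of_frame", "outofframe")] <- "out_of_frame"
    out[f %in% c("stop", "has_stop")] <- "stop"
    return(out)
  }
  if (!"productive" %in% colnames(tab)) return(rep(NA_character_, n))
  prod <- toupper(tab$productive) %in% c("T", "TRUE", "YES", "1")
  out <- rep(NA_character_, n)
  out[prod] <- "in_frame"
  if ("stop_codon" %in% colnames(tab)) {
    stopc <- toupper(tab$stop_codon) %in% c("T", "TRUE", "YES", "1")
    out[!prod & stopc] <- "stop"
    out[!prod & !stopc] <- "out_of_frame"
  } else if ("vj_in_frame" %in% colnames(tab)) {
    inf <- toupper(tab$vj_in_frame) %in% c("T", "TRUE", "YES", "1")
    out[!prod & inf] <- "stop"       # in frame yet unproductive => stop codon
    out[!prod & !inf] <- "out_of_frame"
  } else {
    ## productive=F alone cannot distinguish frameshift from stop; leave to
    ## translation (frame status NA defers to the computed classification)
    out[!prod] <- NA_character_
  }
  out
}

.readGroups <- function(metadata) {
  if (is.null(metadata)) return(NULL)
  md <- utils::read.delim(metadata, header = TRUE, sep = "\t",
                          colClasses = "character")
  if (!all(c("sample_id", "group") %in% colnames(md))) {
    stop("metadata file must have columns 'sample_id' and 'group'")
  }
  bad <- setdiff(unique(md$group), .GROUP_LEVELS)
  if (length(bad)) {
    stop("unknown group label(s) in metadata: ", paste(bad, collapse = ", "))
  }
  stats::setNames(md$group, md$sample_id)
}

#' Write translated CDR3 amino acid sequences to FASTA
#'
#' Writes one record per rearrangement, header `sampleId|index|templates`,
#' sequence lines wrapped at 80 columns. Every record must carry a
#' `cdr3_aa`; translate first with [translateRepertoire()]. By default only
#' productive rearrangements are written (the downstream biochemical and
#' immunogenicity analyses operate on protein products).
#'
#' @param repertoire a [CDR3Repertoire-class].
#' @param path output file path.
#' @param productiveOnly write only productive records (default `TRUE`;
#'   requires productivity classification, else all records with an aa
#'   sequence are candidates).
#' @return the number of records written, invisibly a count.
#' @examples
#' rep <- translateRepertoire(CDR3Repertoire("s1", "TGTGCCAGCAGTTTT", 3))
#' fa <- tempfile(fileext = ".fasta")
#' writeCdr3Fasta(rep, fa)
#' @export
writeCdr3Fasta <- function(repertoire, path, productiveOnly = TRUE) {
  df <- rearrangements(repertoire)
  keep <- if (productiveOnly && "productive" %in% colnames(df)) {
    which(df$productive)
  } else {
    seq_len(nrow(df))
  }
  if (length(keep) && anyNA(df$cdr3_aa[keep])) {
    stop("records lack cdr3_aa; run translateRepertoire() first")
  }
  seqs <- Biostrings::AAStringSet(as.character(df$cdr3_aa[keep]))
  names(seqs) <- sprintf("%s|%d|%d", sampleId(repertoire), keep,
                         df$templates[keep])
  Biostrings::writeXStringSet(seqs, filepath = path, width = 80L)
  length(seqs)
}
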