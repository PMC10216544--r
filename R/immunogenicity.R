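#' Construct an immunogenicity model
#'
#' @param enrichment named numeric log-enrichment weight per standard amino
#'   acid (all 20 required).
#' @param importance numeric length-9 position-importance vector on the
#'   9-mer template; masked positions must carry 0.
#' @param maskPositions template positions excluded from scoring; the last
#'   entry is interpreted as the C-terminal position of any peptide.
#' @param description free-text provenance.
#' @return an [ImmunogenicityModel-class].
#' @seealso [defaultImmunogenicityModel()]
#' @export
ImmunogenicityModel <- function(enrichment, importance,
                                maskPositions = c(1L, 2L, 9L),
                                description = "user-supplied") {
  importance[maskPositions] <- 0
  new("ImmunogenicityModel", enrichment = enrichment,
      importance = as.numeric(importance),
      maskPositions = as.integer(maskPositions),
      description = as.character(description))
}

#' Load an immunogenicity model from a weight file
#'
#' The file is a tab-separated three-column table (`type`, `key`, `weight`;
#' `#` comments allowed) with one `residue` row per amino acid and nine
#' `position` rows for the 9-mer importance vector.
#'
#' @param path weight file path.
#' @return an [ImmunogenicityModel-class].
#' @export
readImmunogenicityModel <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           col.names = c("type", "key", "weight"),
                           colClasses = c("character", "character", "numeric"))
  res <- tab[tab$type == "residue", ]
  pos <- tab[tab$type == "position", ]
  imp <- numeric(9L)
  imp[as.integer(pos$key)] <- pos$weight
  ImmunogenicityModel(stats::setNames(res$weight, res$key), imp,
                      maskPositions = c(1L, 2L, 9L),
                      description = paste("loaded from", basename(path)))
}

#' Packaged default immunogenicity model
#'
#' Loads the enrichment weight file shipped with the package (see
#' `system.file("extdata", "immunogenicity_model_default.tsv",
#' package = "cdr3profiler")` for the constants and their provenance).
#'
#' @return an [ImmunogenicityModel-class].
#' @examples
#' defaultImmunogenicityModel()
#' @export
defaultImmunogenicityModel <- function() {
  readImmunogenicityModel(system.file("extdata",
                                      "immunogenicity_model_default.tsv",
                                      package = "cdr3profiler"))
}

## position-importance weights for a peptide of length L: template positions
## 1 and 2 and the C-terminal position are masked (weight 0); interior
## positions beyond the 9-mer importance map reuse the central-position
## weight (a documented extrapolation for long CDR3 peptides).
.positionWeights <- function(L, model) {
  imp <- model@importance
  central <- imp[5L]
  w <- numeric(L)
  if (L > 2L) {
    interior <- 3L:(L - 1L)
    w[interior] <- ifelse(interior <= 8L, imp[interior], central)
  }
  w[c(1L, min(2L, L), L)] <- 0
  w
}

#' Score a peptide with the enrichment immunogenicity model
#'
#' The score is the sum over unmasked positions of the residue's
#' log-enrichment weight times the position importance; peptides scoring
#' above 0 are classified immunogenicity-positive. The default mode scores
#' each whole CDR3 peptide once; `mode = "max9"` instead slides a 9-residue
#' window and reports the maximum window score (peptides shorter than 9 are
#' then scored whole).
#'
#' @param cdr3_aa peptide of standard residues, length at least 3 (shorter
#'   peptides are entirely covered by the anchor mask).
#' @param model an [ImmunogenicityModel-class] (default the packaged model).
#' @param mode `"whole"` (default) or `"max9"`.
#' @return data.frame row: `cdr3_aa`, `score`, `positive`.
#' @examples
#' scorePeptide("CASSLGQAYEQYF")
#' @export
scorePeptide <- function(cdr3_aa, model = defaultImmunogenicityModel(),
                         mode = c("whole", "max9")) {
  mode <- match.arg(mode)
  res <- strsplit(cdr3_aa, "")[[1L]]
  L <- length(res)
  if (L < 3L) {
    stop("peptide shorter than 3 residues; the position mask covers it entirely")
  }
  unknown <- setdiff(res, names(model@enrichment))
  if (length(unknown)) {
    stop("residue(s) without enrichment weight: ",
         paste(unique(unknown), collapse = ", "))
  }
  oneScore <- function(res) {
    sum(model@enrichment[res] * .positionWeights(length(res), model))
  }
  score <- if (mode == "whole" || L <= 9L) {
    oneScore(res)
  } else {
    max(vapply(seq_len(L - 8L),
               function(i) oneScore(res[i:(i + 8L)]), numeric(1)))
  }
  data.frame(cdr3_aa = cdr3_aa, score = unname(score),
             positive = unname(score) > 0, row.names = NULL)
}

#' Score every productive CDR3 of a repertoire
#'
#' @param repertoire a [CDR3Repertoire-class].
#' @inheritParams scorePeptide
#' @return data.frame with `sample_id`, `group`, `cdr3_aa`, `score`,
#'   `positive` (one row per productive clonotype).
#' @export
scoreRepertoire <- function(repertoire, model = defaultImmunogenicityModel(),
                            mode = c("whole", "max9")) {
  mode <- match.arg(mode)
  aa <- productiveSequences(repertoire)
  if (!length(aa)) return(NULL)
  scored <- do.call(rbind, lapply(aa, scorePeptide, model = model, mode = mode))
  cbind(sample_id = sampleId(repertoire), group = groupLabel(repertoire),
        scored)
}

#' Summarize immunogenicity calls for one sample
#'
#' @param scores data.frame with a logical `positive` column (as from
#'   [scorePeptide()] rows), or a logical vector of calls.
#' @param sample_id label for the output row.
#' @return data.frame row: `sample_id`, `positive_count`, `total_count`,
#'   `percent_positive` (percentage, reported to two decimals).
#' @examples
#' summarizeImmunogenicity(c(TRUE, FALSE, TRUE, FALSE), "s1")
#' @export
summarizeImmunogenicity <- function(scores, sample_id = NA_character_) {
  pos <- if (is.data.frame(scores)) scores$positive else as.logical(scores)
  if (!length(pos)) stop("empty score collection")
  data.frame(sample_id = sample_id,
             positive_count = sum(pos), total_count = length(pos),
             percent_positive = round(100 * sum(pos) / length(pos), 2),
             row.names = NULL)
}

#' Immunogenicity summary across a cohort
#'
#' @param cohort a [CDR3Cohort-class].
#' @inheritParams scorePeptide
#' @return list with `scores` (per-clonotype data.frame) and `summary`
#'   (per-sample positive counts and percent positive, with group labels).
#' @export
cohortImmunogenicity <- function(cohort, model = defaultImmunogenicityModel(),
                                 mode = c("whole", "max9")) {
  mode <- match.arg(mode)
  scores <- do.call(rbind, lapply(as.list(repertoires(cohort)),
                                  scoreRepertoire, model = model, mode = mode))
  summary <- do.call(rbind, lapply(split(scores, scores$sample_id), function(s)
    cbind(summarizeImmunogenicity(s, s$sample_id[1L])[1L],
          group = s$group[1L],
          summarizeImmunogenicity(s, s$sample_id[1L])[-1L])))
  rownames(summary) <- NULL
  list(scores = scores, summary = summary)
}

#' Compare immunogenicity score variances between two groups
#'
#' F-test for equality of variances of per-sequence immunogenicity scores
#' between two clinical groups. The choice of an F-test is a documented,
#' replaceable convention — pass any two-sample variance test through
#' `testFun` (e.g. a permutation test) to change it.
#'
#' @param scores data.frame with `score` and `group` columns (as from
#'   [cohortImmunogenicity()]).
#' @param groups length-2 character vector naming the groups to compare.
#' @param testFun function(x, y) returning an object with a `p.value`
#'   (default [stats::var.test]).
#' @return the test object returned by `testFun`.
#' @export
immunogenicityVarianceTest <- function(scores,
                                       groups = c("ARDS", "non_ARDS"),
                                       testFun = stats::var.test) {
  x <- scores$score[scores$group == groups[[1L]]]
  y <- scores$score[scores$group == groups[[2L]]]
  if (length(x) < 2L || length(y) < 2L) {
    stop("each group needs at least two scores")
  }
  testFun(x, y)
}
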