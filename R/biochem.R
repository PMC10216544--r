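#' Default pKa table for peptide net charge
#'
#' Dissociation constants for the nine ionizable groups entering the
#' Henderson-Hasselbalch net-charge model: both termini, the basic side
#' chains (K, R, H) and the acidic/titratable side chains (D, E, C, Y).
#' The defaults are a widely used published set; supply your own named
#' vector to match the constants of any other pI tool.
#'
#' @return named numeric vector with entries `N_terminus`, `C_terminus`,
#'   `K`, `R`, `H`, `D`, `E`, `C`, `Y`, all in (0, 14).
#' @examples
#' defaultPkaTable()
#' @export
defaultPkaTable <- function() {
  c(N_terminus = 8.6, C_terminus = 3.6,
    K = 10.8, R = 12.5, H = 6.5,
    D = 3.9, E = 4.1, C = 8.5, Y = 10.1)
}

.checkPka <- function(pka) {
  need <- names(defaultPkaTable())
  miss <- setdiff(need, names(pka))
  if (length(miss)) {
    stop("pKa table missing group(s): ", paste(miss, collapse = ", "))
  }
  if (any(pka[need] <= 0 | pka[need] >= 14)) stop("pKa values must lie in (0, 14)")
  pka[need]
}

.residueCounts <- function(cdr3_aa, allowed = .AA20) {
  res <- strsplit(cdr3_aa, "")[[1L]]
  unknown <- setdiff(res, allowed)
  if (length(unknown)) {
    stop("nonstandard residue(s) in peptide: ",
         paste(unique(unknown), collapse = ", "))
  }
  table(factor(res, levels = allowed))
}

#' Net charge of a peptide at a given pH
#'
#' Henderson-Hasselbalch sum over the peptide's ionizable groups: the free
#' N-terminus and each basic side chain contribute `1/(1 + 10^(pH - pKa))`
#' positive charge; the free C-terminus and each acidic side chain
#' contribute `1/(1 + 10^(pKa - pH))` negative charge. The result is
#' strictly decreasing in pH, which makes the isoelectric point a unique
#' root.
#'
#' @param cdr3_aa peptide sequence of standard residues (B/Z ambiguity codes
#'   have no defined pKa and are rejected).
#' @param pH numeric pH (vectorized).
#' @param pka named pKa vector as from [defaultPkaTable()].
#' @return net charge (same length as `pH`).
#' @examples
#' netCharge("CASSF", 7)
#' @export
netCharge <- function(cdr3_aa, pH, pka = defaultPkaTable()) {
  pka <- .checkPka(pka)
  cnt <- .residueCounts(cdr3_aa)
  pos <- 1 / (1 + 10^(pH - pka[["N_terminus"]]))
  for (r in c("K", "R", "H")) {
    pos <- pos + cnt[[r]] / (1 + 10^(pH - pka[[r]]))
  }
  neg <- 1 / (1 + 10^(pka[["C_terminus"]] - pH))
  for (r in c("D", "E", "C", "Y")) {
    neg <- neg + cnt[[r]] / (1 + 10^(pka[[r]] - pH))
  }
  pos - neg
}

#' Theoretical isoelectric point of a peptide
#'
#' Finds the pH at which [netCharge()] is zero by bisection on \[0, 14\].
#' Because the net charge is strictly decreasing in pH the root is unique
#' and the procedure is deterministic. Iteration stops when the absolute
#' charge falls below `tol` or the bracketing interval is narrower than
#' 1e-6 pH units.
#'
#' @inheritParams netCharge
#' @param tol convergence tolerance on the absolute net charge (charge
#'   units, default 1e-4).
#' @return list with `cdr3_aa` and `pI` (pH in (0, 14)).
#' @examples
#' isoelectricPoint("CASSF")$pI
#' @export
isoelectricPoint <- function(cdr3_aa, pka = defaultPkaTable(), tol = 1e-4) {
  lo <- 0
  hi <- 14
  repeat {
    mid <- (lo + hi) / 2
    q <- netCharge(cdr3_aa, mid, pka)
    if (abs(q) < tol || (hi - lo) < 1e-6) break
    if (q > 0) lo <- mid else hi <- mid
  }
  list(cdr3_aa = cdr3_aa, pI = mid)
}

#' Per-sequence isoelectric points across a cohort
#'
#' @param cohort a translated [CDR3Cohort-class]; productive sequences only.
#' @inheritParams isoelectricPoint
#' @return data.frame with `sample_id`, `group`, `cdr3_aa`, `pI`.
#' @export
cohortIsoelectricPoints <- function(cohort, pka = defaultPkaTable(),
                                    tol = 1e-4) {
  do.call(rbind, lapply(as.list(repertoires(cohort)), function(rep) {
    aa <- productiveSequences(rep)
    if (!length(aa)) return(NULL)
    data.frame(sample_id = sampleId(rep), group = groupLabel(rep),
               cdr3_aa = aa,
               pI = vapply(aa, function(s) isoelectricPoint(s, pka, tol)$pI,
                           numeric(1), USE.NAMES = FALSE))
  }))
}

## productive aa sequences of a repertoire (translating if necessary)
productiveSequences <- function(repertoire) {
  df <- rearrangements(repertoire)
  if (!"productive" %in% colnames(df)) {
    df <- rearrangements(translateRepertoire(repertoire, verbose = FALSE))
  }
  as.character(df$cdr3_aa[df$productive])
}

#' Residue physicochemical property scheme
#'
#' The IUPAC-IUB style grouping used for CDR3 residue composition: six
#' physicochemical groups (Aliphatic, Aromatic, Sulphur, Basic, Acidic,
#' Aliphatic hydroxyl — pairwise disjoint, jointly covering every standard
#' residue except proline) plus the two aminoacyl-tRNA synthetase classes,
#' which partition all twenty residues (and the Asx/Glx ambiguity codes B
#' and Z) into class I and class II. A residue may belong to one
#' physicochemical group and one synthetase class at the same time.
#'
#' @return named list of character vectors (group name to residue set).
#' @examples
#' propertyScheme()$Aromatic
#' @export
propertyScheme <- function() {
  list(
    "Aliphatic" = c("G", "A", "V", "L", "I"),
    "Aromatic" = c("F", "W", "Y"),
    "Sulphur" = c("C", "M"),
    "Basic" = c("K", "R", "H"),
    "Acidic" = c("B", "D", "E", "N", "Q", "Z"),
    "Aliphatic hydroxyl" = c("S", "T"),
    "tRNA synthetase class I" = c("Z", "E", "Q", "R", "C", "M", "V", "I",
                                  "L", "Y", "W"),
    "tRNA synthetase class II" = c("B", "G", "A", "P", "S", "T", "H", "D",
                                   "N", "K", "F")
  )
}

#' Residue-property composition of a peptide collection
#'
#' Counts residue occurrences per property group across all peptides. A
#' residue may count toward several overlapping groups (e.g. E is both
#' Acidic and tRNA synthetase class I), so percentages are on the total
#' residue count, and the two synthetase-class percentages always sum
#' to 100. With `weights` supplied (e.g. template counts) each peptide's
#' residues are multiplied by its weight; the default counts every peptide
#' once, giving raw residue occurrence counts.
#'
#' @param peptides character vector of amino acid sequences.
#' @param scheme grouping as from [propertyScheme()].
#' @param weights optional non-negative numeric weights, one per peptide.
#' @return data.frame with `group`, `times_found`, `percentage`, plus
#'   attribute `total_residues`.
#' @examples
#' residueComposition("CASSF")
#' @export
residueComposition <- function(peptides, scheme = propertyScheme(),
                               weights = NULL) {
  if (!length(peptides)) stop("empty peptide collection")
  if (is.null(weights)) weights <- rep.int(1, length(peptides))
  stopifnot(length(weights) == length(peptides), all(weights >= 0))
  allowed <- union(.AA20, c("B", "Z"))
  counts <- stats::setNames(numeric(length(allowed)), allowed)
  for (i in seq_along(peptides)) {
    cnt <- .residueCounts(peptides[[i]], allowed = allowed)
    counts <- counts + as.numeric(cnt) * weights[[i]]
  }
  total <- sum(counts)
  if (total == 0) stop("no residues counted (all weights zero?)")
  tf <- vapply(scheme, function(set) sum(counts[set]), numeric(1))
  data.frame(group = names(scheme), times_found = unname(tf),
             percentage = unname(100 * tf / total),
             row.names = NULL) |>
    structure(total_residues = total)
}

#' Composition tables per sample and per group
#'
#' Pools productive CDR3 amino acid sequences per sample and per clinical
#' group and applies [residueComposition()] to each pool.
#'
#' @param cohort a translated [CDR3Cohort-class].
#' @param scheme grouping as from [propertyScheme()].
#' @param templateWeighted weight each sequence by its template count
#'   (default `FALSE`: raw occurrence counts over unique clonotypes).
#' @return data.frame with `level` (`"sample"` or `"group"`), `id`, `group`,
#'   `times_found`, `percentage`.
#' @export
cohortComposition <- function(cohort, scheme = propertyScheme(),
                              templateWeighted = FALSE) {
  reps <- as.list(repertoires(cohort))
  one <- function(aa, w, level, id) {
    if (!length(aa)) return(NULL)
    comp <- residueComposition(aa, scheme, weights = w)
    data.frame(level = level, id = id, comp, row.names = NULL)
  }
  pools <- lapply(reps, function(rep) {
    df <- rearrangements(translateRepertoire(rep, verbose = FALSE))
    df <- df[df$productive, , drop = FALSE]
    list(aa = as.character(df$cdr3_aa),
         w = if (templateWeighted) df$templates else NULL,
         group = groupLabel(rep), id = sampleId(rep))
  })
  bySample <- do.call(rbind, lapply(pools, function(p)
    one(p$aa, p$w, "sample", p$id)))
  groups <- unique(vapply(pools, `[[`, character(1), "group"))
  byGroup <- do.call(rbind, lapply(groups, function(g) {
    sel <- pools[vapply(pools, function(p) p$group == g, logical(1))]
    one(unlist(lapply(sel, `[[`, "aa")),
        if (templateWeighted) unlist(lapply(sel, `[[`, "w")) else NULL,
        "group", g)
  }))
  rbind(bySample, byGroup)
}
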