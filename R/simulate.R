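## sense codons (61, stops excluded) for junction interiors
.SENSE_CODONS <- local({
  b <- c("A", "C", "G", "T")
  all <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all, c("TAA", "TAG", "TGA"))
})
.STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Simulation configuration for synthetic CDR3 cohorts
#'
#' Bundles and validates the knobs of the repertoire generator. The
#' defaults emulate a small two-group lung edema fluid TCR-beta cohort: 4
#' ARDS-like and 3 non-ARDS-like samples; unique clone counts drawn per
#' sample from 56-1560 (ARDS) and 25-169 (non-ARDS); productive junction
#' lengths in nt multiples of 3 spanning 21-69 (ARDS) and 30-66
#' (non-ARDS); clone frequencies from a symmetric Dirichlet with
#' concentration `alpha = 2`, which puts Simpson clonality roughly in
#' 0.04-0.24 across those sample sizes (plug-in expectation
#' `(1+alpha)/(1+k*alpha)` for k clones); a 10% nonproductive clone
#' fraction realized by frameshift or internal stop injection; and a
#' shared-clone plan planting 4 sequences across three same-group samples
#' plus 1 across groups.
#'
#' @param nSamples named integer vector: samples per group.
#' @param cloneRange named list of length-2 integer ranges of unique clones
#'   per sample, by group.
#' @param lengthRange named list of length-2 nt length bounds (multiples of
#'   3), by group.
#' @param alpha Dirichlet concentration (> 0); larger is more even.
#' @param model `"dirichlet"` or `"powerlaw"` (frequencies proportional to
#'   `rank^-powerlawExponent`, a heavy-tailed alternative).
#' @param powerlawExponent exponent for the power-law mode.
#' @param nonproductiveFraction fraction of clones made nonproductive,
#'   in \[0, 1).
#' @param depth named numeric vector: total templates per sample, by group.
#' @param sharedPlan list of `list(n = <count>, samples = <ids>)` entries
#'   planting `n` productive sequences into each listed sample.
#' @param sharedLength nt length of planted shared sequences (multiple of 3).
#' @param seed mandatory integer seed; every draw of the generator is
#'   reproducible from it.
#' @return a validated list of class `"SimulationConfig"`.
#' @examples
#' cfg <- simulationConfig(seed = 1)
#' @export
simulationConfig <- function(
    nSamples = c(ARDS = 4L, non_ARDS = 3L),
    cloneRange = list(ARDS = c(56L, 1560L), non_ARDS = c(25L, 169L),
                      unlabeled = c(25L, 1560L)),
    lengthRange = list(ARDS = c(21L, 69L), non_ARDS = c(30L, 66L),
                       unlabeled = c(21L, 69L)),
    alpha = 2,
    model = c("dirichlet", "powerlaw"),
    powerlawExponent = 1.5,
    nonproductiveFraction = 0.1,
    depth = c(ARDS = 20000, non_ARDS = 6000, unlabeled = 10000),
    sharedPlan = NULL,
    sharedLength = 42L,
    seed) {
  if (missing(seed)) stop("a seed is mandatory for reproducibility")
  model <- match.arg(model)
  stopifnot(alpha > 0, powerlawExponent > 0,
            nonproductiveFraction >= 0, nonproductiveFraction < 1,
            sharedLength %% 3L == 0L, sharedLength >= 9L)
  for (g in names(lengthRange)) {
    lr <- lengthRange[[g]]
    if (any(lr %% 3L != 0L) || lr[1L] > lr[2L] || lr[1L] < 9L) {
      stop("length bounds for ", g,
           " must be multiples of 3, at least 9, low <= high")
    }
  }
  for (g in names(cloneRange)) {
    cr <- cloneRange[[g]]
    if (cr[1L] < 1L || cr[1L] > cr[2L]) stop("bad clone range for ", g)
  }
  structure(list(nSamples = nSamples, cloneRange = cloneRange,
                 lengthRange = lengthRange, alpha = alpha, model = model,
                 powerlawExponent = powerlawExponent,
                 nonproductiveFraction = nonproductiveFraction,
                 depth = depth, sharedPlan = sharedPlan,
                 sharedLength = as.integer(sharedLength),
                 seed = as.integer(seed)),
            class = "SimulationConfig")
}

## random productive junctions: conserved first codon (Cys: TGT/TGC),
## conserved last codon (Phe: TTT/TTC), sense-codon interior
.randomJunctions <- function(n, lengths, avoid = character()) {
  make <- function(len) {
    k <- len %/% 3L
    paste0(sample(c("TGT", "TGC"), 1L),
           paste(sample(.SENSE_CODONS, k - 2L, replace = TRUE), collapse = ""),
           sample(c("TTT", "TTC"), 1L))
  }
  out <- character(n)
  seen <- avoid
  for (i in seq_len(n)) {
    repeat {
      j <- make(lengths[[i]])
      if (!j %in% seen) break
    }
    out[[i]] <- j
    seen <- c(seen, j)
  }
  out
}

## make a junction nonproductive: frameshift (drop one interior nt) or
## internal stop-codon injection, chosen at random
.breakJunction <- function(nt) {
  if (stats::runif(1) < 0.5) {
    cut <- sample(nchar(nt) - 1L, 1L)
    paste0(substr(nt, 1L, cut - 1L), substr(nt, cut + 1L, nchar(nt)))
  } else {
    k <- nchar(nt) %/% 3L
    pos <- sample(2L:(k - 1L), 1L)
    paste0(substr(nt, 1L, (pos - 1L) * 3L),
           sample(.STOP_CODONS, 1L),
           substr(nt, pos * 3L + 1L, nchar(nt)))
  }
}

#' Simulate one CDR3 repertoire
#'
#' Draws unique in-frame junctions (conserved C...F anchors, sense-codon
#' interiors), assigns clone frequencies from the configured model,
#' realizes them as template counts by multinomial sampling at the
#' configured depth, and converts the configured fraction of clones to
#' nonproductive by frameshift or internal stop injection. Clones drawing
#' zero templates are unobserved and dropped; planted shared sequences are
#' guaranteed at least one template and are always productive.
#'
#' @param config a [simulationConfig()] object.
#' @param sampleId sample label.
#' @param group group label (selects clone-range, length-range and depth
#'   presets).
#' @param nClones unique clone count; drawn from the group's range when
#'   `NULL`.
#' @param plantedSequences character vector of productive nt junctions to
#'   include (used by [simulateCohort()] for the shared-clone plan).
#' @param seed integer seed; `NULL` continues from the current RNG state
#'   (how [simulateCohort()] calls it).
#' @return a [CDR3Repertoire-class] with attribute `truth`: a data.frame
#'   of `cdr3_nt`, `true_frequency`, `productive_truth`, `planted` for
#'   every generated clone (including any that drew zero templates).
#' @examples
#' cfg <- simulationConfig(seed = 7)
#' simulateRepertoire(cfg, "s1", "non_ARDS", nClones = 50, seed = 7)
#' @export
simulateRepertoire <- function(config, sampleId, group = "unlabeled",
                               nClones = NULL, plantedSequences = character(),
                               seed = config$seed) {
  stopifnot(inherits(config, "SimulationConfig"))
  if (!is.null(seed)) set.seed(seed)
  cr <- config$cloneRange[[group]]
  lr <- config$lengthRange[[group]]
  if (is.null(nClones)) {
    nClones <- sample(seq.int(cr[1L], cr[2L]), 1L)
  }
  nPlanted <- length(plantedSequences)
  if (nPlanted > nClones) {
    stop("shared-clone plan exceeds the clone budget of sample ", sampleId)
  }
  nFree <- nClones - nPlanted
  lengths <- sample(seq.int(lr[1L], lr[2L], by = 3L), nFree, replace = TRUE)
  free <- .randomJunctions(nFree, lengths, avoid = plantedSequences)
  nBad <- floor(config$nonproductiveFraction * nClones)
  if (nBad > nFree) stop("nonproductive fraction infeasible with plan size")
  badIdx <- if (nBad > 0L) sample(nFree, nBad) else integer()
  prodTruth <- rep(TRUE, nFree)
  prodTruth[badIdx] <- FALSE
  for (i in badIdx) {
    repeat {
      b <- .breakJunction(free[[i]])
      if (!b %in% free[-i] && !b %in% plantedSequences) break
    }
    free[[i]] <- b
  }
  nt <- c(plantedSequences, free)
  productive <- c(rep(TRUE, nPlanted), prodTruth)
  planted <- c(rep(TRUE, nPlanted), rep(FALSE, nFree))
  p <- switch(config$model,
    dirichlet = {
      g <- stats::rgamma(nClones, shape = config$alpha)
      g / sum(g)
    },
    powerlaw = {
      w <- seq_len(nClones)^(-config$powerlawExponent)
      sample(w / sum(w))
    })
  templates <- as.integer(stats::rmultinom(1L, size = config$depth[[group]],
                                           prob = p))
  templates[planted] <- pmax(templates[planted], 1L)
  truth <- data.frame(cdr3_nt = nt, true_frequency = p,
                      productive_truth = productive, planted = planted)
  obs <- templates > 0L
  rep <- CDR3Repertoire(sampleId, nt[obs], templates[obs], group = group)
  attr(rep, "truth") <- truth
  rep
}

#' Simulate a two-group cohort with a planted sharing pattern
#'
#' Generates one repertoire per sample under the configuration's group
#' presets. Sample ids are `A1..An` for the ARDS-like group and `N1..Nm`
#' for the non-ARDS-like group. The default shared-clone plan (when
#' `config$sharedPlan` is `NULL` and both default group sizes are present)
#' plants 4 productive sequences into three ARDS-like samples (A2, A3, A4)
#' and 1 into a cross-group pair (A3, N3), giving a 5-sequence sharing
#' pattern with known ground truth.
#'
#' @param config a [simulationConfig()] object; `config$seed` drives every
#'   draw.
#' @return list with `cohort` (a [CDR3Cohort-class]) and `truth` (list:
#'   `shared` data.frame of planted sequences and their sample sets,
#'   `perSample` list of per-repertoire truth tables as in
#'   [simulateRepertoire()]).
#' @examples
#' sim <- simulateCohort(simulationConfig(seed = 42))
#' sim$cohort
#' @export
simulateCohort <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  ids <- unlist(lapply(names(config$nSamples), function(g) {
    prefix <- if (g == "ARDS") "A" else if (g == "non_ARDS") "N" else "U"
    sprintf("%s%d", prefix, seq_len(config$nSamples[[g]]))
  }))
  groups <- rep(names(config$nSamples), config$nSamples)
  names(groups) <- ids
  plan <- config$sharedPlan
  if (is.null(plan) && all(c("A4", "N3") %in% ids)) {
    plan <- list(list(n = 4L, samples = c("A2", "A3", "A4")),
                 list(n = 1L, samples = c("A3", "N3")))
  }
  planted <- stats::setNames(vector("list", length(ids)), ids)
  sharedTruth <- NULL
  if (!is.null(plan)) {
    unknown <- setdiff(unlist(lapply(plan, `[[`, "samples")), ids)
    if (length(unknown)) {
      stop("shared plan names unknown sample(s): ",
           paste(unknown, collapse = ", "))
    }
    all_shared <- character()
    for (entry in plan) {
      seqs <- .randomJunctions(entry$n,
                               rep(config$sharedLength, entry$n),
                               avoid = all_shared)
      all_shared <- c(all_shared, seqs)
      for (s in entry$samples) planted[[s]] <- c(planted[[s]], seqs)
      sharedTruth <- rbind(sharedTruth, data.frame(
        cdr3_nt = seqs,
        cdr3_aa = translateCdr3(seqs)$cdr3_aa,
        samples = paste(sort(entry$samples), collapse = ","),
        groups = paste(sort(unique(groups[entry$samples])), collapse = ",")))
    }
  }
  reps <- lapply(ids, function(s)
    simulateRepertoire(config, s, groups[[s]],
                       plantedSequences = planted[[s]], seed = NULL))
  names(reps) <- ids
  cohort <- CDR3Cohort(reps, provenance = sprintf(
    "synthetic cohort (model %s, alpha %g, seed %d)",
    config$model, config$alpha, config$seed))
  list(cohort = cohort,
       truth = list(shared = sharedTruth,
                    perSample = lapply(reps, attr, "truth")))
}

#' Export a cohort as rearrangement + metadata TSV
#'
#' Writes one dialect-valid rearrangement table covering every sample, and
#' a two-column sample metadata file, the same formats
#' [readRearrangements()] consumes.
#'
#' @param cohort a [CDR3Cohort-class].
#' @param dir output directory (created if needed).
#' @param dialect `"immunoseq"` or `"airr"` column names.
#' @return named character vector of the two file paths.
#' @export
exportCohort <- function(cohort, dir, dialect = c("immunoseq", "airr")) {
  dialect <- match.arg(dialect)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- do.call(rbind, lapply(as.list(repertoires(cohort)), function(rep) {
    df <- rearrangements(translateRepertoire(rep, verbose = FALSE))
    status <- ifelse(!df$in_frame, "out_of_frame",
                     ifelse(df$has_stop, "stop", "in_frame"))
    data.frame(cdr3_nt = df$cdr3_nt, cdr3_aa = df$cdr3_aa,
               templates = df$templates, status = status,
               productive = df$productive,
               sample_id = sampleId(rep), group = groupLabel(rep))
  }))
  tab <- if (dialect == "immunoseq") {
    data.frame(rearrangement = rows$cdr3_nt, amino_acid = rows$cdr3_aa,
               templates = rows$templates,
               frame_type = c(in_frame = "In", out_of_frame = "Out",
                              stop = "Stop")[rows$status],
               sample_id = rows$sample_id)
  } else {
    data.frame(junction = rows$cdr3_nt, junction_aa = rows$cdr3_aa,
               duplicate_count = rows$templates,
               productive = ifelse(rows$productive, "T", "F"),
               vj_in_frame = ifelse(rows$status != "out_of_frame", "T", "F"),
               stop_codon = ifelse(rows$status == "stop", "T", "F"),
               sample_id = rows$sample_id)
  }
  rePath <- file.path(dir, sprintf("rearrangements_%s.tsv", dialect))
  mdPath <- file.path(dir, "sample_metadata.tsv")
  utils::write.table(tab, rePath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  md <- unique(rows[, c("sample_id", "group")])
  utils::write.table(md, mdPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  c(rearrangements = rePath, metadata = mdPath)
}

#' Write simulation ground truth as JSON
#'
#' @param truth the `truth` element returned by [simulateCohort()].
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
writeSimulationTruth <- function(truth, path) {
  jsonlite::write_json(truth, path, dataframe = "columns", digits = NA,
                       auto_unbox = TRUE, null = "null")
  invisible(path)
}
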