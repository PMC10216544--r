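#' Per-sample length-distribution plot
#'
#' Grouped per-sample bars of the sum productive frequency at each CDR3
#' length, faceted by clinical group.
#'
#' @param cohort a [CDR3Cohort-class].
#' @param scale `"nt"` or `"aa"`.
#' @return a ggplot object.
#' @export
plotLengthDistribution <- function(cohort, scale = c("nt", "aa")) {
  scale <- match.arg(scale)
  tab <- cohortLengthTable(cohort, scale)
  ggplot2::ggplot(tab, ggplot2::aes(
      x = factor(.data$length), y = 100 * .data$frequency,
      fill = .data$sample_id)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(preserve = "single")) +
    ggplot2::facet_wrap(~group, ncol = 1L, scales = "free_y") +
    ggplot2::labs(x = sprintf("CDR3 length (%s)", scale),
                  y = "sum productive frequency (%)", fill = "sample") +
    ggplot2::theme_bw()
}

#' Simpson clonality bar chart across samples
#'
#' @param clonality data.frame from [cohortClonality()].
#' @return a ggplot object.
#' @export
plotClonality <- function(clonality) {
  ggplot2::ggplot(clonality, ggplot2::aes(
      x = stats::reorder(.data$sample_id, -.data$clonality),
      y = .data$clonality, fill = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "sample", y = "Simpson clonality", fill = "group") +
    ggplot2::theme_bw()
}

#' Run the full repertoire characterization and write a report bundle
#'
#' Orchestrates every analysis stage over a cohort: translation and
#' productivity classification, length distributions and moment summaries,
#' per-sequence isoelectric points, residue-property composition, Simpson
#' clonality, immunogenicity scoring, cross-sample clonotype sharing, and
#' the pairwise clone-frequency rank comparison. Each stage writes a tidy
#' TSV under `outDir`; a combined per-sample summary (unique sequences,
#' positive immunogenicity counts and percentage, clonality, mean pI),
#' length and clonality figures (PDF), a MANIFEST of produced files and a
#' run log with package version and parameters complete the bundle. A
#' stage failure aborts with the stage name; files already written are
#' retained and the MANIFEST records the run as incomplete.
#'
#' @param cohort a [CDR3Cohort-class].
#' @param outDir output directory (created).
#' @param stages character subset of
#'   `c("lengths", "pi", "composition", "clonality", "immunogenicity",
#'   "sharing", "compare")`; toggled-off stages are skipped and their
#'   columns omitted from the combined summary.
#' @param model an [ImmunogenicityModel-class].
#' @param pka pKa table for [isoelectricPoint()].
#' @param figures write PDF figures (default `TRUE`).
#' @return `outDir`, invisibly; side effect: the report bundle.
#' @examples
#' sim <- simulateCohort(simulationConfig(
#'   nSamples = c(ARDS = 2L, non_ARDS = 2L),
#'   cloneRange = list(ARDS = c(30L, 40L), non_ARDS = c(25L, 30L)),
#'   seed = 11))
#' out <- runReport(sim$cohort, tempfile("report"), figures = FALSE)
#' list.files(out)
#' @export
runReport <- function(cohort, outDir,
                      stages = c("lengths", "pi", "composition", "clonality",
                                 "immunogenicity", "sharing", "compare"),
                      model = defaultImmunogenicityModel(),
                      pka = defaultPkaTable(), figures = TRUE) {
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  manifest <- file.path(outDir, "MANIFEST")
  emit <- function(df, name) {
    p <- file.path(outDir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    written <<- c(written, name)
    p
  }
  fail <- function(stage, sample, err) {
    writeLines(c("status: INCOMPLETE",
                 sprintf("failed stage: %s (%s)", stage, sample),
                 "files:", written), manifest)
    stop(sprintf("stage '%s' failed for %s: %s", stage, sample,
                 conditionMessage(err)), call. = FALSE)
  }
  run <- function(stage, sample = "cohort", expr) {
    tryCatch(expr, error = function(e) fail(stage, sample, e))
  }

  cohort <- run("translate", expr = translateRepertoire(cohort,
                                                        verbose = FALSE))
  perSample <- data.frame(sample_id = sampleIds(cohort),
                          group = unname(groupLabels(cohort)))
  perSample$unique_rearrangements <- vapply(
    as.list(repertoires(cohort)),
    function(r) nrow(rearrangements(r)), integer(1))
  perSample$productive_rearrangements <- vapply(
    as.list(repertoires(cohort)),
    function(r) sum(rearrangements(r)$productive), integer(1))

  if ("lengths" %in% stages) {
    run("lengths", expr = {
      tab <- cohortLengthTable(cohort, "nt")
      emit(tab, "length_distribution_nt.tsv")
      emit(cohortLengthTable(cohort, "aa"), "length_distribution_aa.tsv")
      moments <- do.call(rbind, lapply(as.list(repertoires(cohort)),
        function(r) {
          d <- lengthDistribution(r, "nt")
          if (!nrow(d)) return(NULL)
          cbind(sample_id = sampleId(r), suppressWarnings(lengthSummary(d)))
        }))
      emit(moments, "length_summary_nt.tsv")
      if (figures) {
        p <- file.path(outDir, "length_distribution.pdf")
        ggplot2::ggsave(p, plotLengthDistribution(cohort, "nt"),
                        width = 8, height = 6)
        written <- c(written, basename(p))
      }
    })
  }
  if ("pi" %in% stages) {
    run("pi", expr = {
      pi <- cohortIsoelectricPoints(cohort, pka = pka)
      emit(pi, "isoelectric_points.tsv")
      agg <- stats::aggregate(pI ~ sample_id, pi, mean)
      perSample$mean_pI <- agg$pI[match(perSample$sample_id, agg$sample_id)]
    })
  }
  if ("composition" %in% stages) {
    run("composition",
        expr = emit(cohortComposition(cohort), "residue_composition.tsv"))
  }
  if ("clonality" %in% stages) {
    run("clonality", expr = {
      cl <- cohortClonality(cohort)
      emit(cl, "clonality.tsv")
      perSample$clonality <- cl$clonality[match(perSample$sample_id,
                                                 cl$sample_id)]
      if (figures) {
        p <- file.path(outDir, "clonality.pdf")
        ggplot2::ggsave(p, plotClonality(cl), width = 6, height = 4)
        written <- c(written, basename(p))
      }
    })
  }
  if ("immunogenicity" %in% stages) {
    run("immunogenicity", expr = {
      im <- cohortImmunogenicity(cohort, model = model)
      emit(im$scores, "immunogenicity_scores.tsv")
      emit(im$summary, "immunogenicity_summary.tsv")
      i <- match(perSample$sample_id, im$summary$sample_id)
      perSample$positive_scoring <- im$summary$positive_count[i]
      perSample$percent_positive <- im$summary$percent_positive[i]
    })
  }
  if ("sharing" %in% stages) {
    run("sharing", expr = {
      sh <- sharedClones(cohort)
      emit(sh, "shared_clones.tsv")
      lens <- nchar(sh$sequence)
      if (nrow(sh) >= 2L && length(unique(lens)) == 1L) {
        writeLines(alignmentBlock(sh$sequence, sh$samples),
                   file.path(outDir, "shared_alignment.txt"))
        written <- c(written, "shared_alignment.txt")
      }
    })
  }
  if ("compare" %in% stages) {
    run("compare",
        expr = emit(cloneFrequencyComparison(cohort),
                    "clone_frequency_dunns.tsv"))
  }
  emit(perSample, "cohort_summary.tsv")
  writeLines(c(
    sprintf("cdr3profiler %s", as.character(utils::packageVersion("cdr3profiler"))),
    sprintf("date: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf("samples: %s", paste(sampleIds(cohort), collapse = ", ")),
    sprintf("stages: %s", paste(stages, collapse = ", "))),
    file.path(outDir, "run_log.txt"))
  written <- c(written, "run_log.txt")
  writeLines(c("status: COMPLETE", "files:", written), manifest)
  invisible(outDir)
}
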