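#' Accessors for CDR3 containers
#'
#' `sampleId()`, `groupLabel()` and `rearrangements()` read the slots of a
#' [CDR3Repertoire-class]; `repertoires()`, `sampleIds()` and `groupLabels()`
#' read a [CDR3Cohort-class]. `x[[i]]` extracts one repertoire from a cohort
#' by index or sample id, and `length(x)` gives the number of samples.
#'
#' @param x a [CDR3Repertoire-class] or [CDR3Cohort-class].
#' @return the corresponding slot value (see each accessor).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("sampleId", "CDR3Repertoire", function(x) x@sampleId)

#' @rdname accessors
#' @export
setMethod("groupLabel", "CDR3Repertoire", function(x) x@group)

#' @rdname accessors
#' @export
setMethod("rearrangements", "CDR3Repertoire", function(x) x@rearrangements)

#' @rdname accessors
#' @export
setMethod("repertoires", "CDR3Cohort", function(x) x@repertoires)

#' @rdname accessors
#' @export
setMethod("sampleIds", "CDR3Cohort", function(x)
  unname(vapply(x@repertoires, sampleId, character(1))))

#' @rdname accessors
#' @export
setMethod("groupLabels", "CDR3Cohort", function(x) {
  g <- vapply(x@repertoires, groupLabel, character(1))
  names(g) <- sampleIds(x)
  g
})

#' @rdname accessors
#' @param i index or sample id.
#' @export
setMethod("[[", "CDR3Cohort", function(x, i) x@repertoires[[i]])

#' @rdname accessors
#' @export
setMethod("length", "CDR3Cohort", function(x) length(x@repertoires))

setMethod("show", "CDR3Repertoire", function(object) {
  df <- object@rearrangements
  cat(sprintf("CDR3Repertoire '%s' (%s): %d unique rearrangement(s), %d template(s)\n",
              object@sampleId, object@group, nrow(df),
              if (nrow(df)) sum(df$templates) else 0L))
  if ("productive" %in% colnames(df)) {
    cat(sprintf("  productive: %d of %d\n",
                sum(df$productive, na.rm = TRUE), nrow(df)))
  } else {
    cat("  not yet translated (run translateRepertoire())\n")
  }
})

setMethod("show", "CDR3Cohort", function(object) {
  g <- vapply(object@repertoires, groupLabel, character(1))
  n <- vapply(object@repertoires,
              function(r) nrow(r@rearrangements), integer(1))
  cat(sprintf("CDR3Cohort: %d sample(s) [%s]\n", length(object@repertoires),
              paste(sprintf("%s=%d", names(table(g)), table(g)),
                    collapse = ", ")))
  cat(sprintf("  unique rearrangements per sample: %s (total %d)\n",
              paste(n, collapse = ", "), sum(n)))
  if (length(object@provenance)) {
    cat("  provenance:", object@provenance[1L], "\n")
  }
})
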