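#' Accessors for pgxfreq classes
#'
#' \code{doses} returns the loci x individuals alt-allele dose matrix of a
#' \linkS4class{PgxCohort}; \code{variantInfo} its variant annotation;
#' \code{cohortStrata} its per-individual stratum table. \code{panelFreqs}
#' and \code{populationLabels} expose a \linkS4class{ReferencePanel};
#' \code{trueAncestry} the ground-truth ancestry matrix of a
#' \linkS4class{SimulatedCohort}.
#'
#' @param x a pgxfreq object.
#' @name pgxfreq-accessors
NULL

#' @rdname pgxfreq-accessors
#' @export
setGeneric("doses", function(x) standardGeneric("doses"))

#' @rdname pgxfreq-accessors
#' @export
setGeneric("variantInfo", function(x) standardGeneric("variantInfo"))

#' @rdname pgxfreq-accessors
#' @export
setGeneric("cohortStrata", function(x) standardGeneric("cohortStrata"))

#' @rdname pgxfreq-accessors
#' @export
setGeneric("panelFreqs", function(x) standardGeneric("panelFreqs"))

#' @rdname pgxfreq-accessors
#' @export
setGeneric("populationLabels", function(x) standardGeneric("populationLabels"))

#' @rdname pgxfreq-accessors
#' @export
setGeneric("trueAncestry", function(x) standardGeneric("trueAncestry"))

#' @rdname pgxfreq-accessors
#' @export
setMethod("doses", "PgxCohort", function(x) assay(x, "dose"))

#' @rdname pgxfreq-accessors
#' @export
setMethod("variantInfo", "PgxCohort",
          function(x) as.data.frame(rowData(x)))

#' @rdname pgxfreq-accessors
#' @export
setMethod("cohortStrata", "PgxCohort",
          function(x) as.data.frame(colData(x)))

#' @rdname pgxfreq-accessors
#' @export
setMethod("panelFreqs", "ReferencePanel", function(x) x@freqs)

#' @rdname pgxfreq-accessors
#' @export
setMethod("populationLabels", "ReferencePanel", function(x) colnames(x@freqs))

#' @rdname pgxfreq-accessors
#' @export
setMethod("doses", "SimulatedCohort", function(x) doses(x@cohort))

#' @rdname pgxfreq-accessors
#' @export
setMethod("cohortStrata", "SimulatedCohort", function(x) cohortStrata(x@cohort))

#' @rdname pgxfreq-accessors
#' @export
setMethod("trueAncestry", "SimulatedCohort", function(x) x@trueQ)

#' @describeIn pgxfreq-accessors the generated PgxCohort inside a
#'   SimulatedCohort.
#' @export
setGeneric("simCohort", function(x) standardGeneric("simCohort"))

#' @rdname pgxfreq-accessors
#' @export
setMethod("simCohort", "SimulatedCohort", function(x) x@cohort)

#' @rdname pgxfreq-accessors
#' @export
setMethod("panelFreqs", "SimulatedCohort", function(x) panelFreqs(x@panel))

setMethod("show", "PgxCohort", function(object) {
    cat("PgxCohort:", nrow(object), "loci x", ncol(object), "individuals\n")
    d <- assay(object, "dose")
    cat(sprintf("  missing calls: %.2f%%\n", 100 * mean(is.na(d))))
    sv <- colnames(colData(object))
    if (length(sv))
        cat("  strata:", paste(sv, collapse = ", "), "\n")
})

setMethod("show", "ReferencePanel", function(object) {
    cat("ReferencePanel:", nrow(object@freqs), "loci x",
        ncol(object@freqs), "populations (",
        paste(colnames(object@freqs), collapse = ", "), ")\n")
})

setMethod("show", "SimulatedCohort", function(object) {
    cat("SimulatedCohort (seed", object@config@seed, ")\n")
    show(object@cohort)
})

setMethod("show", "FstProfile", function(object) {
    cat("FstProfile", object@label, ":", nrow(object@results), "loci\n")
    cat(sprintf("  mean FST %.4f (SD %.4f)\n", object@meanFst, object@sdFst))
    cc <- object@categoryCounts
    cat("  ", paste(names(cc), cc, sep = "=", collapse = "  "), "\n")
    if (object@nDropped > 0)
        cat("  dropped (missing frequency):", object@nDropped, "\n")
})

#' Coerce an FstProfile to a per-locus data.frame
#'
#' @param x an \linkS4class{FstProfile}.
#' @param ... ignored.
#' @return data.frame with columns \code{rsid}, \code{p1}, \code{p2},
#'   \code{fst}, \code{category}, \code{monomorphic}.
#' @export
as.data.frame.FstProfile <- function(x, ...) x@results

#' @rdname pgxfreq-accessors
#' @export
setGeneric("meanFst", function(x) standardGeneric("meanFst"))

#' @rdname pgxfreq-accessors
#' @export
setMethod("meanFst", "FstProfile", function(x) x@meanFst)

#' @rdname pgxfreq-accessors
#' @export
setGeneric("sdFst", function(x) standardGeneric("sdFst"))

#' @rdname pgxfreq-accessors
#' @export
setMethod("sdFst", "FstProfile", function(x) x@sdFst)

#' @rdname pgxfreq-accessors
#' @export
setGeneric("categoryCounts", function(x) standardGeneric("categoryCounts"))

#' @rdname pgxfreq-accessors
#' @export
setMethod("categoryCounts", "FstProfile", function(x) x@categoryCounts)
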