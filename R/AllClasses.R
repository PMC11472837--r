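#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData colData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' PgxCohort: a genotyped cohort with per-sample strata
#'
#' An S4 container for a biallelic genotype matrix, built on
#' \linkS4class{SummarizedExperiment}. The single assay \code{"dose"} holds
#' alt-allele doses (0, 1, 2 or \code{NA} for a missing call) with variants as
#' rows and individuals as columns. \code{rowData} carries the variant
#' annotation (\code{rsid}, \code{gene}, \code{ref_allele}, \code{alt_allele},
#' \code{note}); \code{colData} carries per-individual stratum labels such as
#' skin-color category and birth region.
#'
#' @slot .  Inherits all slots from \code{SummarizedExperiment}.
#' @export
setClass("PgxCohort", contains = "SummarizedExperiment")

setValidity("PgxCohort", function(object) {
    msg <- character()
    if (!"dose" %in% names(assays(object)))
        msg <- c(msg, "assay 'dose' is required")
    else {
        d <- assay(object, "dose")
        bad <- !is.na(d) & !(d %in% c(0, 1, 2))
        if (any(bad))
            msg <- c(msg, "doses must be 0, 1, 2 or NA")
    }
    rd <- rowData(object)
    need <- c("rsid", "ref_allele", "alt_allele")
    miss <- setdiff(need, colnames(rd))
    if (length(miss))
        msg <- c(msg, paste0("rowData lacks column(s): ",
                             paste(miss, collapse = ", ")))
    else {
        if (anyDuplicated(rd$rsid))
            msg <- c(msg, "rsid values must be unique")
        same <- !is.na(rd$ref_allele) & !is.na(rd$alt_allele) &
            rd$ref_allele == rd$alt_allele
        if (any(same))
            msg <- c(msg, "ref and alt allele must differ")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a PgxCohort
#'
#' @param doses numeric matrix of alt-allele doses, loci in rows, individuals
#'   in columns; entries 0/1/2 or \code{NA}.
#' @param variants data.frame with one row per locus: columns \code{rsid},
#'   \code{ref_allele}, \code{alt_allele}; optionally \code{gene} and
#'   \code{note}.
#' @param strata data.frame with one row per individual (stratum labels,
#'   e.g. \code{skin_color}, \code{region}). May be \code{NULL}.
#' @return a \linkS4class{PgxCohort}.
#' @examples
#' v <- data.frame(rsid = c("rs1", "rs2"), ref_allele = "A", alt_allele = "G")
#' d <- matrix(c(0, 2, 1, 1, 2, 0), nrow = 2,
#'             dimnames = list(v$rsid, paste0("S", 1:3)))
#' PgxCohort(d, v, data.frame(skin_color = c("white", "black", "admixed")))
#' @export
PgxCohort <- function(doses, variants, strata = NULL) {
    doses <- as.matrix(doses)
    variants <- as.data.frame(variants)
    if (!"gene" %in% colnames(variants)) variants$gene <- NA_character_
    if (!"note" %in% colnames(variants)) variants$note <- NA_character_
    if (nrow(variants) != nrow(doses))
        stop("variant table and dose matrix disagree on locus count")
    rownames(doses) <- variants$rsid
    if (is.null(colnames(doses)))
        colnames(doses) <- paste0("sample_", seq_len(ncol(doses)))
    if (is.null(strata))
        strata <- data.frame(row.names = colnames(doses))
    if (nrow(strata) != ncol(doses))
        stop("strata table and dose matrix disagree on individual count")
    rownames(strata) <- colnames(doses)
    se <- SummarizedExperiment(
        assays = list(dose = doses),
        rowData = DataFrame(variants, row.names = variants$rsid),
        colData = DataFrame(strata))
    new("PgxCohort", se)
}

#' ReferencePanel: fixed allele frequencies of K ancestral populations
#'
#' Alt-allele frequencies of L loci in K reference (ancestral) populations,
#' used as the fixed parameters of supervised admixture estimation.
#' Frequencies are clamped away from 0 and 1 by \code{eps} so that every
#' genotype retains positive likelihood under every ancestry.
#'
#' @slot freqs numeric L x K matrix of alt-allele frequencies; rows are loci
#'   (rownames = rsids), columns are populations (colnames = labels).
#' @slot eps clamping bound applied to the frequencies.
#' @export
setClass("ReferencePanel",
         representation(freqs = "matrix", eps = "numeric"))

setValidity("ReferencePanel", function(object) {
    f <- object@freqs
    if (!is.numeric(f) || ncol(f) < 1L || nrow(f) < 1L)
        return("freqs must be a numeric matrix with >= 1 locus and population")
    if (any(is.na(f)))
        return("panel frequencies must not be missing")
    if (any(f <= 0) || any(f >= 1))
        return("panel frequencies must lie strictly inside (0, 1) after clamping")
    TRUE
})

#' Construct a ReferencePanel
#'
#' @param freqs numeric L x K matrix of alt-allele frequencies (loci in rows,
#'   populations in columns). Values are clamped into
#'   \code{[eps, 1 - eps]}.
#' @param labels optional character vector of K population names (defaults to
#'   existing colnames or \code{pop1..popK}).
#' @param eps clamping bound (default \code{1e-6}).
#' @return a \linkS4class{ReferencePanel}.
#' @examples
#' referencePanel(matrix(c(0.9, 0.1, 0.8, 0.2), nrow = 2),
#'                labels = c("EUR", "AFR"))
#' @export
referencePanel <- function(freqs, labels = NULL, eps = 1e-6) {
    freqs <- as.matrix(freqs)
    if (is.null(labels))
        labels <- colnames(freqs)
    if (is.null(labels))
        labels <- paste0("pop", seq_len(ncol(freqs)))
    colnames(freqs) <- labels
    if (is.null(rownames(freqs)))
        rownames(freqs) <- paste0("locus_", seq_len(nrow(freqs)))
    freqs <- pmin(pmax(freqs, eps), 1 - eps)
    new("ReferencePanel", freqs = freqs, eps = eps)
}

#' CohortConfig: full specification of a simulated admixed cohort
#'
#' @slot strata data.frame with columns \code{label} and \code{n}.
#' @slot alphas numeric S x K matrix of per-stratum Dirichlet parameters.
#' @slot panel a \linkS4class{ReferencePanel}.
#' @slot nullGeneProbs numeric(2) deletion probabilities for two unlinked
#'   null-genotype genes, or numeric(0) to skip.
#' @slot seed master integer seed; child seeds for each generation stage are
#'   derived from it.
#' @export
setClass("CohortConfig",
         representation(strata = "data.frame", alphas = "matrix",
                        panel = "ReferencePanel", nullGeneProbs = "numeric",
                        seed = "integer"))

setValidity("CohortConfig", function(object) {
    msg <- character()
    if (!all(c("label", "n") %in% colnames(object@strata)))
        msg <- c(msg, "strata needs columns 'label' and 'n'")
    else if (any(object@strata$n <= 0))
        msg <- c(msg, "all stratum sizes must be positive")
    if (nrow(object@alphas) != nrow(object@strata))
        msg <- c(msg, "one alpha row per stratum required")
    if (any(object@alphas <= 0))
        msg <- c(msg, "all Dirichlet alphas must be positive")
    if (ncol(object@alphas) != ncol(object@panel@freqs))
        msg <- c(msg, "alpha columns must match panel populations")
    if (length(object@nullGeneProbs) %in% c(0L, 2L)) {
        if (length(object@nullGeneProbs) == 2L &&
            (any(object@nullGeneProbs < 0) || any(object@nullGeneProbs > 1)))
            msg <- c(msg, "null-gene probabilities must lie in [0, 1]")
    } else msg <- c(msg, "nullGeneProbs must have length 0 or 2")
    if (length(object@seed) != 1L || is.na(object@seed))
        msg <- c(msg, "a single integer seed is mandatory")
    if (length(msg)) msg else TRUE
})

#' SimulatedCohort: a generated cohort together with its ground truth
#'
#' @slot cohort the generated \linkS4class{PgxCohort}.
#' @slot trueQ numeric n x K matrix of the true per-individual ancestry
#'   proportions the genotypes were drawn from.
#' @slot panel the \linkS4class{ReferencePanel} used.
#' @slot config the generating \linkS4class{CohortConfig} (echo).
#' @export
setClass("SimulatedCohort",
         representation(cohort = "PgxCohort", trueQ = "matrix",
                        panel = "ReferencePanel", config = "CohortConfig"))

#' FstProfile: per-locus pairwise FST for one population comparison
#'
#' @slot label comparison label, e.g. \code{"Cuba_vs_Africa"}.
#' @slot results data.frame with columns \code{rsid}, \code{p1}, \code{p2},
#'   \code{fst}, \code{category}, \code{monomorphic}.
#' @slot meanFst unweighted mean FST across loci.
#' @slot sdFst sample (n - 1) standard deviation across loci.
#' @slot categoryCounts named integer(4): loci per divergence class.
#' @slot nDropped loci dropped because a frequency was missing.
#' @export
setClass("FstProfile",
         representation(label = "character", results = "data.frame",
                        meanFst = "numeric", sdFst = "numeric",
                        categoryCounts = "integer", nDropped = "integer"))

setValidity("FstProfile", function(object) {
    if (sum(object@categoryCounts) != nrow(object@results))
        return("category counts must sum to the number of profiled loci")
    TRUE
})
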