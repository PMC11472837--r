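#' Alt-allele frequency with a binomial confidence interval
#'
#' Estimates the alternative-allele frequency from a genotype-count triple as
#' (het + 2 * alt-hom) / (2n) and attaches a 95\% confidence interval. The
#' default Wilson score interval stays inside [0, 1] and behaves well at
#' small counts; the Wald interval is offered for comparison with published
#' tables whose interval construction is unstated.
#'
#' @param counts named vector as returned by \code{\link{reconstructCounts}}
#'   (or any numeric with \code{n_ref_hom}, \code{n_het}, \code{n_alt_hom}),
#'   or an unnamed length-3 vector (ref-hom, het, alt-hom).
#' @param ciMethod \code{"wilson"} (default) or \code{"wald"}.
#' @param conf confidence level (default 0.95).
#' @return named list: \code{p_alt}, \code{ci_low}, \code{ci_high},
#'   \code{ci_method}, \code{n_alleles}.
#' @examples
#' alleleFreq(c(289, 64, 4))  # p_alt ~ 0.1008
#' @export
alleleFreq <- function(counts, ciMethod = c("wilson", "wald"), conf = 0.95) {
    ciMethod <- match.arg(ciMethod)
    cts <- .asCounts(counts)
    n <- sum(cts)
    if (n == 0) stop("cohort size must be positive")
    m <- 2L * n                       # allele draws
    x <- cts[2L] + 2L * cts[3L]       # alt-allele copies
    p <- x / m
    z <- stats::qnorm(1 - (1 - conf) / 2)
    if (ciMethod == "wilson") {
        centre <- (p + z^2 / (2 * m)) / (1 + z^2 / m)
        half <- z * sqrt(p * (1 - p) / m + z^2 / (4 * m^2)) / (1 + z^2 / m)
        lo <- max(0, centre - half)
        hi <- min(1, centre + half)
    } else {
        half <- z * sqrt(p * (1 - p) / m)
        lo <- p - half
        hi <- p + half
    }
    list(p_alt = unname(p), ci_low = unname(lo), ci_high = unname(hi),
         ci_method = ciMethod, n_alleles = unname(m))
}

.asCounts <- function(counts) {
    if (!is.null(names(counts)) &&
        all(c("n_ref_hom", "n_het", "n_alt_hom") %in% names(counts)))
        cts <- as.numeric(counts[c("n_ref_hom", "n_het", "n_alt_hom")])
    else if (length(counts) >= 3L)
        cts <- as.numeric(counts[1:3])
    else stop("counts must supply (ref-hom, het, alt-hom)")
    if (any(cts < 0) || any(cts != round(cts)))
        stop("genotype counts must be non-negative integers")
    cts
}

#' Alt-allele frequency implied by published genotype frequencies
#'
#' For a published (ref-hom, het, alt-hom) frequency triple the implied
#' alternative-allele frequency is f_het / 2 + f_alt_hom; no cohort size is
#' needed. Operates on whole frequency tables.
#'
#' @param records data.frame with columns \code{f_het} and \code{f_alt_hom}
#'   (e.g. from \code{\link{readFrequencyTable}}).
#' @return numeric vector of implied alt-allele frequencies, named by rsid
#'   when available.
#' @export
impliedAltFreq <- function(records) {
    p <- records$f_het / 2 + records$f_alt_hom
    if (!is.null(records$rsid)) names(p) <- records$rsid
    p
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom asymptotic chi-square test of observed genotype
#' counts against the Hardy-Weinberg expectation n * (q^2, 2pq, p^2), with p
#' estimated from the same counts and no continuity correction. A
#' monomorphic locus (p = 0 or 1) has no testable departure and returns a
#' flagged degenerate result (chi2 = 0, p = 1) instead of erroring, so
#' whole-table scans never abort.
#'
#' @param counts genotype counts as in \code{\link{alleleFreq}}.
#' @return named list: \code{chi2}, \code{df}, \code{p_value},
#'   \code{expected} (length-3), \code{monomorphic}.
#' @examples
#' hweChisq(c(289, 64, 4))$p_value  # ~0.83
#' @export
hweChisq <- function(counts) {
    cts <- .asCounts(counts)
    n <- sum(cts)
    if (n == 0) stop("cohort size must be positive")
    p <- (cts[2L] + 2 * cts[3L]) / (2 * n)
    q <- 1 - p
    if (p == 0 || p == 1)
        return(list(chi2 = 0, df = 1L, p_value = 1,
                    expected = cts, monomorphic = TRUE))
    expd <- n * c(q^2, 2 * p * q, p^2)
    chi2 <- sum((cts - expd)^2 / expd)
    list(chi2 = chi2, df = 1L,
         p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
         expected = expd, monomorphic = FALSE)
}

#' Range of population heterozygosity across a variant table
#'
#' @param records data.frame with columns \code{f_het} and \code{rsid}.
#' @return named list: \code{min_het}, \code{max_het}, \code{min_locus},
#'   \code{max_locus}. Ties resolve to the first row in table order.
#' @export
heterozygositySummary <- function(records) {
    if (NROW(records) == 0) stop("empty variant table")
    i <- which.min(records$f_het)
    j <- which.max(records$f_het)
    list(min_het = records$f_het[i], max_het = records$f_het[j],
         min_locus = records$rsid[i], max_locus = records$rsid[j])
}

#' Null-genotype (whole-gene deletion) frequencies
#'
#' Summarizes per-individual presence calls for two deletion-polymorphic
#' genes (e.g. GSTM1 and GSTT1, where a null genotype is the homozygous
#' deletion detected as absence of amplification) into the frequency of each
#' null genotype and of the concomitant double deletion.
#'
#' @param presentA,presentB logical vectors, one entry per individual:
#'   \code{TRUE} when the gene is present (amplifies), \code{FALSE} for the
#'   null genotype.
#' @return named list: \code{f_null_A}, \code{f_null_B}, \code{f_concomitant}.
#' @export
nullGenotypeSummary <- function(presentA, presentB) {
    if (length(presentA) == 0 || length(presentA) != length(presentB))
        stop("presence calls must be non-empty and of equal length")
    list(f_null_A = mean(!presentA),
         f_null_B = mean(!presentB),
         f_concomitant = mean(!presentA & !presentB))
}

#' Per-locus genotype counts of a cohort
#'
#' Missing calls are excluded per locus, so each locus carries its own
#' effective sample size.
#'
#' @param cohort a \linkS4class{PgxCohort}.
#' @param samples optional logical or index vector selecting individuals.
#' @return data.frame: \code{rsid}, \code{n_ref_hom}, \code{n_het},
#'   \code{n_alt_hom}, \code{n}.
#' @export
genotypeCounts <- function(cohort, samples = NULL) {
    d <- doses(cohort)
    if (!is.null(samples)) d <- d[, samples, drop = FALSE]
    cnt <- function(k) rowSums(d == k, na.rm = TRUE)
    out <- data.frame(rsid = rownames(d),
                      n_ref_hom = cnt(0), n_het = cnt(1), n_alt_hom = cnt(2),
                      row.names = NULL)
    out$n <- out$n_ref_hom + out$n_het + out$n_alt_hom
    out
}

#' Full per-locus frequency/HWE table for a cohort
#'
#' Computes, per locus: genotype frequencies, alt-allele frequency with its
#' confidence interval, and the HWE chi-square p-value. The output matches
#' the column schema of \code{\link{readFrequencyTable}}, so simulated
#' cohorts can be summarized in the same shape as published tables.
#'
#' @param cohort a \linkS4class{PgxCohort}.
#' @param ciMethod passed to \code{\link{alleleFreq}}.
#' @param samples optional selection of individuals.
#' @return data.frame with columns \code{rsid gene ref alt f_ref_hom f_het
#'   f_alt_hom p_alt ci_low ci_high hwe_p n}.
#' @export
cohortFrequencyTable <- function(cohort, ciMethod = "wilson", samples = NULL) {
    cts <- genotypeCounts(cohort, samples)
    v <- variantInfo(cohort)
    rows <- lapply(seq_len(nrow(cts)), function(i) {
        tri <- as.numeric(cts[i, c("n_ref_hom", "n_het", "n_alt_hom")])
        if (sum(tri) == 0)
            return(data.frame(f_ref_hom = NA, f_het = NA, f_alt_hom = NA,
                              p_alt = NA, ci_low = NA, ci_high = NA,
                              hwe_p = NA))
        af <- alleleFreq(tri, ciMethod = ciMethod)
        hw <- hweChisq(tri)
        data.frame(f_ref_hom = tri[1] / sum(tri), f_het = tri[2] / sum(tri),
                   f_alt_hom = tri[3] / sum(tri), p_alt = af$p_alt,
                   ci_low = af$ci_low, ci_high = af$ci_high,
                   hwe_p = hw$p_value)
    })
    data.frame(rsid = cts$rsid, gene = v$gene,
               ref = v$ref_allele, alt = v$alt_allele,
               do.call(rbind, rows), n = cts$n, row.names = NULL)
}
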