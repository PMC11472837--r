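#' Pairwise variant-specific FST between two populations
#'
#' Wright's fixation index for a single biallelic locus compared between two
#' equally weighted populations with allele frequencies p1 and p2:
#' \deqn{F_{ST} = (p_1 - p_2)^2 / [(p_1 + p_2)(2 - p_1 - p_2)]}
#' which equals the heterozygosity form (H_T - H_S) / H_T. When both
#' populations are fixed for the same allele the ratio is 0/0; the statistic
#' is then defined as 0 and flagged monomorphic so panel-wide profiles never
#' abort.
#'
#' @param p1,p2 allele frequencies in [0, 1] (vectorized).
#' @return numeric FST in [0, 1], with attribute \code{"monomorphic"}
#'   (logical vector) marking 0/0 loci.
#' @examples
#' pairwiseFst(0.69, 0.18)  # 0.2646, large divergence
#' @export
pairwiseFst <- function(p1, p2) {
    if (any(p1 < 0 | p1 > 1 | p2 < 0 | p2 > 1, na.rm = TRUE))
        stop("allele frequencies must lie in [0, 1]")
    den <- (p1 + p2) * (2 - p1 - p2)
    mono <- !is.na(den) & den == 0
    fst <- ifelse(mono, 0, (p1 - p2)^2 / den)
    attr(fst, "monomorphic") <- mono
    fst
}

.fstCategories <- c("low", "moderate", "large", "very_large")

#' Classify an FST value into a divergence category
#'
#' Thresholds: below 0.05 low; 0.05 up to (but excluding) 0.15 moderate;
#' 0.15 through 0.25 inclusive large; above 0.25 very large. The boundaries
#' are fixed half-open / closed-right so every value falls in exactly one
#' class.
#'
#' @param fst numeric FST value(s) in [0, 1].
#' @return factor with levels \code{low}, \code{moderate}, \code{large},
#'   \code{very_large}.
#' @examples
#' classifyFst(c(0.042, 0.071, 0.15, 0.3))
#' @export
classifyFst <- function(fst) {
    if (any(fst < 0 | fst > 1, na.rm = TRUE))
        stop("FST must lie in [0, 1]")
    out <- ifelse(fst < 0.05, "low",
           ifelse(fst < 0.15, "moderate",
           ifelse(fst <= 0.25, "large", "very_large")))
    factor(out, levels = .fstCategories)
}

#' Per-locus FST profile of one population comparison
#'
#' Computes the pairwise variant-specific FST at every shared locus of two
#' per-locus allele-frequency vectors, classifies each value, and summarizes
#' the comparison with the unweighted mean and sample (n - 1) SD across loci
#' plus per-category counts. Loci with a missing frequency on either side
#' are dropped and counted; loci monomorphic for the same allele in both
#' populations enter as FST = 0 with a flag.
#'
#' @param freqsA,freqsB named numeric vectors of alt-allele frequencies
#'   (names = rsids) or data.frames with \code{rsid} and \code{p_alt}
#'   columns. Both must cover the same locus set (order-free).
#' @param label comparison label.
#' @return an \linkS4class{FstProfile}.
#' @export
fstProfile <- function(freqsA, freqsB, label = "A_vs_B") {
    fa <- .asFreqVector(freqsA)
    fb <- .asFreqVector(freqsB)
    shared <- intersect(names(fa), names(fb))
    if (length(shared) == 0) stop("no shared loci between the two inputs")
    fa <- fa[shared]; fb <- fb[shared]
    keep <- !is.na(fa) & !is.na(fb)
    nDropped <- sum(!keep)
    if (nDropped > 0)
        message("fstProfile[", label, "]: dropped ", nDropped,
                " locus/loci with missing frequency")
    fa <- fa[keep]; fb <- fb[keep]
    if (length(fa) == 0) stop("no loci with frequencies on both sides")
    fst <- pairwiseFst(fa, fb)
    mono <- attr(fst, "monomorphic")
    cat_ <- classifyFst(as.numeric(fst))
    res <- data.frame(rsid = names(fa), p1 = unname(fa), p2 = unname(fb),
                      fst = as.numeric(fst), category = cat_,
                      monomorphic = mono, row.names = NULL)
    cc <- table(factor(cat_, levels = .fstCategories))
    new("FstProfile", label = label, results = res,
        meanFst = mean(res$fst),
        sdFst = if (nrow(res) > 1) stats::sd(res$fst) else 0,
        categoryCounts = stats::setNames(as.integer(cc), .fstCategories),
        nDropped = as.integer(nDropped))
}

.asFreqVector <- function(x) {
    if (is.data.frame(x)) {
        if (!all(c("rsid", "p_alt") %in% colnames(x)))
            stop("frequency data.frame needs 'rsid' and 'p_alt' columns")
        stats::setNames(x$p_alt, x$rsid)
    } else {
        if (is.null(names(x)))
            names(x) <- paste0("locus_", seq_along(x))
        x
    }
}
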