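#' Read a biallelic cohort VCF plus strata labels
#'
#' Parses a minimal VCF (v4.x, GT field) into a \linkS4class{PgxCohort}.
#' Doses are the count of alt alleles in the GT call; phased (\code{|}) and
#' unphased (\code{/}) separators are treated identically and a missing call
#' (\code{./.} or \code{.}) becomes \code{NA}. Multiallelic records are not
#' guessed at: they raise an error naming the site.
#'
#' @param path path to a VCF file.
#' @param strataPath optional path to a tab-separated table
#'   \code{sample_id<TAB>skin_color<TAB>region}. Samples present in the VCF
#'   but absent from the table trigger a warning and are kept with
#'   \code{"unlabeled"} strata.
#' @return a \linkS4class{PgxCohort}.
#' @export
readCohortVcf <- function(path, strataPath = NULL) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    multi <- grepl(",", fix$ALT, fixed = TRUE)
    if (any(multi))
        stop("multiallelic site(s) not supported: ",
             paste(fix$ID[multi], collapse = ", "))
    gt <- vcfR::extract.gt(v, element = "GT")
    dose <- apply(gt, c(1, 2), .gtToDose)
    variants <- data.frame(rsid = fix$ID,
                           gene = NA_character_,
                           ref_allele = fix$REF,
                           alt_allele = fix$ALT,
                           note = NA_character_,
                           stringsAsFactors = FALSE)
    strata <- NULL
    if (!is.null(strataPath)) {
        st <- utils::read.delim(strataPath, stringsAsFactors = FALSE)
        if (!"sample_id" %in% colnames(st))
            stop("strata file needs a 'sample_id' column")
        idx <- match(colnames(gt), st$sample_id)
        if (anyNA(idx))
            warning("sample(s) in VCF missing from strata file: ",
                    paste(colnames(gt)[is.na(idx)], collapse = ", "),
                    "; assigned 'unlabeled' strata")
        strata <- st[idx, setdiff(colnames(st), "sample_id"), drop = FALSE]
        strata[] <- lapply(strata, function(col) {
            col[is.na(idx)] <- "unlabeled"
            col
        })
        rownames(strata) <- colnames(gt)
    }
    PgxCohort(dose, variants, strata)
}

.gtToDose <- function(gt) {
    if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return(NA_real_)
    alleles <- strsplit(gt, "[/|]")[[1]]
    if (any(alleles == ".")) return(NA_real_)
    if (!all(alleles %in% c("0", "1")))
        stop("unsupported GT call '", gt, "' (biallelic 0/1 only)")
    sum(alleles == "1")
}

#' Write a PgxCohort as a minimal VCF plus strata table
#'
#' The inverse of \code{\link{readCohortVcf}}: emits a VCFv4.2 file holding
#' only GT calls (unphased) and, when the cohort carries strata, a companion
#' tab-separated label table.
#'
#' @param cohort a \linkS4class{PgxCohort}.
#' @param path output VCF path.
#' @param strataPath optional output path for the strata table.
#' @return invisibly, \code{path}.
#' @export
writeCohortVcf <- function(cohort, path, strataPath = NULL) {
    d <- doses(cohort)
    v <- variantInfo(cohort)
    gtOf <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
    gt <- matrix("./.", nrow = nrow(d), ncol = ncol(d))
    ok <- !is.na(d)
    gt[ok] <- gtOf[as.character(d[ok])]
    hdr <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", colnames(d)), collapse = "\t"))
    body <- vapply(seq_len(nrow(d)), function(i) {
        paste(c("1", i, v$rsid[i], v$ref_allele[i], v$alt_allele[i], ".",
                "PASS", ".", "GT", gt[i, ]), collapse = "\t")
    }, character(1))
    writeLines(c(hdr, body), path)
    if (!is.null(strataPath)) {
        st <- cohortStrata(cohort)
        utils::write.table(
            cbind(sample_id = colnames(d), st),
            strataPath, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    invisible(path)
}

#' Read a per-locus published frequency table
#'
#' Loads a tab-separated table of published per-variant summaries (genotype
#' frequencies, alt-allele frequency with 95\% CI, HWE p-value) and validates
#' it. Published genotype-frequency triples are rounded to two decimals, so
#' their sum is accepted within 0.01 of 1; larger discrepancies raise an
#' error naming the offending row. A confidence interval that fails to
#' bracket its own point estimate is kept verbatim but flagged with a
#' warning, since it usually signals a transcription slip in the source
#' (e.g. an interval printed for the complementary allele).
#'
#' @param path path to a TSV with columns \code{rsid gene ref alt f_ref_hom
#'   f_het f_alt_hom p_alt ci_low ci_high hwe_p} (optionally \code{note}).
#' @return data.frame of validated records, one row per variant.
#' @export
readFrequencyTable <- function(path) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("rsid", "ref", "alt", "f_ref_hom", "f_het", "f_alt_hom",
              "p_alt", "ci_low", "ci_high", "hwe_p")
    miss <- setdiff(need, colnames(tab))
    if (length(miss))
        stop("frequency table lacks column(s): ", paste(miss, collapse = ", "))
    if (anyDuplicated(tab$rsid))
        stop("duplicate rsid in frequency table")
    fcols <- c("f_ref_hom", "f_het", "f_alt_hom", "p_alt", "ci_low",
               "ci_high", "hwe_p")
    for (cc in fcols) {
        bad <- !is.na(tab[[cc]]) & (tab[[cc]] < 0 | tab[[cc]] > 1)
        if (any(bad))
            stop("frequency outside [0, 1] in column ", cc, ", row ",
                 paste(tab$rsid[bad], collapse = ", "))
    }
    s <- tab$f_ref_hom + tab$f_het + tab$f_alt_hom
    off <- abs(s - 1) > 0.01 + 1e-9
    if (any(off))
        stop("genotype frequencies of ", paste(tab$rsid[off], collapse = ", "),
             " sum to ", paste(round(s[off], 3), collapse = ", "),
             " (beyond the 0.01 rounding slack)")
    noBracket <- tab$ci_low > tab$p_alt | tab$ci_high < tab$p_alt
    if (any(noBracket))
        warning("confidence interval does not bracket p_alt for: ",
                paste(tab$rsid[noBracket], collapse = ", "),
                " (printed values kept verbatim)")
    if (!"note" %in% colnames(tab)) tab$note <- NA_character_
    tab
}

#' The packaged Cuban pharmacogene variant table
#'
#' Published genotype and allele frequencies of 39 pharmacogene SNVs
#' genotyped in 357 unrelated Cuban volunteers (GRCh38, plus strand;
#' the TP53 rs1042522 row carries a strand-orientation note). Loaded through
#' \code{\link{readFrequencyTable}}, so the transcription-slip warning for
#' the rs2740574 interval is raised on load.
#'
#' @return data.frame with one row per variant.
#' @examples
#' tab <- suppressWarnings(cubanSnvTable())
#' nrow(tab)  # 39
#' @export
cubanSnvTable <- function() {
    readFrequencyTable(system.file("extdata", "cuban_snv_table1.tsv",
                                   package = "pgxfreq", mustWork = TRUE))
}

#' Reconstruct integer genotype counts from rounded frequencies
#'
#' Finds the genotype-count triple (ref-hom, het, alt-hom) summing to
#' \code{n} whose implied frequencies are closest, in squared error, to a
#' published rounded triple. Ties are broken by the lexicographically
#' smallest triple, making the reconstruction deterministic. This inverts
#' the 2-decimal rounding of published tables well enough that
#' downstream statistics (allele frequencies, HWE tests) can be recomputed
#' from summary data.
#'
#' @param fRefHom,fHet,fAltHom published genotype frequencies.
#' @param n cohort size (positive integer).
#' @return named integer(4): \code{n_ref_hom}, \code{n_het}, \code{n_alt_hom},
#'   \code{n}.
#' @examples
#' reconstructCounts(0.14, 0.35, 0.52, 357)  # 49, 124, 184
#' @export
reconstructCounts <- function(fRefHom, fHet, fAltHom, n) {
    stopifnot(length(n) == 1L, n > 0, n == round(n))
    a <- rep.int(0:n, (n:0) + 1L)
    b <- sequence((n:0) + 1L) - 1L
    cc <- n - a - b
    d <- (a / n - fRefHom)^2 + (b / n - fHet)^2 + (cc / n - fAltHom)^2
    tied <- which(d <= min(d) + 1e-12)
    best <- tied[order(a[tied], b[tied])][1L]
    c(n_ref_hom = a[best], n_het = b[best], n_alt_hom = cc[best], n = as.integer(n))
}

#' Write a results table as TSV
#'
#' Numeric columns are written at full precision in up to six significant
#' digits after the decimal point so that a write/read round trip is stable.
#' An empty table yields a header-only file.
#'
#' @param results data.frame (e.g. a frequency table, an FST profile via
#'   \code{as.data.frame}, or a strata-scan table).
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeResultsTsv <- function(results, path) {
    results <- as.data.frame(results)
    num <- vapply(results, is.numeric, logical(1))
    results[num] <- lapply(results[num], function(x) round(x, 6))
    ok <- tryCatch({
        utils::write.table(results, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        TRUE
    }, error = function(e) e)
    if (!isTRUE(ok))
        stop("cannot write results to '", path, "': ", conditionMessage(ok))
    invisible(path)
}

#' Read and write reference-panel frequency tables
#'
#' The panel TSV has one row per locus: an \code{rsid} column followed by one
#' alt-allele-frequency column per reference population.
#'
#' @param path TSV path.
#' @param eps clamping bound passed to \code{\link{referencePanel}}.
#' @return \code{readPanelTsv}: a \linkS4class{ReferencePanel}.
#' @export
readPanelTsv <- function(path, eps = 1e-6) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!"rsid" %in% colnames(tab))
        stop("panel file needs an 'rsid' column")
    f <- as.matrix(tab[setdiff(colnames(tab), "rsid")])
    rownames(f) <- tab$rsid
    referencePanel(f, eps = eps)
}

#' @rdname readPanelTsv
#' @param panel a \linkS4class{ReferencePanel}.
#' @return \code{writePanelTsv}: invisibly, \code{path}.
#' @export
writePanelTsv <- function(panel, path) {
    f <- panelFreqs(panel)
    writeResultsTsv(data.frame(rsid = rownames(f), f, check.names = FALSE),
                    path)
}
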