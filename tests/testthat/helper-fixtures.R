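# In-code fixtures shared across test files.

# Minimal 3-sample, 2-site VCF whose hand-counted dose matrix
# (individuals x loci) is [[0,2],[1,1],[2,0]]; one call is phased to check
# phased/unphased equivalence.
writeToyVcf <- function(path) {
    writeLines(c(
        "##fileformat=VCFv4.2",
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
        paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
              "INFO", "FORMAT", "S1", "S2", "S3", sep = "\t"),
        paste("1", "100", "rsA", "A", "G", ".", "PASS", ".", "GT",
              "0/0", "0/1", "1/1", sep = "\t"),
        paste("1", "200", "rsB", "C", "T", ".", "PASS", ".", "GT",
              "1|1", "0/1", "0/0", sep = "\t")), path)
    path
}

writeToyStrata <- function(path, ids = c("S1", "S2", "S3")) {
    utils::write.table(
        data.frame(sample_id = ids,
                   skin_color = c("white", "admixed", "black")[seq_along(ids)],
                   region = "west"),
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
}

# A small deterministic cohort built directly (no I/O).
toyCohort <- function() {
    v <- data.frame(rsid = c("rsA", "rsB", "rsC"),
                    ref_allele = "A", alt_allele = "G")
    d <- matrix(c(0, 1, 2, 2, 1, 0, 1, NA, 1, 0, 0, 2), nrow = 3,
                dimnames = list(v$rsid, paste0("S", 1:4)))
    PgxCohort(d, v, data.frame(grp = c("x", "x", "y", "y")))
}

# Independent brute-force L2 count reconstruction (double loop, no shared
# code with the package implementation).
bruteReconstruct <- function(f, n) {
    best <- NULL; bestD <- Inf
    for (a in 0:n) for (b in 0:(n - a)) {
        cc <- n - a - b
        d <- (a / n - f[1])^2 + (b / n - f[2])^2 + (cc / n - f[3])^2
        if (d < bestD - 1e-15 ||
            (abs(d - bestD) <= 1e-15 &&
             !is.null(best) && (a < best[1] || (a == best[1] && b < best[2])))) {
            bestD <- d; best <- c(a, b, cc)
        }
    }
    best
}

# The paper-facing simulation conditions: self-reported skin-color strata
# with their ancestry means (European, African, Amerindian).
skinColorStrata <- function(exchangeable = FALSE) {
    if (exchangeable) {
        m <- c(0.678, 0.272, 0.053)
        list(list(label = "white",   n = 190, mean = m),
             list(label = "admixed", n = 101, mean = m),
             list(label = "black",   n = 66,  mean = m))
    } else {
        list(list(label = "white",   n = 190, mean = c(0.859, 0.093, 0.048)),
             list(label = "admixed", n = 101, mean = c(0.577, 0.363, 0.060)),
             list(label = "black",   n = 66,  mean = c(0.312, 0.647, 0.041)))
    }
}
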