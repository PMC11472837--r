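#' Fisher-Freeman-Halton exact test for r x c contingency tables
#'
#' Tests independence of rows and columns under the fixed-margin
#' (multivariate hypergeometric) null. The two-sided p-value follows the
#' Freeman-Halton convention: the sum of conditional probabilities of every
#' margin-compatible table no more probable than the observed one, with a
#' relative slack of 1e-9 for floating-point ties.
#'
#' Small tables are fully enumerated by recursive traversal of all tables
#' with the observed margins. When a cheap upper bound on the number of such
#' tables (product of per-row composition counts) exceeds 1e6, the same tail
#' probability is instead estimated by Monte Carlo over fixed-margin tables
#' drawn with Patefield's algorithm (\code{\link[stats]{r2dtable}}), using
#' the add-one estimator (x + 1) / (N + 1) so the p-value is never 0 and the
#' observed table always counts itself.
#'
#' @param table integer matrix of counts, at least 2 x 2, no empty row or
#'   column margin.
#' @param mode \code{"auto"} (default), \code{"enumerate"} or \code{"mc"}.
#' @param nPermutations Monte Carlo sample size (default 1e5).
#' @param seed integer seed, mandatory whenever Monte Carlo is used (the
#'   reproducibility contract); ignored by full enumeration.
#' @return named list: \code{p_value}, \code{method}
#'   (\code{"full_enumeration"} or \code{"monte_carlo"}),
#'   \code{n_permutations} and \code{seed} (MC only, otherwise \code{NA}).
#' @examples
#' fisherFreemanHalton(matrix(c(3, 1, 1, 3), 2))$p_value  # 34/70
#' @export
fisherFreemanHalton <- function(table, mode = c("auto", "enumerate", "mc"),
                                nPermutations = 1e5, seed = NULL) {
    mode <- match.arg(mode)
    tab <- as.matrix(table)
    if (nrow(tab) < 2 || ncol(tab) < 2)
        stop("need at least a 2 x 2 table")
    if (any(tab < 0) || any(tab != round(tab)))
        stop("table entries must be non-negative integers")
    rs <- rowSums(tab); cs <- colSums(tab)
    if (any(rs == 0) || any(cs == 0))
        stop("degenerate margin: empty row or column")
    if (mode == "auto")
        mode <- if (.enumBound(rs, cs) <= 1e6) "enumerate" else "mc"
    logObs <- .tableLogProb(tab, rs, cs)
    slack <- 1e-9   # relative tolerance for float ties
    if (mode == "enumerate") {
        p <- .ffhEnumerate(rs, cs, logObs + slack)
        list(p_value = min(p, 1), method = "full_enumeration",
             n_permutations = NA_integer_, seed = NA_integer_)
    } else {
        if (is.null(seed))
            stop("Monte Carlo mode requires a seed (reproducibility contract)")
        old <- .saveSeed()
        on.exit(.restoreSeed(old))
        set.seed(seed)
        sims <- stats::r2dtable(nPermutations, rs, cs)
        logConst <- sum(lfactorial(rs)) + sum(lfactorial(cs)) -
            lfactorial(sum(rs))
        logs <- logConst - vapply(sims, function(t) sum(lfactorial(t)),
                                  numeric(1))
        x <- sum(logs <= logObs + slack)
        list(p_value = (x + 1) / (nPermutations + 1), method = "monte_carlo",
             n_permutations = as.integer(nPermutations),
             seed = as.integer(seed))
    }
}

# log multivariate hypergeometric probability of a table given its margins
.tableLogProb <- function(tab, rs = rowSums(tab), cs = colSums(tab)) {
    sum(lfactorial(rs)) + sum(lfactorial(cs)) - lfactorial(sum(rs)) -
        sum(lfactorial(tab))
}

# upper bound on the number of margin-compatible tables: with rows sorted
# ascending the last (largest) row is forced, and each remaining row ranges
# over compositions of its total into c parts (ignoring the column
# constraint). The p-value is invariant under row/column permutation and
# transposition, so the cheaper orientation is used.
.enumBound1 <- function(rs, cs) {
    rs <- sort(rs); cN <- length(cs)
    prod(vapply(rs[-length(rs)],
                function(ri) choose(ri + cN - 1, cN - 1), numeric(1)))
}

.enumBound <- function(rs, cs) min(.enumBound1(rs, cs), .enumBound1(cs, rs))

# Sum of probabilities of all fixed-margin tables with log-probability
# <= cutoff. Rows are sorted ascending (the forced final row is then the
# largest); the last two rows are always handled as one vectorized 2 x c
# block, and any rows before them by depth-first recursion over cells.
.ffhEnumerate <- function(rs, cs, cutoff) {
    if (.enumBound1(cs, rs) < .enumBound1(rs, cs)) {
        t <- rs; rs <- cs; cs <- t
    }
    rs <- sort(rs)
    r <- length(rs); cN <- length(cs)
    logConst <- sum(lfactorial(rs)) + sum(lfactorial(cs)) -
        lfactorial(sum(rs))
    if (r == 2L) return(.ffh2block(rs[1L], cs, logConst, cutoff))
    total <- 0
    recurseRow <- function(i, colRem, logAcc) {
        if (i == r - 1L) {
            total <<- total + .ffh2block(rs[i], colRem, logAcc, cutoff)
            return()
        }
        fillCell <- function(j, left, colRem, logAcc) {
            if (j == cN) {
                if (left > colRem[cN]) return()
                colRem[cN] <- colRem[cN] - left
                recurseRow(i + 1L, colRem, logAcc - lfactorial(left))
                return()
            }
            for (x in 0:min(left, colRem[j])) {
                cr <- colRem; cr[j] <- cr[j] - x
                fillCell(j + 1L, left - x, cr, logAcc - lfactorial(x))
            }
        }
        fillCell(1L, rs[i], colRem, logAcc)
    }
    recurseRow(1L, cs, logConst)
    total
}

# Vectorized tail mass of a two-row block with row-1 total r1 and column
# margins cs: walks compositions of r1 as a growing grid of
# (cells used, accumulated log term) pairs; the second row is forced.
.ffh2block <- function(r1, cs, logBase, cutoff) {
    cN <- length(cs)
    used <- 0L
    logTerm <- 0
    for (j in seq_len(cN - 1L)) {
        x <- 0:min(r1, cs[j])
        lt <- -lfactorial(x) - lfactorial(cs[j] - x)
        used <- outer(used, x, `+`)
        logTerm <- outer(logTerm, lt, `+`)
        keep <- used <= r1
        used <- used[keep]; logTerm <- logTerm[keep]
    }
    last <- r1 - used
    keep <- last >= 0L & last <= cs[cN]
    logp <- logBase + logTerm[keep] - lfactorial(last[keep]) -
        lfactorial(cs[cN] - last[keep])
    sum(exp(logp[logp <= cutoff]))
}

.saveSeed <- function() {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv())
    else NULL
}

.restoreSeed <- function(old) {
    if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
}

#' Pearson chi-square test on a contingency table
#'
#' Asymptotic cross-check for \code{\link{fisherFreemanHalton}}; no
#' continuity correction. Errors when any expected cell is zero (the exact
#' test is then the right tool).
#'
#' @param table integer matrix of counts.
#' @return named list: \code{chi2}, \code{df}, \code{p_value}.
#' @export
chisqContingency <- function(table) {
    tab <- as.matrix(table)
    expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expd == 0))
        stop("zero expected cell; use fisherFreemanHalton() instead")
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
         p_value = ct$p.value)
}

#' Scan every locus for genotype-distribution differences across strata
#'
#' Builds, per locus, the genotype-class by stratum contingency table
#' (rows = ref-hom / het / alt-hom, dropping classes absent from the whole
#' locus; columns = the levels of the chosen stratum variable) and applies
#' the Fisher-Freeman-Halton exact test. Raw p-values are compared to
#' \code{alpha} without multiple-testing correction by default (the
#' convention of raw p < 0.05 significance counting), with Bonferroni or
#' Benjamini-Hochberg switches available.
#'
#' @param cohort a \linkS4class{PgxCohort}.
#' @param by name of the stratum column in \code{cohortStrata(cohort)}.
#' @param alpha significance level (default 0.05).
#' @param correction \code{"none"} (default), \code{"bonferroni"} or
#'   \code{"BH"}; applied to the p-values before counting significance.
#' @param seed integer seed used to derive a per-locus child seed for any
#'   Monte Carlo test in the scan.
#' @param nPermutations Monte Carlo sample size per locus.
#' @param mode passed to \code{\link{fisherFreemanHalton}}.
#' @return data.frame \code{rsid, p_value, p_adjusted, method, significant},
#'   with attribute \code{"n_significant"} and per-locus skips logged via
#'   \code{message()}.
#' @export
scanLoci <- function(cohort, by, alpha = 0.05, correction = c("none",
                     "bonferroni", "BH"), seed = 1L, nPermutations = 1e5,
                     mode = "auto") {
    correction <- match.arg(correction)
    st <- cohortStrata(cohort)
    if (!by %in% colnames(st))
        stop("no stratum variable '", by, "' in the cohort")
    groups <- factor(st[[by]])
    if (nlevels(groups) < 2)
        stop("stratum variable must have at least 2 levels present")
    d <- doses(cohort)
    rows <- lapply(seq_len(nrow(d)), function(i) {
        g <- d[i, ]
        ok <- !is.na(g)
        if (!any(ok)) {
            message("scanLoci: locus ", rownames(d)[i],
                    " has no called genotypes; skipped")
            return(NULL)
        }
        tab <- table(factor(g[ok], levels = 0:2), droplevels(groups[ok]))
        tab <- tab[rowSums(tab) > 0, , drop = FALSE]
        tab <- tab[, colSums(tab) > 0, drop = FALSE]
        if (nrow(tab) < 2 || ncol(tab) < 2) {
            message("scanLoci: locus ", rownames(d)[i],
                    " is degenerate (single genotype class or stratum); skipped")
            return(NULL)
        }
        res <- fisherFreemanHalton(tab, mode = mode,
                                   nPermutations = nPermutations,
                                   seed = childSeed(seed, i))
        data.frame(rsid = rownames(d)[i], p_value = res$p_value,
                   method = res$method)
    })
    out <- do.call(rbind, rows)
    if (is.null(out)) stop("no testable locus in the cohort")
    out$p_adjusted <- stats::p.adjust(out$p_value, method = switch(correction,
        none = "none", bonferroni = "bonferroni", BH = "BH"))
    out$significant <- out$p_adjusted < alpha
    attr(out, "n_significant") <- sum(out$significant)
    out
}
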