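#' Supervised admixture-proportion estimation by EM
#'
#' Maximizes the supervised admixture likelihood of one individual's
#' alt-allele doses given fixed reference-panel allele frequencies. Each of
#' the two allele copies at locus j is modelled as drawn from ancestral
#' population k with probability q_k and then carrying the alt allele with
#' probability p_jk, so the log-likelihood is
#' \deqn{\ell(q) = \sum_j g_j \log\left(\sum_k q_k p_{jk}\right) +
#'   (2 - g_j) \log\left(\sum_k q_k (1 - p_{jk})\right)}
#' The EM iteration computes per-allele-copy responsibilities and averages
#' them; the log-likelihood is non-decreasing at every step. Initialization
#' is the uniform simplex, making the estimate deterministic. Missing doses
#' contribute nothing (dropped per locus).
#'
#' @param dosesVec numeric vector of alt-allele doses (0/1/2, \code{NA}
#'   missing), aligned with the panel loci.
#' @param panel a \linkS4class{ReferencePanel} with the same loci.
#' @param tol relative log-likelihood convergence tolerance (default 1e-8).
#' @param maxIter iteration cap (default 2000).
#' @param returnTrace when \code{TRUE}, also return the per-iteration
#'   log-likelihood trace (for monotonicity diagnostics).
#' @return named list: \code{q} (named K-simplex), \code{loglik},
#'   \code{n_iter}, \code{converged}, and \code{trace} when requested.
#' @export
supervisedAdmixtureEM <- function(dosesVec, panel, tol = 1e-8,
                                  maxIter = 2000L, returnTrace = FALSE) {
    P <- panelFreqs(panel)
    if (length(dosesVec) != nrow(P))
        stop("dose vector and panel disagree on locus count")
    ok <- !is.na(dosesVec)
    if (!any(ok)) stop("all doses missing; cannot estimate ancestry")
    g <- as.numeric(dosesVec[ok])
    P <- P[ok, , drop = FALSE]
    K <- ncol(P)
    if (K == 1L) {
        out <- list(q = stats::setNames(1, colnames(P)),
                    loglik = sum(g * log(P) + (2 - g) * log(1 - P)),
                    n_iter = 0L, converged = TRUE)
        if (returnTrace) out$trace <- out$loglik
        return(out)
    }
    L <- nrow(P)
    q <- rep(1 / K, K)
    ll <- -Inf
    converged <- FALSE
    trace <- if (returnTrace) numeric(maxIter) else NULL
    for (it in seq_len(maxIter)) {
        A <- sweep(P, 2, q, `*`)          # q_k p_jk
        R <- sweep(1 - P, 2, q, `*`)      # q_k (1 - p_jk)
        sa <- rowSums(A); sr <- rowSums(R)
        llNew <- sum(g * log(sa) + (2 - g) * log(sr))
        if (returnTrace) trace[it] <- llNew
        # M-step: expected ancestral origin counts over the 2L allele copies
        m <- colSums(A * (g / sa)) + colSums(R * ((2 - g) / sr))
        q <- m / (2 * L)
        if (is.finite(ll) && abs(llNew - ll) <= tol * (abs(ll) + 1e-12)) {
            ll <- llNew
            converged <- TRUE
            break
        }
        ll <- llNew
    }
    q <- q / sum(q)
    out <- list(q = stats::setNames(q, colnames(P)), loglik = ll,
                n_iter = it, converged = converged)
    if (returnTrace) out$trace <- trace[seq_len(it)]
    out
}

#' Ancestry estimates for every individual of a cohort
#'
#' Maps \code{\link{supervisedAdmixtureEM}} over the individuals of a
#' cohort. Deterministic given the inputs (uniform-simplex initialization).
#' Individuals whose estimation fails (e.g. all doses missing) are skipped
#' with a logged message.
#'
#' @param cohort a \linkS4class{PgxCohort} whose loci match the panel (by
#'   rsid when both are named; otherwise by position).
#' @param panel a \linkS4class{ReferencePanel}.
#' @param tol,maxIter passed to \code{\link{supervisedAdmixtureEM}}.
#' @return data.frame with one row per estimated individual: \code{sample_id},
#'   one column per ancestry component, \code{loglik}, \code{n_iter},
#'   \code{converged}.
#' @export
cohortAncestry <- function(cohort, panel, tol = 1e-8, maxIter = 2000L) {
    d <- doses(cohort)
    P <- panelFreqs(panel)
    if (!is.null(rownames(d)) && all(rownames(d) %in% rownames(P)))
        panel <- referencePanel(P[rownames(d), , drop = FALSE],
                                eps = panel@eps)
    else if (nrow(d) != nrow(P))
        stop("cohort loci do not match the panel")
    rows <- lapply(seq_len(ncol(d)), function(i) {
        est <- tryCatch(supervisedAdmixtureEM(d[, i], panel, tol, maxIter),
                        error = function(e) e)
        if (inherits(est, "error")) {
            message("cohortAncestry: skipped ", colnames(d)[i], ": ",
                    conditionMessage(est))
            return(NULL)
        }
        data.frame(sample_id = colnames(d)[i], t(est$q),
                   loglik = est$loglik, n_iter = est$n_iter,
                   converged = est$converged, check.names = FALSE)
    })
    do.call(rbind, rows)
}

#' Per-group summary of ancestry components
#'
#' Arithmetic mean, minimum and maximum of each ancestry component within
#' each group (e.g. skin-color category or birth region). Groups absent
#' from the labels are reported as missing and logged.
#'
#' @param estimates data.frame from \code{\link{cohortAncestry}} (or any
#'   data.frame of simplex columns).
#' @param labels vector of group labels aligned with the rows of
#'   \code{estimates}.
#' @param components character vector naming the ancestry columns; default
#'   all numeric columns except fit diagnostics.
#' @return data.frame: \code{group}, \code{component}, \code{mean},
#'   \code{min}, \code{max}, \code{n}.
#' @export
groupSummary <- function(estimates, labels, components = NULL) {
    if (nrow(estimates) != length(labels))
        stop("labels must align with estimate rows")
    if (is.null(components))
        components <- setdiff(
            colnames(estimates)[vapply(estimates, is.numeric, logical(1))],
            c("loglik", "n_iter"))
    labels <- factor(labels)
    empty <- levels(labels)[tabulate(labels, nlevels(labels)) == 0]
    if (length(empty))
        message("groupSummary: empty group(s) reported as absent: ",
                paste(empty, collapse = ", "))
    out <- expand.grid(group = setdiff(levels(labels), empty),
                       component = components, stringsAsFactors = FALSE)
    stat <- function(f) mapply(function(g, cc)
        f(estimates[[cc]][labels == g]), out$group, out$component)
    out$mean <- stat(mean); out$min <- stat(min); out$max <- stat(max)
    out$n <- mapply(function(g, cc) sum(labels == g), out$group,
                    out$component)
    out
}

#' Kruskal-Wallis test with Dunn's post hoc pairwise comparisons
#'
#' Compares one ancestry component (or any numeric variable) across groups
#' by the Kruskal-Wallis rank test (tie-corrected H, chi-square p on
#' groups - 1 df), followed by Dunn's z-tests on mean ranks for every group
#' pair. Pairwise p-values are two-sided and compared against a stated
#' Bonferroni-style alpha (default 0.017 for three groups) rather than
#' being adjusted.
#'
#' @param values numeric vector of observations.
#' @param groups group labels aligned with \code{values}.
#' @param alphaPairwise pairwise significance level (default 0.017).
#' @return named list: \code{kw_h}, \code{kw_df}, \code{kw_p} and
#'   \code{pairwise}, a data.frame \code{group_i, group_j, z, dunn_p,
#'   significant}.
#' @examples
#' kruskalDunn(c(1:3, 4:6, 7:9), rep(letters[1:3], each = 3))$kw_p  # 0.027
#' @export
kruskalDunn <- function(values, groups, alphaPairwise = 0.017) {
    groups <- factor(groups)
    groups <- droplevels(groups)
    if (nlevels(groups) < 2)
        stop("need at least two groups")
    if (length(unique(values)) == 1L) {
        # all observations tied: no rank variation, H defined as 0
        pairs <- utils::combn(levels(groups), 2)
        pw <- data.frame(group_i = pairs[1, ], group_j = pairs[2, ],
                         z = 0, dunn_p = 1, significant = FALSE)
        return(list(kw_h = 0, kw_df = nlevels(groups) - 1L, kw_p = 1,
                    pairwise = pw))
    }
    kw <- stats::kruskal.test(values, groups)
    N <- length(values)
    rk <- rank(values)
    ties <- table(rk)
    tieCorr <- sum(ties^3 - ties) / (12 * (N - 1))
    meanRank <- tapply(rk, groups, mean)
    nG <- tapply(rk, groups, length)
    pairs <- utils::combn(levels(groups), 2)
    pw <- apply(pairs, 2, function(pr) {
        i <- pr[1]; j <- pr[2]
        se <- sqrt((N * (N + 1) / 12 - tieCorr) * (1 / nG[i] + 1 / nG[j]))
        z <- if (se == 0) 0 else (meanRank[i] - meanRank[j]) / se
        p <- 2 * stats::pnorm(-abs(z))
        data.frame(group_i = i, group_j = j, z = unname(z),
                   dunn_p = unname(p), significant = unname(p < alphaPairwise))
    })
    list(kw_h = unname(kw$statistic), kw_df = unname(kw$parameter),
         kw_p = kw$p.value, pairwise = do.call(rbind, pw))
}
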