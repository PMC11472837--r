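#' Derive a child seed from a master seed
#'
#' One master seed expands into per-stage (or per-locus) child seeds by a
#' fixed affine scheme modulo a Mersenne prime, so individual stages of a
#' simulation or scan can be rerun in isolation with identical randomness.
#'
#' @param seed master integer seed.
#' @param stage non-negative integer stage index.
#' @return a positive integer seed below 2^31.
#' @export
childSeed <- function(seed, stage) {
    as.integer((as.numeric(seed) %% 2147483647 + 104729 * as.numeric(stage)) %%
               2147483647 + 1)
}

#' Calibrate Dirichlet parameters to target ancestry means
#'
#' The Dirichlet(alpha) mean is alpha / sum(alpha), so alpha =
#' concentration * means reproduces any target simplex exactly while the
#' concentration controls individual-level spread. Zero mean components are
#' floored at 1e-3 * concentration (and logged) so the distribution stays
#' proper.
#'
#' @param targetMeans non-negative vector; renormalized to the simplex.
#' @param concentration positive scalar (sum of alphas).
#' @return numeric alpha vector.
#' @examples
#' calibrateAlphas(c(0.678, 0.272, 0.053), 10)
#' @export
calibrateAlphas <- function(targetMeans, concentration = 10) {
    stopifnot(concentration > 0, all(targetMeans >= 0), sum(targetMeans) > 0)
    m <- targetMeans / sum(targetMeans)
    alpha <- concentration * m
    zero <- alpha == 0
    if (any(zero)) {
        message("calibrateAlphas: floored ", sum(zero),
                " zero component(s) at 1e-3 * concentration")
        alpha[zero] <- 1e-3 * concentration
    }
    alpha
}

#' Simulate an ancestry-informative reference panel
#'
#' Draws per-population alt-allele frequencies independently from a Beta
#' distribution, by default Beta(0.5, 0.5), whose U-shape pushes
#' frequencies toward 0 and 1 and so yields strong between-population
#' differentiation -- the defining property of ancestry-informative
#' markers.
#'
#' @param K number of ancestral populations.
#' @param L number of loci.
#' @param betaParams length-2 shape parameters (default \code{c(0.5, 0.5)}).
#' @param seed integer seed (mandatory; panels are reproducible).
#' @param labels optional population names.
#' @param eps clamping bound.
#' @return a \linkS4class{ReferencePanel}.
#' @export
simulatePanel <- function(K, L, betaParams = c(0.5, 0.5), seed,
                          labels = NULL, eps = 1e-6) {
    stopifnot(L >= 1, K >= 1, length(betaParams) == 2)
    old <- .saveSeed()
    on.exit(.restoreSeed(old))
    set.seed(seed)
    f <- matrix(stats::rbeta(L * K, betaParams[1], betaParams[2]),
                nrow = L, ncol = K)
    rownames(f) <- sprintf("sim_snv_%03d", seq_len(L))
    referencePanel(f, labels = labels, eps = eps)
}

#' Specify a simulated admixed cohort
#'
#' @param strata list of stratum specs, each a list with \code{label},
#'   \code{n} and either \code{alpha} (Dirichlet K-vector) or \code{mean}
#'   (target ancestry means, turned into alphas via
#'   \code{\link{calibrateAlphas}} with \code{concentration}).
#' @param panel a \linkS4class{ReferencePanel}, or \code{NULL} to generate
#'   one with \code{\link{simulatePanel}} using \code{K}, \code{L},
#'   \code{betaParams}.
#' @param L loci count (required when generating the panel; otherwise taken
#'   from it).
#' @param K number of ancestral populations when generating the panel.
#' @param betaParams Beta shapes for panel generation.
#' @param concentration Dirichlet concentration for \code{mean}-specified
#'   strata (default 10, giving individual spread comparable to the wide
#'   per-group ancestry ranges seen in admixed cohorts).
#' @param nullGeneProbs optional numeric(2): marginal deletion probabilities
#'   of two unlinked null-genotype genes, drawn independently per
#'   individual.
#' @param seed mandatory master seed.
#' @param populationLabels labels for a generated panel.
#' @return a \linkS4class{CohortConfig}.
#' @export
cohortConfig <- function(strata, panel = NULL, L = NULL, K = 3,
                         betaParams = c(0.5, 0.5), concentration = 10,
                         nullGeneProbs = NULL, seed,
                         populationLabels = NULL) {
    if (missing(seed)) stop("a seed is mandatory")
    if (is.null(panel)) {
        if (is.null(L)) stop("L is required when no panel is supplied")
        panel <- simulatePanel(K, L, betaParams, seed = childSeed(seed, 1),
                               labels = populationLabels)
    }
    K <- ncol(panelFreqs(panel))
    stTab <- data.frame(
        label = vapply(strata, `[[`, character(1), "label"),
        n = vapply(strata, function(s) as.integer(s$n), integer(1)))
    alphas <- t(vapply(strata, function(s) {
        if (!is.null(s$alpha)) as.numeric(s$alpha)
        else if (!is.null(s$mean)) calibrateAlphas(s$mean, concentration)
        else stop("each stratum needs 'alpha' or 'mean'")
    }, numeric(K)))
    new("CohortConfig", strata = stTab, alphas = alphas, panel = panel,
        nullGeneProbs = if (is.null(nullGeneProbs)) numeric(0)
                        else as.numeric(nullGeneProbs),
        seed = as.integer(seed))
}

#' Simulate an admixed cohort
#'
#' For each individual of each stratum: ancestry proportions q are drawn
#' from the stratum's Dirichlet; the per-locus mixed alt-allele dose
#' probability is q %*% t(panel frequencies); the genotype is
#' Binomial(2, mixed probability). Loci are independent (no linkage
#' disequilibrium) and allele frequencies uncorrelated across populations.
#' Optional null-genotype genes are deleted independently per individual.
#' Every stage uses a child seed of the master seed, so identical configs
#' give bit-identical cohorts.
#'
#' @param config a \linkS4class{CohortConfig}.
#' @return a \linkS4class{SimulatedCohort}.
#' @export
simulateCohort <- function(config) {
    stopifnot(is(config, "CohortConfig"))
    validObject(config)
    P <- panelFreqs(config@panel)
    L <- nrow(P); K <- ncol(P)
    nTot <- sum(config@strata$n)
    old <- .saveSeed()
    on.exit(.restoreSeed(old))

    # stage 2: ancestry proportions
    set.seed(childSeed(config@seed, 2))
    Q <- matrix(0, nrow = nTot, ncol = K,
                dimnames = list(NULL, colnames(P)))
    labels <- character(nTot)
    at <- 0L
    for (s in seq_len(nrow(config@strata))) {
        ns <- config@strata$n[s]
        gm <- matrix(stats::rgamma(ns * K, shape = rep(config@alphas[s, ],
                                                       each = ns)),
                     nrow = ns)
        Q[at + seq_len(ns), ] <- gm / rowSums(gm)
        labels[at + seq_len(ns)] <- config@strata$label[s]
        at <- at + ns
    }

    # stage 3: genotypes given mixed dose probability
    set.seed(childSeed(config@seed, 3))
    mix <- Q %*% t(P)                      # n x L
    g <- matrix(stats::rbinom(length(mix), 2, mix), nrow = nTot)
    d <- t(g)                              # loci x individuals
    rownames(d) <- rownames(P)
    colnames(d) <- sprintf("ind_%04d", seq_len(nTot))
    rownames(Q) <- colnames(d)

    st <- data.frame(stratum = labels, row.names = colnames(d))

    # stage 4: optional null-genotype genes (independent deletions)
    if (length(config@nullGeneProbs) == 2L) {
        set.seed(childSeed(config@seed, 4))
        st$gene_A_present <- stats::runif(nTot) >= config@nullGeneProbs[1]
        st$gene_B_present <- stats::runif(nTot) >= config@nullGeneProbs[2]
    }

    variants <- data.frame(rsid = rownames(P), gene = NA_character_,
                           ref_allele = "A", alt_allele = "G",
                           note = "synthetic locus")
    cohort <- PgxCohort(d, variants, st)
    new("SimulatedCohort", cohort = cohort, trueQ = Q,
        panel = config@panel, config = config)
}

#' Frequency report of a simulated cohort
#'
#' Runs the frequency/HWE machinery over the simulated genotypes, overall
#' and per stratum, producing tables in the same column schema as the
#' packaged published table.
#'
#' @param simulated a \linkS4class{SimulatedCohort}.
#' @param ciMethod passed through to \code{\link{cohortFrequencyTable}}.
#' @return data.frame with a leading \code{stratum} column
#'   (\code{"overall"} plus one block per stratum).
#' @export
cohortReport <- function(simulated, ciMethod = "wilson") {
    stopifnot(is(simulated, "SimulatedCohort"))
    ch <- simCohort(simulated)
    st <- cohortStrata(ch)$stratum
    blocks <- c(list(overall = cohortFrequencyTable(ch, ciMethod)),
                lapply(stats::setNames(nm = unique(st)), function(lv)
                    cohortFrequencyTable(ch, ciMethod, samples = st == lv)))
    out <- do.call(rbind, Map(function(nm, tab)
        cbind(stratum = nm, tab), names(blocks), blocks))
    rownames(out) <- NULL
    out
}
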