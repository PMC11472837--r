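test_that("EM handles the degenerate and symmetric panels analytically", {
    p1 <- referencePanel(matrix(0.3, 50, 1, dimnames = list(NULL, "only")))
    one <- supervisedAdmixtureEM(rbinom(50, 2, 0.3), p1)
    expect_equal(unname(one$q), 1)

    # maximally informative symmetric 2-way panel
    P <- cbind(eur = rep(1 - 1e-6, 50), afr = rep(1e-6, 50))
    pan <- referencePanel(P)
    het <- supervisedAdmixtureEM(rep(1, 50), pan)
    expect_equal(unname(het$q), c(0.5, 0.5), tolerance = 1e-6)

    hom <- supervisedAdmixtureEM(rep(2, 50), pan)
    expect_gt(hom$q[["eur"]], 0.999)

    expect_error(supervisedAdmixtureEM(rep(NA, 50), pan), "missing")
})

test_that("EM log-likelihood is non-decreasing on random instances", {
    set.seed(61)
    for (i in 1:8) {
        L <- 30
        pan <- simulatePanel(3, L, seed = 600 + i)
        q <- as.numeric(rmultinom(1, 10, rep(1, 3))) / 10
        g <- rbinom(L, 2, panelFreqs(pan) %*% q)
        fit <- supervisedAdmixtureEM(g, pan, returnTrace = TRUE)
        expect_true(all(diff(fit$trace) > -1e-8 * abs(fit$trace[-1])))
        expect_equal(sum(fit$q), 1, tolerance = 1e-8)
        expect_true(all(fit$q >= 0))
    }
})

test_that("estimates are invariant to locus permutation and identical inputs give identical output", {
    set.seed(62)
    pan <- simulatePanel(3, 40, seed = 63)
    g <- rbinom(40, 2, panelFreqs(pan) %*% c(0.6, 0.3, 0.1))
    f1 <- supervisedAdmixtureEM(g, pan)
    perm <- sample(40)
    f2 <- supervisedAdmixtureEM(g[perm],
                                referencePanel(panelFreqs(pan)[perm, ]))
    expect_equal(f1$q, f2$q, tolerance = 1e-10)

    d <- matrix(rep(g, 3), ncol = 3,
                dimnames = list(rownames(panelFreqs(pan)), paste0("I", 1:3)))
    ch <- PgxCohort(d, data.frame(rsid = rownames(panelFreqs(pan)),
                                  ref_allele = "A", alt_allele = "G"))
    est <- cohortAncestry(ch, pan)
    expect_equal(est[1, populationLabels(pan)], est[2, populationLabels(pan)],
                 ignore_attr = TRUE)
})

test_that("ancestry recovery sharpens as the marker panel grows", {
    mkCohort <- function(L) {
        cf <- cohortConfig(strata = list(list(label = "all", n = 50,
                                              mean = c(0.678, 0.272, 0.053))),
                           L = L, K = 3, seed = 71,
                           populationLabels = c("EUR", "AFR", "AMR"))
        simulateCohort(cf)
    }
    maeOf <- function(sim) {
        est <- cohortAncestry(simCohort(sim), sim@panel)
        mean(abs(as.matrix(est[, c("EUR", "AFR", "AMR")]) - trueAncestry(sim)))
    }
    m34 <- maeOf(mkCohort(34))
    m136 <- maeOf(mkCohort(136))
    expect_lt(m136, m34)
})

test_that("group summaries average components correctly", {
    est <- data.frame(EUR = c(0.8, 0.6), AFR = c(0.2, 0.4), AMR = c(0, 0))
    gs <- groupSummary(est, c("g", "g"), components = c("EUR", "AFR", "AMR"))
    expect_equal(gs$mean[gs$component == "EUR"], 0.7)
    expect_equal(gs$mean[gs$component == "AFR"], 0.3)
    expect_equal(gs$min[gs$component == "EUR"], 0.6)

    single <- groupSummary(est[1, ], "solo", components = c("EUR", "AFR"))
    expect_equal(single$mean, c(0.8, 0.2))
    expect_error(groupSummary(est, c("a")), "align")
})

test_that("per-stratum ancestry means are recovered within Monte Carlo error", {
    cf <- cohortConfig(strata = skinColorStrata(), L = 60, K = 3, seed = 81,
                       concentration = 10,
                       populationLabels = c("EUR", "AFR", "AMR"))
    sim <- simulateCohort(cf)
    est <- cohortAncestry(simCohort(sim), sim@panel)
    labs <- cohortStrata(sim)$stratum
    gs <- groupSummary(est, labs, components = c("EUR", "AFR", "AMR"))
    targets <- skinColorStrata()
    for (s in targets) {
        m <- s$mean / sum(s$mean)
        for (k in 1:3) {
            comp <- c("EUR", "AFR", "AMR")[k]
            got <- gs$mean[gs$group == s$label & gs$component == comp]
            # Dirichlet component SD at concentration 10 plus estimation noise
            se <- sqrt(m[k] * (1 - m[k]) / 11) / sqrt(s$n) + 0.02
            expect_lt(abs(got - m[k]), 3 * se)
        }
    }
})

test_that("Kruskal-Wallis with Dunn post hoc matches hand-ranked results", {
    r <- kruskalDunn(1:9, rep(c("a", "b", "c"), each = 3))
    expect_equal(r$kw_h, 7.2)
    expect_equal(r$kw_p, 0.02732372, tolerance = 1e-6)
    expect_equal(nrow(r$pairwise), 3L)  # all pairs covered
    ac <- r$pairwise[r$pairwise$group_i == "a" & r$pairwise$group_j == "c", ]
    expect_true(ac$significant)  # only extreme pair clears alpha = 0.017

    tied <- kruskalDunn(rep(1, 9), rep(c("a", "b", "c"), each = 3))
    expect_equal(tied$kw_h, 0)
    expect_equal(tied$kw_p, 1)
    expect_error(kruskalDunn(1:5, rep("a", 5)), "two groups")
})

test_that("Kruskal-Wallis holds its nominal type-I rate", {
    set.seed(91)
    rej <- replicate(2000, {
        kruskalDunn(rnorm(300), rep(1:3, each = 100))$kw_p < 0.05
    })
    expect_gte(mean(rej), 0.035)
    expect_lte(mean(rej), 0.065)
})
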