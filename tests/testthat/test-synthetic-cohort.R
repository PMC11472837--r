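test_that("alpha calibration reproduces targets and floors zero components", {
    a <- calibrateAlphas(c(0.678, 0.272, 0.053), 10)
    expect_equal(a, 10 * c(0.678, 0.272, 0.053) / 1.003, tolerance = 1e-12)
    expect_message(fl <- calibrateAlphas(c(1, 0, 0), 10), "floored")
    expect_equal(fl, c(10, 0.01, 0.01))
    expect_error(calibrateAlphas(c(0.5, 0.5), -1))
})

test_that("Dirichlet draws at the calibrated alphas hit the target means", {
    a <- calibrateAlphas(c(0.678, 0.272, 0.053), 10)
    set.seed(101)
    n <- 1e5
    gm <- matrix(rgamma(n * 3, shape = rep(a, each = n)), nrow = n)
    qs <- gm / rowSums(gm)
    m <- a / sum(a)
    for (k in 1:3) {
        se <- sqrt(m[k] * (1 - m[k]) / (sum(a) + 1)) / sqrt(n)
        expect_lt(abs(mean(qs[, k]) - m[k]), 3 * se)
    }
})

test_that("simulated panels are reproducible and ancestry-informative", {
    p1 <- simulatePanel(3, 200, seed = 111)
    p2 <- simulatePanel(3, 200, seed = 111)
    expect_identical(panelFreqs(p1), panelFreqs(p2))
    expect_false(identical(panelFreqs(p1),
                           panelFreqs(simulatePanel(3, 200, seed = 112))))

    big <- panelFreqs(simulatePanel(2, 1000, seed = 113))
    expect_equal(mean(big), 0.5, tolerance = 3 * 0.35 / sqrt(2000))
    # U-shaped Beta(0.5, 0.5) draws give AIM-like differentiation
    prof <- fstProfile(big[, 1], big[, 2], "panel")
    expect_gt(meanFst(prof), 0.05)
})

test_that("identical configs give bit-identical cohorts", {
    cf <- cohortConfig(strata = skinColorStrata(), L = 25, K = 3, seed = 121,
                       nullGeneProbs = c(0.39, 0.18))
    s1 <- simulateCohort(cf)
    s2 <- simulateCohort(cf)
    expect_identical(doses(s1), doses(s2))
    expect_identical(trueAncestry(s1), trueAncestry(s2))
    expect_identical(cohortStrata(s1), cohortStrata(s2))
    expect_false(identical(doses(s1), doses(simulateCohort(
        cohortConfig(strata = skinColorStrata(), L = 25, K = 3, seed = 122,
                     nullGeneProbs = c(0.39, 0.18))))))
})

test_that("mixture expectation propagates to empirical allele frequencies", {
    # ancestry pinned to population 1; panel flat at 0.7 for it
    P <- cbind(a = rep(0.7, 30), b = rep(0.2, 30))
    cf <- cohortConfig(strata = list(list(label = "s", n = 800,
                                          alpha = c(500, 0.01))),
                       panel = referencePanel(P), seed = 131)
    sim <- simulateCohort(cf)
    tab <- cohortFrequencyTable(simCohort(sim))
    se <- sqrt(0.7 * 0.3 / (2 * 800))
    expect_lt(max(abs(tab$p_alt - 0.7)), 4 * se + 0.01)
})

test_that("realized stratum ancestry approaches the Dirichlet means as n grows", {
    mk <- function(n, seed) {
        cf <- cohortConfig(strata = list(list(label = "s", n = n,
                                              mean = c(0.678, 0.272, 0.053))),
                          L = 5, K = 3, seed = seed)
        colMeans(trueAncestry(simulateCohort(cf)))
    }
    m <- c(0.678, 0.272, 0.053) / 1.003
    errSmall <- max(abs(mk(50, 141) - m))
    errBig <- max(abs(mk(5000, 141) - m))
    expect_lt(errBig, errSmall)
    expect_lt(errBig, 3 * sqrt(max(m * (1 - m)) / 11) / sqrt(5000))
})

test_that("null-genotype calls appear at the configured deletion rates", {
    cf <- cohortConfig(strata = list(list(label = "s", n = 4000,
                                          mean = c(0.7, 0.25, 0.05))),
                       L = 5, K = 3, seed = 151,
                       nullGeneProbs = c(0.39, 0.18))
    st <- cohortStrata(simulateCohort(cf))
    ns <- nullGenotypeSummary(st$gene_A_present, st$gene_B_present)
    expect_lt(abs(ns$f_null_A - 0.39), 3 * sqrt(0.39 * 0.61 / 4000))
    expect_lt(abs(ns$f_null_B - 0.18), 3 * sqrt(0.18 * 0.82 / 4000))
    expect_lt(abs(ns$f_concomitant - 0.39 * 0.18),
              3 * sqrt(0.0702 * (1 - 0.0702) / 4000))
})

test_that("pooling differentiated strata inflates HWE rejections (Wahlund)", {
    cf <- cohortConfig(strata = list(
        list(label = "eur", n = 180, mean = c(0.95, 0.04, 0.01)),
        list(label = "afr", n = 180, mean = c(0.05, 0.94, 0.01))),
        L = 400, K = 3, seed = 161)
    sim <- simulateCohort(cf)
    ch <- simCohort(sim)
    st <- cohortStrata(ch)$stratum
    rejRate <- function(sel = NULL) {
        tab <- cohortFrequencyTable(ch, samples = sel)
        mean(tab$hwe_p < 0.05, na.rm = TRUE)
    }
    pooled <- rejRate()
    eur <- rejRate(st == "eur")
    afr <- rejRate(st == "afr")
    expect_gt(pooled, eur)
    expect_gt(pooled, afr)
    expect_gt(pooled, 0.05)
})

test_that("cohort reports mirror direct genotype counting, per stratum and overall", {
    cf <- cohortConfig(strata = skinColorStrata(), L = 12, K = 3, seed = 171)
    sim <- simulateCohort(cf)
    rep_ <- cohortReport(sim)
    expect_equal(nrow(rep_), 4 * 12)  # overall + 3 strata
    expect_setequal(unique(rep_$stratum),
                    c("overall", "white", "admixed", "black"))
    ch <- simCohort(sim)
    d <- doses(ch)
    ov <- rep_[rep_$stratum == "overall", ]
    expect_equal(ov$f_het,
                 unname(rowSums(d == 1) / rowSums(!is.na(d))),
                 tolerance = 1e-12)
    wh <- rep_[rep_$stratum == "white", ]
    sel <- cohortStrata(ch)$stratum == "white"
    expect_equal(wh$p_alt,
                 unname((rowSums(d[, sel] == 1) + 2 * rowSums(d[, sel] == 2)) /
                        (2 * rowSums(!is.na(d[, sel])))),
                 tolerance = 1e-12)
})
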