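test_that("full enumeration reproduces hand-enumerated exact p-values", {
    # margins (4,4)/(4,4): five tables, tail mass 34/70
    r <- fisherFreemanHalton(matrix(c(3, 1, 1, 3), 2))
    expect_equal(r$p_value, 34 / 70, tolerance = 1e-12)
    expect_equal(r$method, "full_enumeration")
    # modal table with proportional rows: every table is <=-probable
    expect_equal(fisherFreemanHalton(matrix(c(2, 2, 2, 2), 2))$p_value, 1)
})

test_that("enumeration agrees with the independent exact-test implementation", {
    set.seed(31)
    for (i in 1:12) {
        nr <- sample(2:3, 1); nc <- sample(2:3, 1)
        m <- matrix(rpois(nr * nc, 3), nr, nc)
        if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
        expect_equal(fisherFreemanHalton(m, mode = "enumerate")$p_value,
                     stats::fisher.test(m)$p.value, tolerance = 1e-9,
                     info = paste(m, collapse = ","))
    }
})

test_that("exact p-values are invariant under row and column permutation", {
    m <- matrix(c(5, 2, 1, 3, 4, 2, 0, 1, 3), 3, 3)
    p0 <- fisherFreemanHalton(m, mode = "enumerate")$p_value
    set.seed(8)
    for (i in 1:5) {
        pm <- m[sample(3), sample(3)]
        expect_equal(fisherFreemanHalton(pm, mode = "enumerate")$p_value, p0,
                     tolerance = 1e-12)
        expect_equal(fisherFreemanHalton(t(pm), mode = "enumerate")$p_value,
                     p0, tolerance = 1e-12)
    }
})

test_that("Monte Carlo estimates converge on the enumerated tail", {
    m <- matrix(c(3, 2, 1, 2, 2, 2, 1, 2, 3), 3)
    exact <- fisherFreemanHalton(m, mode = "enumerate")$p_value
    mc5 <- fisherFreemanHalton(m, mode = "mc", nPermutations = 1e5, seed = 7)
    se <- sqrt(exact * (1 - exact) / 1e5)
    expect_lt(abs(mc5$p_value - exact), 3 * se)
    expect_equal(mc5$method, "monte_carlo")
    # coarser estimate is noisier but consistent
    mc3 <- fisherFreemanHalton(m, mode = "mc", nPermutations = 1e3, seed = 7)
    expect_lt(abs(mc3$p_value - exact), 3 * sqrt(exact * (1 - exact) / 1e3))
    expect_lt(abs(mc5$p_value - exact), abs(mc3$p_value - exact) + 3 * se)
    # reproducibility and the seed contract
    again <- fisherFreemanHalton(m, mode = "mc", nPermutations = 1e3, seed = 7)
    expect_identical(again$p_value, mc3$p_value)
    expect_error(fisherFreemanHalton(m, mode = "mc"), "seed")
})

test_that("exact p-values always land in (0, 1]", {
    set.seed(12)
    for (i in 1:10) {
        m <- matrix(rpois(6, 2) + 1, 2, 3)
        p <- fisherFreemanHalton(m, mode = "enumerate")$p_value
        expect_gt(p, 0); expect_lte(p, 1)
    }
    big <- matrix(c(120, 30, 5, 20, 60, 40, 10, 30, 42), 3)
    pm <- fisherFreemanHalton(big, mode = "mc", nPermutations = 500,
                              seed = 3)$p_value
    expect_gt(pm, 0); expect_lte(pm, 1)
})

test_that("degenerate margins and invalid tables are refused", {
    expect_error(fisherFreemanHalton(matrix(c(0, 0, 3, 4), 2)), "margin")
    expect_error(fisherFreemanHalton(matrix(c(1.5, 1, 1, 1), 2)), "integer")
    expect_error(fisherFreemanHalton(matrix(1:3, 1)), "2 x 2")
})

test_that("chi-square cross-check matches hand computation and flags zero cells", {
    flat <- chisqContingency(matrix(10, 2, 2))
    expect_equal(flat$chi2, 0)
    expect_equal(flat$p_value, 1)
    r <- chisqContingency(matrix(c(20, 5, 5, 20), 2))
    expect_equal(r$chi2, 18)
    expect_equal(r$df, 1)
    expect_error(chisqContingency(matrix(c(0, 0, 1, 2), 2)),
                 "fisherFreemanHalton")
    # asymptotic and exact answers agree on well-filled tables
    m <- matrix(c(70, 55, 60, 58, 62, 52), 2, 3)
    expect_lt(abs(chisqContingency(m)$p_value -
                  fisherFreemanHalton(m, mode = "mc", nPermutations = 2e4,
                                      seed = 5)$p_value), 0.02)
})

test_that("locus scans count significant loci and skip degenerate loci with a log", {
    cf <- cohortConfig(strata = skinColorStrata(), L = 20, K = 3, seed = 41)
    ch <- simCohort(simulateCohort(cf))
    scan <- suppressMessages(scanLoci(ch, by = "stratum", seed = 42,
                                      nPermutations = 2000))
    expect_true(all(scan$p_value > 0 & scan$p_value <= 1))
    expect_equal(attr(scan, "n_significant"), sum(scan$p_value < 0.05))
    expect_setequal(unique(scan$method),
                    intersect(unique(scan$method),
                              c("full_enumeration", "monte_carlo")))

    # an all-missing locus is skipped, not fatal
    d <- doses(ch)
    d[1, ] <- NA
    ch2 <- PgxCohort(d, variantInfo(ch), cohortStrata(ch))
    expect_message(scan2 <- scanLoci(ch2, by = "stratum", seed = 42,
                                     nPermutations = 2000),
                   "skipped")
    expect_false(variantInfo(ch)$rsid[1] %in% scan2$rsid)
    expect_error(scanLoci(ch, by = "nope"), "stratum variable")
})

test_that("strata that differ in ancestry produce far more significant loci than the null", {
    # exchangeable strata: significance is pure type-I noise
    cf0 <- cohortConfig(strata = skinColorStrata(exchangeable = TRUE),
                        L = 39, K = 3, seed = 51)
    s0 <- suppressMessages(scanLoci(simCohort(simulateCohort(cf0)),
                                    by = "stratum", seed = 52,
                                    nPermutations = 2000))
    # binomial 95% upper bound on 39 tests at alpha = 0.05
    expect_lte(attr(s0, "n_significant"),
               qbinom(0.975, 39, 0.05))
    # ancestry-differentiated strata: systematic genotype differences
    cf1 <- cohortConfig(strata = skinColorStrata(), L = 39, K = 3, seed = 51)
    s1 <- suppressMessages(scanLoci(simCohort(simulateCohort(cf1)),
                                    by = "stratum", seed = 52,
                                    nPermutations = 2000))
    expect_gt(attr(s1, "n_significant"), qbinom(0.975, 39, 0.05))
})
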