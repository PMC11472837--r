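Package: pgxfreq
Title: Population Pharmacogenetics of Admixed Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for profiling pharmacogene variant frequencies in admixed
    populations. Implements genotype and allele frequency estimation with
    Wilson or Wald confidence intervals, Hardy-Weinberg equilibrium screening,
    pairwise variant-specific FST with divergence classification,
    Fisher-Freeman-Halton exact tests of genotype-by-stratum tables,
    supervised admixture-proportion estimation by expectation maximization
    against fixed reference allele-frequency panels, Kruskal-Wallis and Dunn
    comparisons of ancestry across strata, and a seeded simulator of admixed
    cohorts (Dirichlet ancestry, binomial genotypes given mixed allele dose)
    for end-to-end validation. Ships a packaged summary table of 39
    pharmacogene variants genotyped in 357 Cuban volunteers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
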