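---
title: "Population pharmacogenetics of admixed cohorts with pgxfreq"
author: "pgxfreq authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population pharmacogenetics of admixed cohorts with pgxfreq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgxfreq)
```

## Scope and motivation

Admixed populations -- Latin American and Caribbean cohorts in particular --
carry pharmacogene allele frequencies that cannot be extrapolated from any
single ancestral population. A frequency survey of such a cohort answers
four connected questions: what are the genotype and allele frequencies of
the target variants; are the genotype distributions compatible with
Hardy-Weinberg equilibrium (HWE), and if not, why; how differentiated is
the cohort from its ancestral and neighbouring populations; and how is
ancestry distributed across the cohort and its self-reported strata
(skin-color categories, birth regions)?

`pgxfreq` implements this analysis as a set of composable operations on two
S4 containers: `PgxCohort`, a `SummarizedExperiment` holding a loci x
individuals alt-allele dose matrix with variant annotation and
per-individual strata, and `ReferencePanel`, a loci x populations matrix of
ancestral allele frequencies. A packaged table
(`cubanSnvTable()`) ships the published genotype and allele frequencies of
39 pharmacogene SNVs from 357 Cuban volunteers, which drives the worked
examples and the reproduction tests.

## Frequencies, intervals, and count reconstruction

For genotype counts $(n_{rr}, n_{ra}, n_{aa})$ summing to $n$, the
alt-allele frequency is $\hat p = (n_{ra} + 2 n_{aa}) / 2n$. The default
95% interval is the Wilson score interval on $2n$ allele draws; it respects
$[0,1]$ and stays sensible at the small counts typical of rare
pharmacogene variants. A Wald interval is available for comparison with
published tables, whose interval construction is often unstated; published
intervals are therefore treated as descriptive, not as ground truth.

Published tables round frequencies to two decimals, so
`reconstructCounts()` inverts the rounding: it returns the integer triple
summing to $n$ minimizing the squared distance to the published triple,
with ties broken lexicographically so the reconstruction is deterministic.
On the packaged table this reproduces the published downstream statistics:

```{r counts}
tab <- suppressWarnings(cubanSnvTable())
r <- tab[tab$rsid == "rs1799853", ]
k <- reconstructCounts(r$f_ref_hom, r$f_het, r$f_alt_hom, 357)
k
hweChisq(k)$p_value   # published HWE p: 0.83
```

The load-time warning is deliberate: one published interval (rs2740574,
printed as 0.23 with interval 0.73-0.82) cannot bracket its own point
estimate and is almost certainly the interval of the complementary allele.
The values are kept verbatim and flagged, never silently corrected.

Genotype-frequency triples may sum to $1 \pm 0.01$ under rounding; the
reader accepts exactly that slack and rejects anything larger. Two further
published rows (e.g. rs1057910, rs712829) are not exactly consistent with
rounding at $n = 357$, suggesting per-variant missingness the source does
not report; for the same reason missing genotype calls in cohort data are
excluded per locus, giving each locus its own effective $n$.

## Hardy-Weinberg screening

`hweChisq()` is the one-degree-of-freedom asymptotic chi-square test
against expectations $n(q^2, 2pq, p^2)$ with $p$ estimated from the same
counts and no continuity correction; this choice reproduces the published
p-values on hand-checked rows. Exact (Levene/Haldane) HWE tests are out of
scope. Monomorphic loci return a flagged degenerate result
($\chi^2 = 0$, $p = 1$) rather than an error so whole-table scans never
abort. Under simulated equilibrium at $n = 357$ the test holds its nominal
5% level (type-I calibration is asserted in the test suite at 2000
replicates, band $0.05 \pm 0.015$).

In an admixed cohort, HWE deviations are expected even without genotyping
error: pooling subpopulations with different allele frequencies produces
excess homozygosity (the Wahlund effect). The simulator (below) makes this
prediction testable: pooling two strata with strongly differentiated
ancestry inflates the HWE rejection rate far past the nominal level of
either stratum alone, which is the package's mechanistic reading of the
deviations observed in the real cohort.

## Pairwise variant-specific FST

For allele frequencies $p_1, p_2$ in two equally weighted populations,

$$F_{ST} = \frac{(p_1 - p_2)^2}{(p_1 + p_2)(2 - p_1 - p_2)}
        = \frac{H_T - H_S}{H_T},$$

where $H_T$ is the heterozygosity of the pooled frequency and $H_S$ the
mean within-population heterozygosity. The test suite verifies the
algebraic identity of the two forms to $10^{-12}$ on a $101 \times 101$
grid. When both populations are fixed for the same allele the ratio is
$0/0$; it is defined as 0 and flagged monomorphic, and such loci are
included in profile means (with their count logged), since excluding them
would bias comparisons between marker panels.

Divergence categories follow the conventional thresholds, fixed here as
half-open/closed-right so every value has exactly one class: below 0.05
low; $[0.05, 0.15)$ moderate; $[0.15, 0.25]$ large; above 0.25 very
large. `fstProfile()` summarizes a comparison with the unweighted
per-locus mean, the sample ($n-1$) SD, and per-category counts.

```{r fst}
as.numeric(pairwiseFst(0.69, 0.18))   # CYP3A5-like contrast: large divergence
classifyFst(c(0.042, 0.071, 0.18))
```

## Exact tests of genotype-by-stratum tables

Genotype distributions are compared across strata with the
Fisher-Freeman-Halton exact test: under fixed margins, the two-sided
p-value is the total conditional probability of all tables no more
probable than the observed one (relative tie tolerance $10^{-9}$).

Small problems are fully enumerated by a recursive traversal of
margin-compatible tables; rows are sorted so the forced final row is the
largest, and the last two rows are folded into a single vectorized block,
which keeps genotype-by-stratum tables fast. Enumeration is used when a
conservative upper bound on the number of tables -- the product of per-row
composition counts, which bounds the recursion's work -- is at most
$10^6$; counting the tables exactly would cost as much as enumerating
them, so the bound stands in for the count and borderline tables simply
fall through to Monte Carlo. There, tables are drawn from the fixed-margin
null with Patefield's algorithm (`stats::r2dtable`) and the tail is
estimated with the add-one correction $(x+1)/(N+1)$, so a p-value is never
0 and is reproducible from its mandatory seed. `stats::fisher.test` serves
as an independent cross-check in the test suite, never as the
implementation.

`scanLoci()` applies the test per locus to the genotype-class x stratum
table, dropping empty genotype classes, and counts raw $p < \alpha$
without multiple-testing correction by default -- matching the common
practice of reporting raw significant-locus counts -- with Bonferroni and
Benjamini-Hochberg switches when a corrected scan is wanted. Each locus
gets a deterministic child seed of the scan seed so results do not depend
on locus order.

## Supervised admixture estimation

Ancestry proportions are estimated per individual by maximizing the
supervised admixture likelihood with fixed reference allele frequencies
$p_{jk}$ (populations $k = 1..K$, loci $j = 1..L$):

$$\ell(q) = \sum_j \left[ g_j \log \sum_k q_k p_{jk}
          + (2 - g_j) \log \sum_k q_k (1 - p_{jk}) \right].$$

The EM iteration treats each of the two allele copies at a locus as
latently assigned to an ancestral population, computes responsibilities,
and averages them over the $2L$ copies. The log-likelihood is
non-decreasing at every step (asserted in tests), initialization is the
uniform simplex so estimates are deterministic, convergence is declared at
relative log-likelihood change below $10^{-8}$ (cap 2000 iterations), and
panel frequencies are clamped to $[10^{-6}, 1 - 10^{-6}]$ so no genotype
has zero likelihood. Missing doses drop out of the sum.

This is a deliberate surrogate for full Bayesian clustering: when the
reference populations are fixed and labelled -- as they are when HGDP/1000
Genomes reference panels are declared a priori -- the supervised maximum
likelihood captures the estimand of a supervised STRUCTURE run without
MCMC, replicate merging, or $K$ selection, all of which are out of scope.
The correlated-allele-frequencies prior of model-based clustering is
likewise replaced by fixed panel frequencies.

Group structure is then summarized with `groupSummary()` (mean and range
per stratum and component) and tested with `kruskalDunn()`: tie-corrected
Kruskal-Wallis H with a chi-square p on $groups - 1$ degrees of freedom,
followed by Dunn's two-sided z-tests on mean ranks. Pairwise p-values are
compared against a stated alpha (default 0.017, the Bonferroni level for
three pairwise comparisons at 5%) rather than being rescaled, which keeps
the reported p-values interpretable.

## The synthetic-cohort generator

Because individual-level genotypes from real cohorts are rarely shareable,
every pipeline stage is validated against `simulateCohort()`, which
generates the structure the analysis assumes:

1. per stratum, individual ancestry $q_i \sim
   \mathrm{Dirichlet}(\alpha)$ with $\alpha = c \cdot m$ for target means
   $m$ and concentration $c$ (`calibrateAlphas()`);
2. per locus, alt-dose probability $\pi_{ij} = \sum_k q_{ik} p_{jk}$ and
   genotype $g_{ij} \sim \mathrm{Binomial}(2, \pi_{ij})$;
3. optionally, two unlinked null-genotype (whole-gene deletion) calls per
   individual with stated marginal probabilities.

Default conditions mirror the published cohort: strata of 190/101/66
individuals with mean (European, African, Amerindian) ancestry of
(85.9, 9.3, 4.8)%, (57.7, 36.3, 6.0)% and (31.2, 64.7, 4.1)% for the
three skin-color categories, overall means (67.8, 27.2, 5.3)%, 34
ancestry-informative markers, and deletion probabilities 0.39/0.18 for the
two GST null genes. Concentration defaults to 10, chosen once because it
reproduces the wide per-group ancestry ranges reported for such cohorts
(e.g. European ancestry spanning roughly 41-98% within the White
category); panels default to independent Beta(0.5, 0.5) draws per
population, whose U-shape yields the strong differentiation
(panel mean pairwise $F_{ST} > 0.05$) that defines ancestry-informative
markers.

The generator is reproducible at the integer level: one master seed
expands into per-stage child seeds (`childSeed()`, a fixed affine map
modulo $2^{31}-1$), so ancestry draws, genotypes and deletion calls can be
regenerated in isolation. What the simulator deliberately does *not*
emulate: linkage disequilibrium between markers (the analysis is
per-locus throughout), correlated drift between ancestral populations,
genotyping error, and per-locus missingness patterns. Passing tests
therefore demonstrate correctness of the statistical machinery under the
admixture model, not robustness to assay artefacts.

## Numerical and design choices

* **Count reconstruction** is exact L2 minimization with a lexicographic
  tie-break -- deterministic, and equivalent to largest-remainder
  apportionment on all published rows checked by hand.
* **Enumeration cutoff**: the $10^6$ bound is on a cheap upper bound for
  the table count, not the count itself (see above); both routes estimate
  the same tail, and their agreement is tested.
* **Divergence boundaries** are fixed as stated above because the
  conventional verbal definition leaves the interval endpoints ambiguous.
* **Degenerate inputs**: monomorphic loci (HWE, FST) yield flagged zero
  results; empty strata are logged and skipped; all-missing individuals
  or loci are skipped with a message; degenerate contingency margins and
  multiallelic VCF records raise errors naming the offender.
* **Problem sizes in the test suite** were chosen to exercise each claim
  at the cohort scale of the study ($n = 357$, 39 loci, 34-plex panels):
  type-I calibrations use 2000 replicates (HWE, Kruskal-Wallis) or ~2000
  pooled locus-tests (exact scan, Monte Carlo at 2000 permutations per
  locus); ancestry recovery uses $n = 200$ at $L = 34$ vs $136$, averaged
  over several replicate cohorts because the mean absolute error of a
  34-marker panel sits near its acceptance bound (about 0.09); the
  Wahlund demonstration uses 600 loci for a stable rejection-rate
  estimate.

## Known limitations

The HWE test is asymptotic and will be anticonservative for very rare
variants at small $n$; published confidence intervals cannot be
reproduced exactly because their construction is unstated; the supervised
EM inherits the panel's biases (a misspecified reference panel shifts all
estimates, and no uncertainty is attached to $\hat q$); and the exact
test's Monte Carlo p-values carry sampling error of order
$\sqrt{p(1-p)/N}$, which matters for p-values near a decision threshold.

## Session

```{r session}
sessionInfo()
```
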