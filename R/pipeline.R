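#' Run the full frequency/HWE/strata/ancestry/FST pipeline
#'
#' Orchestrates the analysis end to end from a single declarative YAML
#' config: cohort acquisition (simulated via \code{\link{simulateCohort}} or
#' read from a VCF + strata table), per-locus frequency and HWE tables,
#' exact genotype-by-stratum scans, supervised ancestry estimation with
#' per-group summaries and Kruskal-Wallis/Dunn comparisons, pairwise FST
#' profiles between configured strata, and a manifest with a checksum for
#' every emitted file. All randomness derives from the config seed, so
#' rerunning the same config reproduces every output byte for byte.
#'
#' Config keys: \code{seed}; \code{out_dir} (overridable by \code{outDir});
#' \code{cohort} with either \code{simulate} (\code{loci}, \code{panel}
#' {\code{K}, \code{labels}, \code{beta}}, \code{concentration},
#' \code{strata} list of {\code{label}, \code{n}, \code{mean} or
#' \code{alpha}}, optional \code{null_gene_probs}) or \code{vcf} +
#' \code{strata} paths; optional \code{panel_file} (TSV, required for
#' ancestry on a real cohort); \code{analysis} with \code{alpha},
#' \code{ci_method}, \code{strata_by} (vector of stratum columns),
#' \code{n_permutations}, \code{fst_pairs} (list of label pairs).
#'
#' @param configPath path to the YAML config.
#' @param outDir optional output directory (defaults to the config's
#'   \code{out_dir}).
#' @return invisibly, the output directory; side effect: the report files
#'   \code{frequencies.tsv}, \code{hwe.tsv}, per-variable
#'   \code{strata_tests_*.tsv}, \code{ancestry.tsv},
#'   \code{ancestry_groups_*.tsv}, per-pair \code{fst_*.tsv} and
#'   \code{manifest.tsv}.
#' @export
runPipeline <- function(configPath, outDir = NULL) {
    cfg <- yaml::read_yaml(configPath)
    if (is.null(cfg$seed)) stop("pipeline config must declare a seed")
    if (is.null(outDir)) outDir <- cfg$out_dir
    if (is.null(outDir)) stop("no output directory configured")
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    an <- cfg$analysis
    alpha <- if (is.null(an$alpha)) 0.05 else an$alpha
    ciMethod <- if (is.null(an$ci_method)) "wilson" else an$ci_method
    nPerm <- if (is.null(an$n_permutations)) 1e5 else an$n_permutations

    stage <- function(name, expr) {
        res <- tryCatch(expr, error = function(e)
            stop("pipeline stage '", name, "' failed: ",
                 conditionMessage(e), call. = FALSE))
        res
    }
    emit <- function(tab, file) {
        writeResultsTsv(tab, file.path(outDir, file))
        message("pipeline: wrote ", file, " (", NROW(tab), " rows)")
        file
    }
    files <- character(0)

    # --- cohort acquisition -------------------------------------------------
    acquired <- stage("cohort", {
        if (!is.null(cfg$cohort$simulate)) {
            sm <- cfg$cohort$simulate
            strata <- lapply(sm$strata, function(s)
                list(label = s$label, n = s$n, mean = s$mean,
                     alpha = s$alpha))
            conf <- cohortConfig(
                strata = strata, L = sm$loci,
                K = if (is.null(sm$panel$K)) 3 else sm$panel$K,
                betaParams = if (is.null(sm$panel$beta)) c(0.5, 0.5)
                             else as.numeric(sm$panel$beta),
                concentration = if (is.null(sm$concentration)) 10
                                else sm$concentration,
                nullGeneProbs = sm$null_gene_probs,
                seed = cfg$seed,
                populationLabels = unlist(sm$panel$labels))
            sim <- simulateCohort(conf)
            list(cohort = simCohort(sim), panel = sim@panel)
        } else {
            list(cohort = readCohortVcf(cfg$cohort$vcf, cfg$cohort$strata),
                 panel = NULL)
        }
    })
    cohort <- acquired$cohort
    panel <- acquired$panel
    if (!is.null(cfg$panel_file))
        panel <- stage("panel", readPanelTsv(cfg$panel_file))

    # --- frequencies + HWE --------------------------------------------------
    freqTab <- stage("frequencies", cohortFrequencyTable(cohort, ciMethod))
    files <- c(files, emit(freqTab, "frequencies.tsv"))
    hweTab <- freqTab[, c("rsid", "hwe_p")]
    hweTab$deviating <- !is.na(hweTab$hwe_p) & hweTab$hwe_p < alpha
    files <- c(files, emit(hweTab, "hwe.tsv"))

    # --- strata scans -------------------------------------------------------
    byVars <- unlist(an$strata_by)
    if (is.null(byVars)) byVars <- colnames(cohortStrata(cohort))[1]
    for (v in byVars) {
        scan <- stage(paste0("strata_", v),
                      scanLoci(cohort, by = v, alpha = alpha,
                               seed = childSeed(cfg$seed, 10),
                               nPermutations = nPerm))
        files <- c(files, emit(scan, paste0("strata_tests_", v, ".tsv")))
    }

    # --- ancestry -----------------------------------------------------------
    if (!is.null(panel)) {
        anc <- stage("ancestry", cohortAncestry(cohort, panel))
        files <- c(files, emit(anc, "ancestry.tsv"))
        comps <- populationLabels(panel)
        st <- cohortStrata(cohort)
        for (v in byVars) {
            labs <- st[match(anc$sample_id, rownames(st)), v]
            gs <- stage(paste0("ancestry_groups_", v),
                        groupSummary(anc, labs, components = comps))
            kd <- do.call(rbind, lapply(comps, function(cc) {
                r <- kruskalDunn(anc[[cc]], labs)
                cbind(component = cc, kw_p = r$kw_p, r$pairwise)
            }))
            files <- c(files,
                       emit(gs, paste0("ancestry_groups_", v, ".tsv")),
                       emit(kd, paste0("ancestry_tests_", v, ".tsv")))
        }
    }

    # --- FST profiles between configured strata -----------------------------
    for (pair in an$fst_pairs) {
        a <- pair[[1]]; b <- pair[[2]]
        v <- byVars[1]
        st <- cohortStrata(cohort)[[v]]
        profile <- stage(paste0("fst_", a, "_vs_", b), {
            fa <- cohortFrequencyTable(cohort, ciMethod, samples = st == a)
            fb <- cohortFrequencyTable(cohort, ciMethod, samples = st == b)
            fstProfile(fa, fb, label = paste0(a, "_vs_", b))
        })
        tab <- as.data.frame(profile)
        attrLine <- data.frame(rsid = "__summary__", p1 = NA, p2 = NA,
                               fst = meanFst(profile),
                               category = NA, monomorphic = NA)
        files <- c(files, emit(rbind(tab, attrLine),
                               paste0("fst_", a, "_vs_", b, ".tsv")))
    }

    # --- manifest -----------------------------------------------------------
    manifest <- data.frame(
        file = files,
        md5 = unname(tools::md5sum(file.path(outDir, files))),
        config_md5 = unname(tools::md5sum(configPath)),
        seed = cfg$seed)
    writeResultsTsv(manifest, file.path(outDir, "manifest.tsv"))
    message("pipeline: wrote manifest.tsv (", nrow(manifest), " files)")
    invisible(outDir)
}

#' Loci deviating from Hardy-Weinberg equilibrium
#'
#' Filters a per-locus HWE table to the loci with p below alpha, sorted by
#' p-value.
#'
#' @param hweTable data.frame with columns \code{rsid} and \code{hwe_p}
#'   (e.g. from \code{\link{cohortFrequencyTable}} or the packaged table).
#' @param alpha significance level (default 0.05).
#' @return character vector of rsids, most significant first.
#' @export
summarizeHweDeviations <- function(hweTable, alpha = 0.05) {
    keep <- !is.na(hweTable$hwe_p) & hweTable$hwe_p < alpha
    tab <- hweTable[keep, , drop = FALSE]
    tab$rsid[order(tab$hwe_p)]
}
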