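#' Default pipeline configuration
#'
#' Returns the full default configuration of [runPipeline()] as a nested
#' list. A user configuration (YAML file or list) is merged over these
#' defaults, so only deviations need to be stated.
#'
#' @return a named list; see [runPipeline()] for the meaning of each entry.
#' @export
pipelineDefaults <- function() {
    list(
        seed = 1L,
        outdir = "triplet-results",
        vcf = NULL,                 # input VCF; ignored when simulating
        panel_genes = NULL,         # gene list file; auto-written when simulating
        panel_bed = NULL,
        reference_counts = NULL,    # TSV; default: packaged gnomAD NFE counts
        reference_population = NULL,
        simulate = list(
            enabled = TRUE,
            n_samples = 100L, n_variants = 1000L, n_carriers = 3L,
            cluster_fractions = c(1, 0), cluster_fst = 0,
            focal_position = 1000000L,
            partner_offsets = c(-35000L, 52000L),
            background_maf_range = c(0.05, 0.5),
            missing_rate = 0,
            phased_vcf = FALSE),
        maf_threshold = 0.0005,
        missing_maf = "pass",
        strata = c(0, 0.1, 0.05),
        unrelated_threshold = 0.044,
        pca_fraction = 0.5, pca_k = 5L,
        window_bp = 100000L, min_nonref = 3L,
        focal = NULL,               # variant id; default: top candidate
        rarity = list(n_genes = 20000, median_gene_length = 26288,
                      maf = 5e-5, trio_size = 3),
        test_counts = c(443769, 179774))
}

.mergeConfig <- function(base, user) {
    for (k in names(user)) {
        if (is.list(base[[k]]) && is.list(user[[k]]))
            base[[k]] <- .mergeConfig(base[[k]], user[[k]])
        else
            base[[k]] <- user[[k]]
    }
    base
}

#' Read a pipeline configuration file
#'
#' Parses a YAML configuration and merges it over [pipelineDefaults()].
#' Unknown keys are rejected to catch typos early.
#'
#' @param path YAML file path.
#' @return the merged configuration list.
#' @export
readPipelineConfig <- function(path) {
    if (!file.exists(path))
        stop("config file not found: ", path, call. = FALSE)
    user <- yaml::read_yaml(path)
    defs <- pipelineDefaults()
    unknown <- setdiff(names(user), names(defs))
    if (length(unknown))
        stop("unknown config key(s): ", paste(unknown, collapse = ", "),
             call. = FALSE)
    .mergeConfig(defs, user)
}

.stamp <- function(...) {
    message(format(Sys.time(), "[%H:%M:%S] "), ...)
}

#' Run the full triplet analysis pipeline
#'
#' Orchestrates the complete analysis in order: (optional) cohort
#' simulation, VCF ingestion, loss-of-function candidate prioritization,
#' kinship estimation with unrelatedness verdicts, Hardy--Weinberg PCA on a
#' random SNP subsample, windowed LD around the top candidate with
#' perfect-LD partner detection, and the rarity statistics for the
#' candidate's carrier count. Every stage writes its table under
#' \code{outdir}; a combined plain-text report is written at the end.
#' Outputs are fully determined by the configuration (including its seed):
#' a rerun with the same configuration reproduces the same report.
#'
#' With no surviving candidate (e.g. a simulation with zero carriers) the
#' LD and rarity stages are skipped and the report says so.
#'
#' @param config configuration list (see [pipelineDefaults()]) or path to a
#'   YAML file.
#' @param outdir output directory; overrides \code{config$outdir}.
#' @return invisibly, an \code{analysisReport} list with elements
#'   \code{candidates}, \code{kinship}, \code{pca}, \code{ld},
#'   \code{perfect_partners}, \code{rarity}, \code{truth} (when simulated)
#'   and \code{provenance}.
#' @examples
#' \donttest{
#' rep <- runPipeline(list(simulate = list(n_samples = 40, n_variants = 200),
#'                         pca_k = 2), outdir = tempfile())
#' rep$candidates
#' }
#' @export
runPipeline <- function(config = list(), outdir = NULL) {
    if (is.character(config))
        config <- readPipelineConfig(config)
    else
        config <- .mergeConfig(pipelineDefaults(), config)
    if (!is.null(outdir)) config$outdir <- outdir
    outdir <- config$outdir
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    failMarker <- file.path(outdir, "FAILED")
    if (file.exists(failMarker)) unlink(failMarker)
    stage <- function(name, expr) {
        .stamp("stage ", name)
        tryCatch(expr, error = function(e) {
            writeLines(c(paste("stage:", name),
                         paste("error:", conditionMessage(e))), failMarker)
            stop("stage '", name, "' failed: ", conditionMessage(e),
                 call. = FALSE)
        })
    }
    report <- list()

    ## -- simulate ----------------------------------------------------------
    truth <- NULL
    if (isTRUE(config$simulate$enabled)) {
        sim <- stage("simulate", {
            sc <- config$simulate
            cfg <- cohortSimConfig(
                nSamples = sc$n_samples, nVariants = sc$n_variants,
                nCarriers = sc$n_carriers,
                clusterFractions = sc$cluster_fractions,
                clusterFst = sc$cluster_fst,
                focalPosition = sc$focal_position,
                partnerOffsets = sc$partner_offsets,
                backgroundMafRange = sc$background_maf_range,
                missingRate = sc$missing_rate,
                seed = config$seed)
            simulateCohort(cfg)
        })
        truth <- sim$truth
        config$vcf <- file.path(outdir, "cohort.vcf")
        stage("simulate", {
            writeCohortVcf(sim$cohort, config$vcf,
                           phased = isTRUE(config$simulate$phased_vcf))
            writeTruthSet(truth, outdir)
        })
        if (is.null(config$panel_genes)) {
            config$panel_genes <- file.path(outdir, "panel_genes.txt")
            writeLines("FANCI", config$panel_genes)
        }
    }

    ## -- read --------------------------------------------------------------
    cohort <- stage("read_vcf", {
        if (is.null(config$vcf))
            stop("no input VCF configured")
        readAnnotatedVcf(config$vcf)
    })
    .stamp("read ", nrow(dosage(cohort)), " variants x ",
           ncol(dosage(cohort)), " samples")

    ## -- filter ------------------------------------------------------------
    candidates <- stage("filter", {
        if (is.null(config$panel_genes))
            stop("no gene panel configured")
        panel <- readGenePanel(config$panel_genes, config$panel_bed)
        filterLofCandidates(cohort, panel,
                            mafThreshold = config$maf_threshold,
                            missingMaf = config$missing_maf)
    })
    .stamp("filter: ", nrow(dosage(cohort)), " variants in, ",
           nrow(candidates), " candidates out")
    writeCandidates(candidates, file.path(outdir, "candidates.tsv"))
    report$candidates <- candidates

    ## -- kinship -----------------------------------------------------------
    kin <- stage("kinship", {
        est <- estimateKinship(cohort, strata = config$strata)
        maxKinshipReport(est, unrelatedThreshold =
                                  config$unrelated_threshold)
    })
    writeKinshipReport(kin, file.path(outdir, "kinship.tsv"))
    report$kinship <- kin

    ## -- pca ---------------------------------------------------------------
    pca <- stage("pca", {
        idx <- subsampleSnps(nrow(dosage(cohort)), config$pca_fraction,
                             seed = config$seed)
        hweNormalizedPca(cohort, idx, k = config$pca_k,
                         seed = config$seed)
    })
    writePcaResult(pca, file.path(outdir, "pca_scores.tsv"),
                   file.path(outdir, "pca_variance.tsv"))
    report$pca <- pca

    ## -- ld + rarity (need a candidate) -------------------------------------
    if (nrow(candidates) == 0L) {
        .stamp("no candidate variant survives the filter; ",
               "skipping LD and rarity stages")
        report$ld <- NULL
        report$perfect_partners <- character(0)
        report$rarity <- NULL
        skipNote <- "no candidate variant; LD and rarity stages skipped"
    } else {
        focal <- if (!is.null(config$focal)) config$focal else
            candidates$variant_id[1]
        ld <- stage("ld", {
            ldScan(cohort, focal, windowBp = config$window_bp,
                   minNonref = config$min_nonref)
        })
        .writeTsv(ld, file.path(outdir, "ld.tsv"))
        partners <- perfectLdPartners(ld)
        fpos <- start(rowRanges(cohort))[match(focal, variantIds(cohort))]
        hm <- stage("ld", {
            m <- try(ldHeatmapMatrix(
                cohort,
                chrom = as.character(seqnames(rowRanges(cohort)))[
                    match(focal, variantIds(cohort))],
                start = fpos - config$window_bp,
                end = fpos + config$window_bp), silent = TRUE)
            if (inherits(m, "try-error")) NULL else m
        })
        if (!is.null(hm))
            writeLdMatrix(hm, file.path(outdir, "ld_heatmap.tsv"))
        report$ld <- ld
        report$perfect_partners <- partners

        rar <- stage("rarity", {
            refPath <- config$reference_counts
            if (is.null(refPath))
                refPath <- system.file("extdata", "reference_counts.tsv",
                                       package = "RareTriplet",
                                       mustWork = TRUE)
            rc <- readReferenceCounts(refPath, config$reference_population)
            cc <- candidates$carrier_count[match(focal,
                                                 candidates$variant_id)]
            if (is.na(cc))
                stop("focal variant is not among the candidates: ", focal)
            nS <- ncol(dosage(cohort))
            tab <- carrierTable(cc, nS - cc, rc["carriers"],
                                rc["noncarriers"])
            rarityReport(tab,
                         params = rarityParams(
                             nGenes = config$rarity$n_genes,
                             medianGeneLength =
                                 config$rarity$median_gene_length,
                             maf = config$rarity$maf,
                             cohortN = nS,
                             trioSize = config$rarity$trio_size),
                         testCounts = config$test_counts)
        })
        writeRarityReport(rar, file.path(outdir, "rarity.tsv"))
        report$rarity <- rar
        skipNote <- NULL
    }

    report$truth <- truth
    report$provenance <- list(
        package_version = as.character(utils::packageVersion("RareTriplet")),
        seed = config$seed,
        config = config)
    class(report) <- "analysisReport"
    .writeAnalysisReport(report, file.path(outdir, "report.txt"), skipNote)
    .stamp("pipeline complete; outputs in ", outdir)
    invisible(report)
}

## Combined plain-text report. Contains no timestamps so that identical
## configurations yield byte-identical files.
.writeAnalysisReport <- function(report, path, skipNote = NULL) {
    con <- file(path, "w")
    on.exit(close(con))
    w <- function(...) writeLines(paste0(...), con)
    prov <- report$provenance
    w("# Shared rare-variant triplet analysis report")
    w("package_version: ", prov$package_version)
    w("seed: ", prov$seed)
    w("")
    w("## Candidates (", nrow(report$candidates), ")")
    if (nrow(report$candidates)) {
        df <- report$candidates
        for (i in seq_len(nrow(df)))
            w(sprintf("%s gene=%s carriers=%d [%s]", df$variant_id[i],
                      df$gene[i], df$carrier_count[i], df$carrier_ids[i]))
    }
    w("")
    w("## Kinship (", report$kinship$estimator, ")")
    mx <- report$kinship$maxima
    for (i in seq_len(nrow(mx)))
        w(sprintf("max phi [%s]: %.5f (%s, %s)", mx$stratum[i],
                  mx$max_phi[i], mx$sample_a[i], mx$sample_b[i]))
    nv <- table(report$kinship$pairs$verdict)
    w("verdicts: ", paste(sprintf("%s=%d", names(nv), nv), collapse = " "))
    w("")
    ev <- explainedVariance(report$pca)
    w("## PCA")
    w("snps_sampled: ", report$pca@nSnpsSampled,
      " monomorphic_dropped: ", report$pca@nMonomorphicDropped)
    w("eigenvalues: ", paste(sprintf("%.4f", ev), collapse = " "))
    w("")
    if (!is.null(skipNote)) {
        w("## LD / rarity")
        w(skipNote)
    } else {
        w("## LD (window around top candidate)")
        w("partners_tested: ", nrow(report$ld))
        w("perfect_ld_partners: ",
          if (length(report$perfect_partners))
              paste(report$perfect_partners, collapse = ",") else "none")
        w("")
        w("## Rarity statistics")
        r <- report$rarity
        w(sprintf("fisher_p (%s): %.6g", r@alternative, r@fisherP))
        for (i in seq_along(r@bonferroni))
            w(sprintf("bonferroni[%s]: %.6g",
                      sub("^m_", "", names(r@bonferroni)[i]),
                      r@bonferroni[i]))
        w(sprintf("n_snps_effective (%s): %.6g", r@lengthUnit,
                  r@nSnpsEffective))
        w(sprintf("per_trio_probability: %.6g", r@perTrioProbability))
        w(sprintf("n_trios: %d", as.integer(r@nTrios)))
        w(sprintf("fdr_estimate: %.6g (complement %.6g)", r@fdrEstimate,
                  r@fdrComplement))
    }
    invisible(path)
}

#' @export
print.analysisReport <- function(x, ...) {
    cat("analysisReport:", nrow(x$candidates), "candidate(s);",
        "seed", x$provenance$seed, "\n")
    if (!is.null(x$rarity)) show(x$rarity)
    invisible(x)
}
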