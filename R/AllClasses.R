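#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<- mcols mcols<-
#' @importFrom GenomicRanges GRanges seqnames start
#' @importFrom IRanges IRanges
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowRanges colData
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
NULL

#' Cohort genotypes with variant annotation
#'
#' \code{GenotypeCohort} wraps a diploid dosage matrix (variants in rows,
#' samples in columns; entries 0, 1, 2 or \code{NA}) together with the
#' per-variant annotation the downstream analysis consumes: genomic position,
#' alleles, consequence term, gene symbol and reference-population allele
#' frequency. It extends \linkS4class{RangedSummarizedExperiment}, so all the
#' usual subsetting and accessor machinery applies; the single assay is named
#' \code{"dosage"}.
#'
#' Required \code{rowRanges} metadata columns: \code{variant_id}, \code{ref},
#' \code{alt}, \code{consequence}, \code{gene}, \code{ref_af}.
#'
#' @seealso [GenotypeCohort()] for construction from plain objects,
#'   [simulateCohort()] and [readAnnotatedVcf()] which produce one.
#' @export
setClass("GenotypeCohort",
         contains = "RangedSummarizedExperiment")

.validGenotypeCohort <- function(object) {
    msg <- character()
    if (!"dosage" %in% assayNames(object))
        msg <- c(msg, "assay 'dosage' is required")
    else {
        d <- assay(object, "dosage")
        bad <- !(is.na(d) | d %in% c(0, 1, 2))
        if (any(bad))
            msg <- c(msg, "dosage entries must be 0, 1, 2 or NA")
    }
    need <- c("variant_id", "ref", "alt", "consequence", "gene", "ref_af")
    have <- colnames(mcols(rowRanges(object)))
    miss <- setdiff(need, have)
    if (length(miss))
        msg <- c(msg, paste0("missing rowRanges metadata column(s): ",
                             paste(miss, collapse = ", ")))
    if (!length(miss)) {
        vid <- mcols(rowRanges(object))$variant_id
        if (anyDuplicated(vid))
            msg <- c(msg, "variant_id values must be unique")
        af <- mcols(rowRanges(object))$ref_af
        if (any(!is.na(af) & (af < 0 | af > 1)))
            msg <- c(msg, "ref_af must lie in [0, 1] or be NA")
    }
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "sample names must be present and unique")
    if (length(msg)) msg else TRUE
}

setValidity("GenotypeCohort", .validGenotypeCohort)

#' Ground truth of a simulated cohort
#'
#' Bookkeeping object emitted by [simulateCohort()] recording what was planted
#' so every downstream stage can be validated against it: the focal rare
#' stop-gain variant and its carriers, the two perfect-LD haplotype partners,
#' the expected kinship of each pedigree pair (0.25 for parent--offspring and
#' full siblings), and the ancestry cluster label of every sample.
#'
#' @slot plantedVariant variant id of the planted stop-gain variant.
#' @slot carrierIds sample ids carrying the planted heterozygous variant.
#' @slot haplotypePartnerIds variant ids of the two flanking partners placed
#'   on the carrier haplotype (perfect LD by construction).
#' @slot kinshipExpectations data.frame with columns \code{sample_a},
#'   \code{sample_b}, \code{relation}, \code{expected_phi}.
#' @slot clusterLabels character vector of \code{"A"}/\code{"B"} named by
#'   sample id.
#' @export
setClass("TruthSet",
         representation(plantedVariant = "character",
                        carrierIds = "character",
                        haplotypePartnerIds = "character",
                        kinshipExpectations = "data.frame",
                        clusterLabels = "character"))

setValidity("TruthSet", function(object) {
    msg <- character()
    ke <- object@kinshipExpectations
    need <- c("sample_a", "sample_b", "relation", "expected_phi")
    if (!all(need %in% colnames(ke)))
        msg <- c(msg, paste0("kinshipExpectations needs columns ",
                             paste(need, collapse = ", ")))
    if (length(object@plantedVariant) > 1L)
        msg <- c(msg, "plantedVariant must be length 0 or 1")
    if (length(msg)) msg else TRUE
})

#' Simulation configuration for a synthetic cohort
#'
#' Validated parameter set for [simulateCohort()]. See that function for the
#' meaning and defaults of each field; invalid values are rejected at
#' construction time with an error naming the offending field.
#'
#' @export
setClass("CohortSimConfig",
         representation(nSamples = "integer",
                        nVariants = "integer",
                        nCarriers = "integer",
                        clusterFractions = "numeric",
                        clusterFst = "numeric",
                        pedigreePairs = "data.frame",
                        focalPosition = "integer",
                        partnerOffsets = "integer",
                        backgroundMafRange = "numeric",
                        regionLength = "integer",
                        missingRate = "numeric",
                        seed = "integer"))

setValidity("CohortSimConfig", function(object) {
    msg <- character()
    if (object@nSamples < 2L)
        msg <- c(msg, "nSamples: need at least 2 samples")
    if (object@nCarriers < 0L || object@nCarriers > object@nSamples)
        msg <- c(msg, "nCarriers: must satisfy 0 <= nCarriers <= nSamples")
    if (object@nCarriers > 0L && object@nVariants < 3L)
        msg <- c(msg, "nVariants: need >= 3 (planted variant plus 2 partners)")
    cf <- object@clusterFractions
    if (length(cf) != 2L || any(cf < 0) || abs(sum(cf) - 1) > 1e-9)
        msg <- c(msg, "clusterFractions: two proportions summing to 1")
    if (object@clusterFst < 0 || object@clusterFst >= 1)
        msg <- c(msg, "clusterFst: must lie in [0, 1)")
    pp <- object@pedigreePairs
    if (nrow(pp)) {
        if (!all(c("sample_a", "sample_b", "relation") %in% colnames(pp)))
            msg <- c(msg, paste0("pedigreePairs: needs columns sample_a, ",
                                 "sample_b, relation"))
        else {
            if (!all(pp$relation %in% c("parent_offspring", "full_sibling")))
                msg <- c(msg, paste0("pedigreePairs: relation must be ",
                                     "parent_offspring or full_sibling"))
            ids <- c(pp$sample_a, pp$sample_b)
            if (anyDuplicated(ids))
                msg <- c(msg, "pedigreePairs: a sample may appear in one pair only")
            if (any(ids < 1L | ids > object@nSamples))
                msg <- c(msg, "pedigreePairs: sample indices out of range")
        }
    }
    off <- object@partnerOffsets
    if (any(off == 0L) || any(abs(off) > 100000L))
        msg <- c(msg, "partnerOffsets: nonzero and within +/-100000 bp")
    mr <- object@backgroundMafRange
    if (length(mr) != 2L || mr[1] <= 0 || mr[2] > 0.5 || mr[1] > mr[2])
        msg <- c(msg, "backgroundMafRange: an interval within (0, 0.5]")
    if (object@focalPosition < 1L)
        msg <- c(msg, "focalPosition: must be >= 1")
    if (any(object@focalPosition + off < 1L) ||
        any(object@focalPosition + off > object@regionLength))
        msg <- c(msg, "partnerOffsets: partner positions fall outside the region")
    if (object@regionLength < object@nVariants)
        msg <- c(msg, "regionLength: too short for the requested variant count")
    if (object@missingRate < 0 || object@missingRate >= 1)
        msg <- c(msg, "missingRate: must lie in [0, 1)")
    if (length(msg)) msg else TRUE
})

#' Carrier counts for the enrichment test
#'
#' A 2x2 table of carrier / non-carrier counts comparing the study cohort with
#' a reference population, the input to [fisherCarrierTest()]. Carriers are
#' counted as individuals (dosage >= 1), not alleles.
#'
#' @export
setClass("CarrierTable",
         representation(cohortCarriers = "numeric",
                        cohortNoncarriers = "numeric",
                        refCarriers = "numeric",
                        refNoncarriers = "numeric"))

setValidity("CarrierTable", function(object) {
    v <- c(object@cohortCarriers, object@cohortNoncarriers,
           object@refCarriers, object@refNoncarriers)
    msg <- character()
    if (any(v < 0) || any(v != round(v)) || anyNA(v))
        msg <- c(msg, "all counts must be non-negative integers")
    if (object@cohortCarriers + object@cohortNoncarriers < 1)
        msg <- c(msg, "cohort margin must be >= 1")
    if (object@refCarriers + object@refNoncarriers < 1)
        msg <- c(msg, "reference margin must be >= 1")
    if (length(msg)) msg else TRUE
})

#' Parameters of the trio rarity calculation
#'
#' The symbols of the random-occurrence probability for a shared rare variant:
#' number of protein-coding genes, median gene length in base pairs, the
#' variant's minor allele frequency, the cohort size and the trio size.
#' Defaults correspond to 20,000 genes of 26,288 bp median length, MAF
#' 5e-5 and trios of 3 drawn from 100 samples.
#'
#' @export
setClass("RarityParams",
         representation(nGenes = "numeric",
                        medianGeneLength = "numeric",
                        maf = "numeric",
                        cohortN = "numeric",
                        trioSize = "numeric"))

setValidity("RarityParams", function(object) {
    msg <- character()
    if (object@nGenes <= 0 || object@medianGeneLength <= 0 ||
        object@cohortN <= 0 || object@trioSize <= 0)
        msg <- c(msg, "all parameters must be positive")
    if (object@maf <= 0 || object@maf > 0.5)
        msg <- c(msg, "maf must lie in (0, 0.5]")
    if (object@trioSize > object@cohortN)
        msg <- c(msg, "trioSize must not exceed cohortN")
    if (length(msg)) msg else TRUE
})

setClassUnion("GRanges_OR_NULL", c("GRanges", "NULL"))

#' Gene panel restricting the variant search
#'
#' A set of gene symbols, optionally accompanied by genomic intervals
#' (0-based half-open BED convention on import, stored as \code{GRanges}).
#' A variant belongs to the panel if its gene symbol matches, or -- when the
#' symbol annotation is missing -- if its position overlaps a panel interval.
#'
#' @export
setClass("GenePanel",
         representation(genes = "character",
                        intervals = "GRanges_OR_NULL"))

setValidity("GenePanel", function(object) {
    if (length(object@genes) == 0L)
        return("panel must contain at least one gene symbol")
    TRUE
})

#' Hardy--Weinberg-normalized PCA result
#'
#' @slot scores samples-by-k matrix of principal component coordinates.
#' @slot explainedVariance eigenvalues (non-increasing) of the analyzed
#'   components.
#' @slot nSnpsSampled number of SNPs entering the decomposition (after the
#'   random subsample, before dropping monomorphic columns).
#' @slot nMonomorphicDropped monomorphic columns removed prior to
#'   normalization.
#' @slot seed seed used for the SNP subsample (\code{NA} if none drawn).
#' @export
setClass("HwePcaResult",
         representation(scores = "matrix",
                        explainedVariance = "numeric",
                        nSnpsSampled = "integer",
                        nMonomorphicDropped = "integer",
                        seed = "integer"))

#' Rarity statistics report
#'
#' Bundle of the inferential results for one candidate shared rare variant:
#' the carrier-enrichment exact test, the per-trio random-occurrence
#' probability, the FDR estimate over all trios of the cohort, and the
#' Bonferroni-adjusted p-values under supplied genome-wide test counts.
#'
#' @export
setClass("RarityReport",
         representation(table = "CarrierTable",
                        params = "RarityParams",
                        fisherP = "numeric",
                        alternative = "character",
                        nSnpsEffective = "numeric",
                        lengthUnit = "character",
                        perTrioProbability = "numeric",
                        nTrios = "numeric",
                        fdrEstimate = "numeric",
                        fdrComplement = "numeric",
                        bonferroni = "numeric"))
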