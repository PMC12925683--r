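#' Configure a synthetic cohort simulation
#'
#' Builds a validated \linkS4class{CohortSimConfig}. The defaults describe the
#' study design the package's statistics address: a cohort of 100 diploid
#' samples in which 3 unrelated carriers share one rare heterozygous stop-gain
#' variant riding on a 3-variant haplotype (two flanking intergenic partners
#' in perfect LD with it), with optional pedigree pairs for kinship validation
#' and an optional two-cluster ancestry split for PCA validation.
#'
#' @param nSamples number of diploid samples.
#' @param nVariants total number of variant sites, including the planted
#'   triplet (so at least 3).
#' @param nCarriers number of heterozygous carriers of the planted variant;
#'   0 leaves the triplet monomorphic reference.
#' @param clusterFractions two proportions (summing to 1) of samples assigned
#'   to ancestry clusters A and B.
#' @param clusterFst Balding--Nichols divergence parameter in [0, 1); 0 gives
#'   a single panmictic population.
#' @param pedigreePairs data.frame with integer columns \code{sample_a},
#'   \code{sample_b} and character \code{relation}
#'   (\code{"parent_offspring"} or \code{"full_sibling"}); each sample may
#'   appear in at most one pair.
#' @param focalPosition 1-based position of the planted stop-gain variant.
#' @param partnerOffsets two signed base-pair offsets (nonzero, within
#'   \eqn{\pm}100 kb) placing the haplotype partners relative to the focal
#'   variant.
#' @param backgroundMafRange interval within (0, 0.5] from which ancestral
#'   background allele frequencies are drawn uniformly.
#' @param regionLength length in bp of the simulated region.
#' @param missingRate per-genotype probability of a missing call.
#' @param seed integer fixing all randomness; identical configurations yield
#'   byte-identical VCFs.
#'
#' @return a \code{CohortSimConfig}.
#' @seealso [simulateCohort()]
#' @export
cohortSimConfig <- function(nSamples = 100L,
                            nVariants = 1000L,
                            nCarriers = 3L,
                            clusterFractions = c(1, 0),
                            clusterFst = 0,
                            pedigreePairs = data.frame(
                                sample_a = integer(), sample_b = integer(),
                                relation = character()),
                            focalPosition = 1000000L,
                            partnerOffsets = c(-35000L, 52000L),
                            backgroundMafRange = c(0.05, 0.5),
                            regionLength = 2000000L,
                            missingRate = 0,
                            seed = 1L) {
    new("CohortSimConfig",
        nSamples = as.integer(nSamples),
        nVariants = as.integer(nVariants),
        nCarriers = as.integer(nCarriers),
        clusterFractions = as.numeric(clusterFractions),
        clusterFst = as.numeric(clusterFst),
        pedigreePairs = as.data.frame(pedigreePairs),
        focalPosition = as.integer(focalPosition),
        partnerOffsets = as.integer(partnerOffsets),
        backgroundMafRange = as.numeric(backgroundMafRange),
        regionLength = as.integer(regionLength),
        missingRate = as.numeric(missingRate),
        seed = as.integer(seed))
}

## Draw one haplotype (0/1 vector over the background sites) for a sample in
## cluster `cl`, given per-cluster allele frequency matrix pClust.
.drawHap <- function(pClust, cl) {
    stats::rbinom(nrow(pClust), 1L, pClust[, cl])
}

#' Simulate an annotated synthetic cohort
#'
#' Generates a diploid genotype cohort with known ground truth: a planted
#' rare stop-gain variant heterozygous in exactly \code{nCarriers} samples,
#' two flanking intergenic variants placed on the same carrier haplotype
#' (perfect LD by construction), background variants drawn per ancestry
#' cluster under a Balding--Nichols model, and pedigree pairs generated by
#' per-site Mendelian transmission from simulated parental haplotypes.
#'
#' Background sites are mutually in linkage equilibrium; only the planted
#' triplet carries haplotype structure. Pedigree samples are never carriers.
#' All randomness is governed by \code{config@seed}; the caller's RNG state
#' is left untouched.
#'
#' @param config a \linkS4class{CohortSimConfig}, e.g. from
#'   [cohortSimConfig()].
#'
#' @return a list with elements \code{cohort} (a
#'   \linkS4class{GenotypeCohort}; phased haplotypes are kept in
#'   \code{metadata(cohort)$haplotypes}) and \code{truth}
#'   (a \linkS4class{TruthSet}).
#' @examples
#' sim <- simulateCohort(cohortSimConfig(nSamples = 20, nVariants = 50,
#'                                       nCarriers = 3, seed = 7))
#' sim$cohort
#' carrierIds(sim$truth)
#' @export
simulateCohort <- function(config = cohortSimConfig()) {
    stopifnot(is(config, "CohortSimConfig"))
    validObject(config)
    withLocalSeed(config@seed, .simulateCohortImpl(config))
}

.simulateCohortImpl <- function(config) {
    nS <- config@nSamples
    nV <- config@nVariants
    chrom <- "15"
    sampleId <- sprintf("S%03d", seq_len(nS))

    ## cluster assignment: first block A, remainder B
    nA <- round(config@clusterFractions[1] * nS)
    clu <- rep(c(1L, 2L), times = c(nA, nS - nA))
    cluLab <- c("A", "B")[clu]
    names(cluLab) <- sampleId

    ## site positions: planted triplet plus background sites
    tripletPos <- sort(c(config@focalPosition,
                         config@focalPosition + config@partnerOffsets))
    nBg <- nV - 3L
    pool <- sample.int(config@regionLength, min(config@regionLength, nBg + 10L))
    pool <- setdiff(pool, tripletPos)
    if (length(pool) < nBg)
        stop("region too short to place ", nBg, " background variants",
             call. = FALSE)
    bgPos <- sort(pool[seq_len(nBg)])
    pos <- sort(c(tripletPos, bgPos))
    isTriplet <- pos %in% tripletPos

    ## Balding-Nichols background allele frequencies per cluster
    F <- config@clusterFst
    pAnc <- stats::runif(nBg, config@backgroundMafRange[1],
                         config@backgroundMafRange[2])
    if (F > 0) {
        a <- pAnc * (1 - F) / F
        b <- (1 - pAnc) * (1 - F) / F
        pClust <- cbind(stats::rbeta(nBg, a, b), stats::rbeta(nBg, a, b))
        pClust <- pmin(pmax(pClust, 1e-6), 1 - 1e-6)
    } else {
        pClust <- cbind(pAnc, pAnc)
    }

    ## founder haplotypes over background sites
    h1bg <- vapply(seq_len(nS), function(i) .drawHap(pClust, clu[i]),
                   integer(nBg))
    h2bg <- vapply(seq_len(nS), function(i) .drawHap(pClust, clu[i]),
                   integer(nBg))

    ## pedigree pairs: per-site Mendelian transmission (sites are in linkage
    ## equilibrium, so free recombination between sites is harmless and keeps
    ## realized sibling kinship concentrated at its 0.25 expectation)
    pp <- config@pedigreePairs
    pedIdx <- integer(0)
    pick <- function(x, y) ifelse(stats::rbinom(nBg, 1L, 0.5) == 1L, x, y)
    if (nrow(pp)) {
        for (r in seq_len(nrow(pp))) {
            ia <- as.integer(pp$sample_a[r])
            ib <- as.integer(pp$sample_b[r])
            cl <- clu[ia]
            if (pp$relation[r] == "parent_offspring") {
                ## a keeps founder haplotypes; b inherits one gamete from a
                ## and one from an unobserved mate of the same cluster
                h1bg[, ib] <- pick(h1bg[, ia], h2bg[, ia])
                h2bg[, ib] <- .drawHap(pClust, cl)
            } else { # full_sibling: both from two unobserved parents
                m1 <- .drawHap(pClust, cl); m2 <- .drawHap(pClust, cl)
                f1 <- .drawHap(pClust, cl); f2 <- .drawHap(pClust, cl)
                h1bg[, ia] <- pick(m1, m2); h2bg[, ia] <- pick(f1, f2)
                h1bg[, ib] <- pick(m1, m2); h2bg[, ib] <- pick(f1, f2)
            }
            pedIdx <- c(pedIdx, ia, ib)
        }
    }

    ## planted triplet: alt allele on haplotype 1 of each carrier
    h1 <- matrix(0L, nV, nS)
    h2 <- matrix(0L, nV, nS)
    h1[!isTriplet, ] <- h1bg
    h2[!isTriplet, ] <- h2bg
    carrierIdx <- integer(0)
    if (config@nCarriers > 0L) {
        eligible <- setdiff(seq_len(nS), pedIdx)
        if (length(eligible) < config@nCarriers)
            stop("nCarriers: not enough non-pedigree samples to place carriers",
                 call. = FALSE)
        carrierIdx <- eligible[seq_len(config@nCarriers)]
        h1[isTriplet, carrierIdx] <- 1L
    }

    dos <- h1 + h2
    storage.mode(dos) <- "double"
    if (config@missingRate > 0) {
        drop <- stats::runif(length(dos)) < config@missingRate
        dos[drop] <- NA_real_
    }

    ## annotation
    ref <- sample(c("A", "C", "G", "T"), nV, replace = TRUE)
    alt <- vapply(ref, function(r)
        sample(setdiff(c("A", "C", "G", "T"), r), 1L), character(1))
    consequence <- character(nV)
    gene <- rep(NA_character_, nV)
    refAf <- numeric(nV)
    bgi <- which(!isTriplet)
    consequence[bgi] <- sample(
        c("intron_variant", "synonymous_variant", "missense_variant",
          "intergenic_variant"),
        nBg, replace = TRUE, prob = c(0.4, 0.2, 0.2, 0.2))
    geneBlock <- pmin(50L, 1L + (pos[bgi] - 1L) %/%
                          ceiling(config@regionLength / 50))
    gene[bgi] <- ifelse(consequence[bgi] == "intergenic_variant",
                        NA_character_, sprintf("GENE%02d", geneBlock))
    refAf[bgi] <- pAnc
    fi <- which(pos == config@focalPosition)
    consequence[fi] <- "stop_gained"
    gene[fi] <- "FANCI"
    refAf[fi] <- 4.276e-05
    partnerPos <- config@focalPosition + config@partnerOffsets
    pidx <- match(partnerPos, pos)
    consequence[pidx] <- "intergenic_variant"
    gene[pidx] <- NA_character_
    refAf[pidx] <- c(7.3e-05, 1.8e-04)

    vid <- paste(chrom, pos, ref, alt, sep = ":")
    vtab <- data.frame(chrom = chrom, pos = pos, variant_id = vid,
                       ref = ref, alt = alt, consequence = consequence,
                       gene = gene, ref_af = refAf,
                       stringsAsFactors = FALSE)
    cohort <- GenotypeCohort(dos, vtab, sampleIds = sampleId)
    metadata(cohort)$haplotypes <- list(h1 = h1, h2 = h2)
    metadata(cohort)$seed <- config@seed

    ke <- data.frame(sample_a = character(), sample_b = character(),
                     relation = character(), expected_phi = numeric(),
                     stringsAsFactors = FALSE)
    if (nrow(pp))
        ke <- data.frame(sample_a = sampleId[as.integer(pp$sample_a)],
                         sample_b = sampleId[as.integer(pp$sample_b)],
                         relation = pp$relation,
                         expected_phi = 0.25,
                         stringsAsFactors = FALSE)
    truth <- new("TruthSet",
                 plantedVariant = vid[fi],
                 carrierIds = sampleId[carrierIdx],
                 haplotypePartnerIds = vid[pidx],
                 kinshipExpectations = ke,
                 clusterLabels = cluLab)
    list(cohort = cohort, truth = truth)
}

#' Write a TruthSet to plain-text tables
#'
#' Serializes the simulator's ground truth as small TSV files next to the
#' cohort VCF: one key--value table for the planted variant and its carriers
#' and partners, one table of pedigree kinship expectations, and one table of
#' cluster labels.
#'
#' @param truth a \linkS4class{TruthSet}.
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
writeTruthSet <- function(truth, dir) {
    stopifnot(is(truth, "TruthSet"))
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    p1 <- file.path(dir, "truth_planted.tsv")
    .writeTsv(data.frame(
        key = c("planted_variant", "carrier_ids", "haplotype_partner_ids"),
        value = c(paste(truth@plantedVariant, collapse = ","),
                  paste(truth@carrierIds, collapse = ","),
                  paste(truth@haplotypePartnerIds, collapse = ","))), p1)
    p2 <- file.path(dir, "truth_kinship.tsv")
    .writeTsv(truth@kinshipExpectations, p2)
    p3 <- file.path(dir, "truth_clusters.tsv")
    .writeTsv(data.frame(sample_id = names(truth@clusterLabels),
                         cluster = unname(truth@clusterLabels)), p3)
    invisible(c(p1, p2, p3))
}
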