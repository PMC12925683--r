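test_that("planted variant is heterozygous in exactly the configured carriers", {
    sim <- simulateCohort(cohortSimConfig(nSamples = 50, nVariants = 100,
                                          nCarriers = 3, seed = 1))
    d <- dosage(sim$cohort)
    truth <- sim$truth
    focal <- d[plantedVariant(truth), ]
    expect_equal(sum(focal), 3)
    expect_true(all(focal[carrierIds(truth)] == 1))
    expect_true(all(focal[setdiff(names(focal), carrierIds(truth))] == 0))
    # both haplotype partners share the focal genotype vector exactly
    for (pid in haplotypePartnerIds(truth))
        expect_equal(unname(d[pid, ]), unname(focal))
})

test_that("zero-carrier configuration leaves the triplet monomorphic", {
    sim <- simulateCohort(cohortSimConfig(nSamples = 20, nVariants = 50,
                                          nCarriers = 0, seed = 2))
    d <- dosage(sim$cohort)
    expect_equal(sum(d[plantedVariant(sim$truth), ]), 0)
    expect_length(carrierIds(sim$truth), 0)
    cand <- filterLofCandidates(sim$cohort, genePanel("FANCI"))
    expect_equal(nrow(cand), 0)
})

test_that("simulation is deterministic under a fixed seed, down to VCF bytes", {
    cfg <- cohortSimConfig(nSamples = 15, nVariants = 40, nCarriers = 2,
                           seed = 33)
    s1 <- simulateCohort(cfg)
    s2 <- simulateCohort(cfg)
    expect_identical(dosage(s1$cohort), dosage(s2$cohort))
    expect_identical(s1$truth, s2$truth)
    p1 <- tempfile(fileext = ".vcf"); p2 <- tempfile(fileext = ".vcf")
    writeCohortVcf(s1$cohort, p1)
    writeCohortVcf(s2$cohort, p2)
    expect_identical(readBin(p1, "raw", file.size(p1)),
                     readBin(p2, "raw", file.size(p2)))
    # a different seed changes the genotypes
    s3 <- simulateCohort(cohortSimConfig(nSamples = 15, nVariants = 40,
                                         nCarriers = 2, seed = 34))
    expect_false(identical(dosage(s1$cohort), dosage(s3$cohort)))
})

test_that("cluster divergence responds to the Fst parameter", {
    divergence <- function(fst, seed) {
        sim <- simulateCohort(cohortSimConfig(
            nSamples = 200, nVariants = 2000, nCarriers = 0,
            clusterFractions = c(0.5, 0.5), clusterFst = fst,
            backgroundMafRange = c(0.05, 0.5), seed = seed))
        d <- dosage(sim$cohort)
        lab <- clusterLabels(sim$truth)
        fA <- rowMeans(d[, lab == "A"]) / 2
        fB <- rowMeans(d[, lab == "B"]) / 2
        mean(abs(fA - fB))
    }
    for (seed in 1:10)
        expect_gt(divergence(0.05, seed), divergence(0, seed))
})

test_that("genotypes are legal and background frequencies honor the MAF range", {
    sim <- simulateCohort(cohortSimConfig(
        nSamples = 80, nVariants = 300, nCarriers = 3,
        backgroundMafRange = c(0.2, 0.4), missingRate = 0.05, seed = 9))
    d <- dosage(sim$cohort)
    expect_true(all(is.na(d) | d %in% 0:2))
    miss <- mean(is.na(d))
    expect_gt(miss, 0.03); expect_lt(miss, 0.07)
    bg <- setdiff(variantIds(sim$cohort),
                  c(plantedVariant(sim$truth),
                    haplotypePartnerIds(sim$truth)))
    af <- rowMeans(d[bg, ], na.rm = TRUE) / 2
    # binomial noise around ancestral frequencies drawn in [0.2, 0.4]
    expect_gt(min(af), 0.05)
    expect_lt(max(af), 0.55)
})

test_that("pedigree pairs are recorded with the expected kinship", {
    pp <- data.frame(sample_a = c(1L, 3L), sample_b = c(2L, 4L),
                     relation = c("parent_offspring", "full_sibling"))
    sim <- simulateCohort(cohortSimConfig(nSamples = 12, nVariants = 50,
                                          nCarriers = 2, pedigreePairs = pp,
                                          seed = 4))
    ke <- kinshipExpectations(sim$truth)
    expect_equal(nrow(ke), 2)
    expect_equal(ke$expected_phi, c(0.25, 0.25))
    expect_setequal(ke$relation, c("parent_offspring", "full_sibling"))
    # carriers avoid pedigree members
    expect_false(any(carrierIds(sim$truth) %in%
                     c(ke$sample_a, ke$sample_b)))
})

test_that("invalid configurations are rejected naming the offending field", {
    expect_error(cohortSimConfig(nSamples = 10, nCarriers = 11), "nCarriers")
    expect_error(cohortSimConfig(clusterFractions = c(0.6, 0.6)),
                 "clusterFractions")
    expect_error(cohortSimConfig(partnerOffsets = c(0L, 500L)),
                 "partnerOffsets")
    expect_error(cohortSimConfig(partnerOffsets = c(-150000L, 500L)),
                 "partnerOffsets")
    expect_error(cohortSimConfig(backgroundMafRange = c(0, 0.6)),
                 "backgroundMafRange")
    expect_error(cohortSimConfig(clusterFst = 1), "clusterFst")
    expect_error(cohortSimConfig(pedigreePairs = data.frame(
        sample_a = 1L, sample_b = 2L, relation = "cousin")), "relation")
})
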