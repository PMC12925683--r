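test_that("identical genotype vectors give r2 = 1 and d_prime = 1", {
    g <- c(0, 1, 0, 1, 2, 0, 0, 1)
    d <- rbind(g, g, deparse.level = 0)
    colnames(d) <- sprintf("s%d", 1:8)
    gc <- tinyCohort(d, pos = c(1000L, 2000L))
    res <- ldScan(gc, variantIds(gc)[1], minNonref = 1)
    expect_equal(nrow(res), 1)
    expect_equal(res$r2, 1, tolerance = 1e-12)
    expect_equal(res$d_prime, 1, tolerance = 1e-9)
    expect_equal(res$distance_bp, 1000)
})

test_that("the window is inclusive at its boundary and excludes beyond it", {
    set.seed(2)
    d <- matrix(rbinom(4 * 30, 2, 0.3), 4, 30,
                dimnames = list(NULL, sprintf("s%02d", 1:30)))
    gc <- tinyCohort(d, pos = c(500000L, 400000L, 600000L, 600001L))
    res <- ldScan(gc, variantIds(gc)[1], windowBp = 100000, minNonref = 1)
    expect_setequal(res$distance_bp, c(-100000, 100000))
})

test_that("partners below the non-reference call threshold are excluded", {
    d <- rbind(c(0, 1, 1, 1, 0, 0),
               c(0, 1, 1, 0, 0, 0),   # 2 non-ref calls
               c(0, 1, 1, 1, 0, 0))   # 3 non-ref calls
    colnames(d) <- sprintf("s%d", 1:6)
    gc <- tinyCohort(d, pos = c(1000L, 2000L, 3000L))
    res <- ldScan(gc, variantIds(gc)[1], minNonref = 3)
    expect_equal(res$partner_id, variantIds(gc)[3])
    expect_equal(res$n_nonref_partner, 3)
})

test_that("EM haplotype frequencies agree with direct counting when phase is determined", {
    # low-frequency background makes double-het-free pairs common
    sim <- simulateCohort(cohortSimConfig(nSamples = 60, nVariants = 200,
                                          nCarriers = 3,
                                          backgroundMafRange = c(0.02, 0.1),
                                          seed = 31))
    haps <- S4Vectors::metadata(sim$cohort)$haplotypes
    d <- dosage(sim$cohort)
    fi <- match(plantedVariant(sim$truth), variantIds(sim$cohort))
    # triplet pairs: strong LD pins the double-het phase at the ML optimum
    for (pid in haplotypePartnerIds(sim$truth)) {
        pi <- match(pid, variantIds(sim$cohort))
        dpEm <- RareTriplet:::.dPrimeFromFreqs(
            emHaplotypeFreqs(d[fi, ], d[pi, ]))
        dpDirect <- haplotypeDPrime(c(haps$h1[fi, ], haps$h2[fi, ]),
                                    c(haps$h1[pi, ], haps$h2[pi, ]))
        expect_equal(dpEm, dpDirect, tolerance = 1e-6)
        expect_equal(dpEm, 1, tolerance = 1e-6)
    }
    # background pairs without double heterozygotes: phase is unambiguous,
    # so EM fixed counts must reproduce the realized haplotype counts
    tested <- 0
    for (i in seq(4, 198, by = 2)) {
        j <- i + 1
        if (i == fi || j == fi) next
        if (sum(d[i, ] == 1 & d[j, ] == 1) > 0) next
        f <- emHaplotypeFreqs(d[i, ], d[j, ])
        h1 <- c(haps$h1[i, ], haps$h2[i, ])
        h2 <- c(haps$h1[j, ], haps$h2[j, ])
        fDirect <- c(ab = mean(h1 == 0 & h2 == 0),
                     aB = mean(h1 == 0 & h2 == 1),
                     Ab = mean(h1 == 1 & h2 == 0),
                     AB = mean(h1 == 1 & h2 == 1))
        expect_equal(f, fDirect, tolerance = 1e-9)
        tested <- tested + 1
    }
    expect_gt(tested, 5)
})

test_that("EM marginals always match the dosage allele frequencies", {
    set.seed(6)
    for (rep in 1:20) {
        g1 <- rbinom(40, 2, runif(1, 0.1, 0.5))
        g2 <- rbinom(40, 2, runif(1, 0.1, 0.5))
        if (var(g1) == 0 || var(g2) == 0) next
        f <- emHaplotypeFreqs(g1, g2)
        expect_equal(sum(f), 1, tolerance = 1e-9)
        expect_equal(f[["AB"]] + f[["Ab"]], mean(g1) / 2, tolerance = 1e-6)
        expect_equal(f[["AB"]] + f[["aB"]], mean(g2) / 2, tolerance = 1e-6)
    }
})

test_that("r2 and d_prime are invariant under allele relabeling", {
    set.seed(11)
    d <- matrix(rbinom(2 * 50, 2, 0.3), 2, 50,
                dimnames = list(NULL, sprintf("s%02d", 1:50)))
    gc <- tinyCohort(d, pos = c(1000L, 2000L))
    base <- ldScan(gc, variantIds(gc)[1], minNonref = 0)
    flip <- tinyCohort(rbind(d[1, ], 2 - d[2, ], deparse.level = 0),
                       pos = c(1000L, 2000L))
    flipped <- ldScan(flip, variantIds(flip)[1], minNonref = 0)
    expect_equal(flipped$r2, base$r2, tolerance = 1e-12)
    expect_equal(flipped$d_prime, base$d_prime, tolerance = 1e-6)
})

test_that("the heatmap matrix is symmetric, bounded and matches pairwise scans", {
    sim <- simulateCohort(cohortSimConfig(nSamples = 50, nVariants = 12,
                                          nCarriers = 2,
                                          regionLength = 10000L,
                                          focalPosition = 5000L,
                                          partnerOffsets = c(-2000L, 2000L),
                                          seed = 13))
    m <- ldHeatmapMatrix(sim$cohort)
    expect_true(isSymmetric(m))
    expect_true(all(diag(m) == 1))
    expect_true(all(m >= -1e-9 & m <= 1 + 1e-9))
    # cross-check entries against ldScan with filters disabled
    ids <- rownames(m)
    res <- ldScan(sim$cohort, ids[1], windowBp = 10000, minNonref = 0)
    for (k in seq_len(nrow(res))) {
        pid <- res$partner_id[k]
        if (pid %in% ids)
            expect_equal(res$r2[k], m[ids[1], pid], tolerance = 1e-12)
    }
})

test_that("planted haplotype partners are recovered exactly across seeds", {
    for (seed in 1:3) {
        sim <- simulateCohort(cohortSimConfig(seed = seed))
        ld <- ldScan(sim$cohort, plantedVariant(sim$truth))
        partners <- perfectLdPartners(ld)
        expect_setequal(partners, haplotypePartnerIds(sim$truth))
        hit <- ld[ld$partner_id %in% partners, ]
        expect_equal(hit$r2, c(1, 1), tolerance = 1e-9)
        expect_equal(hit$d_prime, c(1, 1), tolerance = 1e-6)
        bg <- ld[!ld$partner_id %in% partners, ]
        expect_lt(mean(bg$r2, na.rm = TRUE), 0.05)
    }
})

test_that("degenerate LD inputs raise informative errors", {
    d <- matrix(c(0, 1, 1, 0, 0, 0), 2, 3, byrow = TRUE,
                dimnames = list(NULL, c("a", "b", "c")))
    gc <- tinyCohort(d, pos = c(100L, 200L))
    expect_error(ldScan(gc, "nope"), "not found")
    expect_error(ldScan(gc, variantIds(gc)[2]), "monomorphic")
    expect_error(ldHeatmapMatrix(gc), "polymorphic")
    expect_identical(perfectLdPartners(
        data.frame(partner_id = character(), r2 = numeric())), character(0))
})
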