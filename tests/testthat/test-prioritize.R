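test_that("a rare panel stop-gain with carriers is retained; consequence matters", {
    d <- matrix(c(0, 1, 1, 1, 0,   # stop-gain, 3 carriers
                  0, 1, 1, 1, 0),  # same genotypes, missense
                nrow = 2, byrow = TRUE,
                dimnames = list(NULL, sprintf("S%d", 1:5)))
    gc <- tinyCohort(d, consequence = c("stop_gained", "missense_variant"),
                     gene = c("FANCI", "FANCI"),
                     ref_af = c(4.276e-05, 4.276e-05))
    out <- filterLofCandidates(gc, genePanel("FANCI"))
    expect_equal(nrow(out), 1)
    expect_equal(out$consequence, "stop_gained")
    expect_equal(out$carrier_count, 3)
    expect_equal(out$carrier_ids, "S2,S3,S4")
})

test_that("filter output equals a brute-force re-evaluation of the predicates", {
    for (seed in 1:5) {
        set.seed(seed)
        nV <- 60; nS <- 12
        d <- matrix(rbinom(nV * nS, 2, 0.15), nV, nS,
                    dimnames = list(NULL, sprintf("S%02d", 1:nS)))
        csq <- sample(c("stop_gained", "missense_variant", "intron_variant"),
                      nV, replace = TRUE)
        gene <- sample(c("FANCI", "GENE01", NA), nV, replace = TRUE)
        af <- sample(c(NA, 1e-5, 4e-4, 0.01), nV, replace = TRUE)
        gc <- tinyCohort(d, consequence = csq, gene = gene, ref_af = af)
        panel <- genePanel(c("FANCI", "GENE01"))
        out <- filterLofCandidates(gc, panel, mafThreshold = 5e-4)

        expectIds <- character(0)
        for (i in seq_len(nV)) {
            inPanel <- !is.na(gene[i]) && gene[i] %in% c("FANCI", "GENE01")
            isLof <- csq[i] == "stop_gained"
            rare <- is.na(af[i]) || af[i] < 5e-4
            hasCarrier <- sum(d[i, ] >= 1) >= 1
            if (inPanel && isLof && rare && hasCarrier)
                expectIds <- c(expectIds, variantIds(gc)[i])
        }
        expect_setequal(out$variant_id, expectIds)
        # sort order: descending carrier count, ties by position
        if (nrow(out) > 1) {
            expect_true(all(diff(out$carrier_count) <= 0))
            ties <- split(out$pos, out$carrier_count)
            expect_true(all(vapply(ties, function(p) !is.unsorted(p),
                                   logical(1))))
        }
    }
})

test_that("raising the MAF threshold never removes a retained variant", {
    gc <- randomCohort(80, 10, seed = 3)
    # give everything panel gene + stop-gain so only the MAF predicate varies
    m <- S4Vectors::mcols(SummarizedExperiment::rowRanges(gc))
    set.seed(4)
    v <- data.frame(chrom = "15", pos = GenomicRanges::start(variantInfo(gc)),
                    variant_id = m$variant_id, ref = m$ref, alt = m$alt,
                    consequence = "stop_gained", gene = "FANCI",
                    ref_af = runif(80, 0, 0.01))
    gc <- GenotypeCohort(dosage(gc), v)
    panel <- genePanel("FANCI")
    prev <- character(0)
    for (thr in c(1e-4, 1e-3, 5e-3, 1e-2, 0.5)) {
        cur <- filterLofCandidates(gc, panel, mafThreshold = thr)$variant_id
        expect_true(all(prev %in% cur))
        prev <- cur
    }
})

test_that("filtering is idempotent", {
    sim <- simulateCohort(cohortSimConfig(nSamples = 30, nVariants = 80,
                                          nCarriers = 3, seed = 6))
    panel <- genePanel("FANCI")
    out1 <- filterLofCandidates(sim$cohort, panel)
    sub <- sim$cohort[match(out1$variant_id, variantIds(sim$cohort)), ]
    out2 <- filterLofCandidates(sub, panel)
    expect_equal(out2, out1)
})

test_that("missing reference MAF passes by default and fails in strict mode", {
    d <- matrix(c(0, 1, 0), nrow = 1, dimnames = list(NULL, c("a", "b", "c")))
    gc <- tinyCohort(d, consequence = "stop_gained", gene = "FANCI",
                     ref_af = NA_real_)
    panel <- genePanel("FANCI")
    expect_equal(nrow(filterLofCandidates(gc, panel)), 1)
    expect_equal(nrow(filterLofCandidates(gc, panel, missingMaf = "fail")), 0)
})

test_that("interval membership rescues variants lacking a gene symbol", {
    d <- matrix(c(1, 0, 1, 0), nrow = 2, byrow = TRUE,
                dimnames = list(NULL, c("a", "b")))
    gc <- tinyCohort(d, pos = c(150L, 9000L),
                     consequence = c("stop_gained", "stop_gained"),
                     gene = c(NA, NA), ref_af = c(NA, NA))
    iv <- GenomicRanges::GRanges("15", IRanges::IRanges(100, 200))
    panel <- genePanel("FANCI", intervals = iv)
    out <- filterLofCandidates(gc, panel)
    expect_equal(out$pos, 150)
})

test_that("an empty panel is rejected and the simulated planted variant is recovered", {
    expect_error(genePanel(character(0)), "at least one gene")
    sim <- simulateCohort(cohortSimConfig(nSamples = 40, nVariants = 500,
                                          nCarriers = 3, seed = 8))
    out <- filterLofCandidates(sim$cohort, genePanel("FANCI"))
    expect_equal(out$variant_id, plantedVariant(sim$truth))
    expect_setequal(strsplit(out$carrier_ids, ",")[[1]],
                    carrierIds(sim$truth))
})
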