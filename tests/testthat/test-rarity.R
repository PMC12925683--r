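test_that("carrier test matches the enumeration oracle and fisher.test", {
    # moderate tables against the pure-choose() oracle, both alternatives
    set.seed(3)
    for (rep in 1:40) {
        N <- sample(8:30, 1)
        n <- sample(1:(N - 1), 1)
        K <- sample(1:(N - 1), 1)
        a <- sample(max(0, n - (N - K)):min(K, n), 1)
        tab <- carrierTable(a, n - a, K - a, (N - K) - (n - a))
        pg <- fisherCarrierTest(tab, "greater")
        pt <- fisherCarrierTest(tab, "two_sided")
        expect_equal(pg, enumTailOracle(a, K, n, N, "greater"),
                     tolerance = 1e-12)
        expect_equal(pt, enumTailOracle(a, K, n, N, "two_sided"),
                     tolerance = 1e-12)
        # independent implementation cross-check
        m <- matrix(c(a, n - a, K - a, (N - K) - (n - a)), 2, byrow = TRUE)
        expect_equal(pg, fisher.test(m, alternative = "greater")$p.value,
                     tolerance = 1e-9)
        expect_equal(pt, fisher.test(m)$p.value, tolerance = 1e-9)
    }
})

test_that("degenerate margins return 1 with a warning", {
    expect_warning(p <- fisherCarrierTest(carrierTable(0, 10, 0, 10)),
                   "degenerate")
    expect_equal(p, 1)
    expect_warning(p2 <- fisherCarrierTest(carrierTable(10, 0, 10, 0)),
                   "degenerate")
    expect_equal(p2, 1)
    expect_error(carrierTable(-1, 5, 5, 5), "non-negative")
    expect_error(carrierTable(0, 0, 5, 5), "cohort margin")
})

test_that("the upper tail is monotone in the cohort carrier count", {
    # margins fixed: K = 10 carriers, n = 20 cohort, N = 200
    ps <- vapply(0:10, function(a)
        RareTriplet:::.hyperTail(a, K = 10, n = 20, N = 200, "greater"),
        numeric(1))
    expect_true(all(diff(ps) < 0))
    expect_equal(ps[1], 1)
})

test_that("trio counts are exact and match brute-force enumeration", {
    expect_identical(nTrios(100, 3), 161700)
    expect_identical(nTrios(3, 3), 1)
    expect_warning(z <- nTrios(2, 3), "exceeds")
    expect_identical(z, 0)
    # explicit triple-loop count at n = 25
    n <- 25; cnt <- 0
    for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n)
        cnt <- cnt + 1
    expect_identical(nTrios(25, 3), cnt)
    expect_equal(cnt, 2300)
    # closed form n(n-1)(n-2)/6 across the full supported range
    ns <- 3:1000
    expect_identical(vapply(ns, nTrios, numeric(1), trioSize = 3),
                     ns * (ns - 1) * (ns - 2) / 6)
})

test_that("trio probability honors its scale modes and monotonicities", {
    tp <- trioProbability(rarityParams())
    expect_equal(tp$n_snps_effective, 20000 * 26.288)
    expect_equal(tp$per_trio_probability, 525760 * (5e-5)^3,
                 tolerance = 1e-12)
    expect_equal(signif(tp$per_trio_probability, 2), 6.6e-08)
    # literal per-bp mode is exactly 1000-fold larger
    tpBp <- trioProbability(rarityParams(), lengthUnit = "bp")
    expect_equal(tpBp$per_trio_probability,
                 1000 * tp$per_trio_probability, tolerance = 1e-12)
    expect_equal(tpBp$length_unit, "bp")
    # small worked example: 1000 genes x 1 kb, MAF 1e-3
    tiny <- trioProbability(rarityParams(nGenes = 1000,
                                         medianGeneLength = 1000,
                                         maf = 1e-3))
    expect_equal(tiny$per_trio_probability, 1e-6, tolerance = 1e-12)
    # strictly increasing in MAF and in gene count
    p1 <- trioProbability(rarityParams(maf = 1e-5))$per_trio_probability
    p2 <- trioProbability(rarityParams(maf = 2e-5))$per_trio_probability
    expect_gt(p2, p1)
    g1 <- trioProbability(rarityParams(nGenes = 10000))$per_trio_probability
    g2 <- trioProbability(rarityParams(nGenes = 20000))$per_trio_probability
    expect_gt(g2, g1)
    expect_error(rarityParams(maf = 0), "maf")
    expect_error(rarityParams(trioSize = 200, cohortN = 100), "trioSize")
})

test_that("FDR estimate: linear and complement forms agree when small", {
    f <- fdrEstimate(6.56e-8, 161700)
    expect_equal(signif(f$fdr, 3), 0.0106)
    expect_lt(abs(f$fdr - f$fdr_complement), 1e-4)
    expect_equal(fdrEstimate(0, 161700)$fdr, 0)
    f2 <- fdrEstimate(1e-6, 5000)
    expect_equal(f2$fdr, 5e-3, tolerance = 1e-12)
    expect_lt(abs(f2$fdr - f2$fdr_complement), 1.3e-5)
    # capping at 1
    expect_equal(fdrEstimate(0.5, 100)$fdr, 1)
})

test_that("Bonferroni adjustment multiplies and caps", {
    b <- bonferroniAdjust(1.57e-7, c(443769, 179774))
    expect_equal(unname(b[1]), 1.57e-7 * 443769, tolerance = 1e-12)
    expect_equal(unname(b[2]), 1.57e-7 * 179774, tolerance = 1e-12)
    expect_equal(unname(bonferroniAdjust(0.5, 3)), 1)
    expect_named(b, c("m_443769", "m_179774"))
})

test_that("the rarity report chains its components consistently", {
    rep <- rarityReport(carrierTable(3, 98, 56, 589929))
    expect_equal(rep@bonferroni,
                 pmin(1, rep@fisherP * c(443769, 179774)),
                 ignore_attr = TRUE)
    expect_equal(rep@fdrEstimate,
                 min(1, rep@perTrioProbability * rep@nTrios))
    expect_equal(rep@nTrios, 161700)
    out <- capture.output(show(rep))
    expect_true(any(grepl("per-trio probability", out)))
    path <- tempfile(fileext = ".tsv")
    writeRarityReport(rep, path)
    tab <- read.delim(path)
    expect_equal(as.numeric(tab$value[tab$key == "n_trios"]), 161700)
})

test_that("reference counts are read from the packaged table", {
    path <- system.file("extdata", "reference_counts.tsv",
                        package = "RareTriplet")
    rc <- readReferenceCounts(path)
    expect_equal(unname(rc["carriers"]), 56)
    expect_equal(unname(rc["noncarriers"]), 589929)
    expect_error(readReferenceCounts(path, "martian"), "not found")
})
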