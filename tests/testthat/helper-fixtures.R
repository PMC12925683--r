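# Shared fixture builders. Everything is generated in code; no data files.

## Minimal cohort from a dosage matrix, with sensible annotation defaults
## that individual tests override as needed.
tinyCohort <- function(dosage, chrom = "15", pos = NULL,
                       consequence = NULL, gene = NULL, ref_af = NULL,
                       sampleIds = NULL) {
    nV <- nrow(dosage)
    if (is.null(pos)) pos <- seq_len(nV) * 1000L
    if (is.null(consequence)) consequence <- rep("intron_variant", nV)
    if (is.null(gene)) gene <- rep(NA_character_, nV)
    if (is.null(ref_af)) ref_af <- rep(NA_real_, nV)
    if (is.null(sampleIds)) {
        sampleIds <- colnames(dosage)
        if (is.null(sampleIds))
            sampleIds <- sprintf("S%02d", seq_len(ncol(dosage)))
    }
    ref <- rep(c("A", "C", "G", "T"), length.out = nV)
    alt <- rep(c("T", "G", "A", "C"), length.out = nV)
    v <- data.frame(chrom = chrom, pos = pos,
                    variant_id = paste(chrom, pos, ref, alt, sep = ":"),
                    ref = ref, alt = alt, consequence = consequence,
                    gene = gene, ref_af = ref_af,
                    stringsAsFactors = FALSE)
    GenotypeCohort(dosage, v, sampleIds = sampleIds)
}

## Random cohort for property tests: independent sites, optional missingness.
randomCohort <- function(nVariants, nSamples, seed, mafRange = c(0.1, 0.5),
                         missingRate = 0) {
    set.seed(seed)
    p <- runif(nVariants, mafRange[1], mafRange[2])
    d <- matrix(rbinom(nVariants * nSamples, 2, rep(p, nSamples)),
                nVariants, nSamples)
    storage.mode(d) <- "double"
    if (missingRate > 0)
        d[runif(length(d)) < missingRate] <- NA
    colnames(d) <- sprintf("S%03d", seq_len(nSamples))
    tinyCohort(d)
}

## Write VCF body lines (plus standard header) to a temp file.
writeVcfText <- function(bodyLines, samples = c("S1", "S2", "S3"),
                         infoDefs = TRUE) {
    path <- tempfile(fileext = ".vcf")
    hdr <- c("##fileformat=VCFv4.2",
             if (infoDefs) c(
                 '##INFO=<ID=CSQ_TERM,Number=1,Type=String,Description="c">',
                 '##INFO=<ID=GENE,Number=1,Type=String,Description="g">',
                 '##INFO=<ID=REF_AF,Number=1,Type=Float,Description="f">'),
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"))
    writeLines(c(hdr, bodyLines), path)
    path
}

## Independent enumeration oracle for the exact conditional test on a 2x2
## table with margins (K carriers, n cohort, N total): pure choose()
## arithmetic, no d/phyper.
enumTailOracle <- function(a, K, n, N, alternative) {
    support <- max(0, n - (N - K)):min(K, n)
    probs <- choose(K, support) * choose(N - K, n - support) / choose(N, n)
    if (alternative == "greater") {
        sum(probs[support >= a])
    } else {
        pa <- probs[support == a]
        sum(probs[probs <= pa * (1 + 1e-7)])
    }
}
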