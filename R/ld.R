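#' Two-locus haplotype frequencies by EM
#'
#' Maximum-likelihood haplotype frequencies for a pair of biallelic loci from
#' unphased diploid dosages, via expectation--maximization. Only the
#' double-heterozygote genotype is phase-ambiguous; the E-step splits it
#' between the two phase configurations in proportion to their current
#' likelihood. Frequencies are initialized at linkage equilibrium.
#'
#' @param g1,g2 numeric dosage vectors (0/1/2, \code{NA} allowed) of equal
#'   length; samples missing at either locus are dropped.
#' @param maxit maximum EM iterations.
#' @param tol convergence tolerance on the largest frequency change.
#' @return named numeric vector of the four haplotype frequencies
#'   \code{c(ab, aB, Ab, AB)}, where \code{A}/\code{B} denote the alternate
#'   alleles at locus 1 and 2.
#' @examples
#' g <- c(0, 1, 2, 1, 0)
#' emHaplotypeFreqs(g, g)
#' @export
emHaplotypeFreqs <- function(g1, g2, maxit = 50L, tol = 1e-8) {
    keep <- !is.na(g1) & !is.na(g2)
    g1 <- g1[keep]; g2 <- g2[keep]
    n <- length(g1)
    if (n == 0L)
        stop("no samples genotyped at both loci", call. = FALSE)
    pA <- mean(g1) / 2
    pB <- mean(g2) / 2
    nDH <- sum(g1 == 1 & g2 == 1)       # double heterozygotes
    ## haplotype counts fixed by the unambiguous genotype classes; only the
    ## double heterozygote leaves the allele pairing open
    cnt <- table(factor(g1, levels = 0:2), factor(g2, levels = 0:2))
    ## fixed AB haplotypes contributed by each unambiguous genotype class
    fixedAB <- 2 * cnt["2", "2"] + cnt["2", "1"] + cnt["1", "2"]
    fixedAb <- 2 * cnt["2", "0"] + cnt["2", "1"] + cnt["1", "0"]
    fixedaB <- 2 * cnt["0", "2"] + cnt["0", "1"] + cnt["1", "2"]
    fixedab <- 2 * cnt["0", "0"] + cnt["0", "1"] + cnt["1", "0"]
    f <- c(ab = (1 - pA) * (1 - pB), aB = (1 - pA) * pB,
           Ab = pA * (1 - pB), AB = pA * pB)
    for (it in seq_len(maxit)) {
        ## E-step: split double hets between AB/ab and Ab/aB phases
        wCis <- f[["AB"]] * f[["ab"]]
        wTrans <- f[["Ab"]] * f[["aB"]]
        frac <- if (wCis + wTrans > 0) wCis / (wCis + wTrans) else 0.5
        nAB <- fixedAB + nDH * frac
        nab <- fixedab + nDH * frac
        nAb <- fixedAb + nDH * (1 - frac)
        naB <- fixedaB + nDH * (1 - frac)
        fNew <- c(ab = nab, aB = naB, Ab = nAb, AB = nAB) / (2 * n)
        delta <- max(abs(fNew - f))
        f <- fNew
        if (delta < tol) break
    }
    f
}

## D' from four haplotype frequencies (named ab, aB, Ab, AB).
.dPrimeFromFreqs <- function(f) {
    pA <- f[["AB"]] + f[["Ab"]]
    pB <- f[["AB"]] + f[["aB"]]
    D <- f[["AB"]] - pA * pB
    dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
            else min(pA * pB, (1 - pA) * (1 - pB))
    if (dmax <= 0) return(NA_real_)
    min(abs(D) / dmax, 1)
}

#' D-prime from phased haplotypes
#'
#' Direct-counting estimate of the normalized disequilibrium coefficient from
#' phased haplotype indicator vectors (one entry per haplotype, 0/1 alternate
#' allele). Serves as the phased oracle against which the unphased EM
#' estimate is validated.
#'
#' @param h1,h2 0/1 vectors of equal length, one entry per haplotype.
#' @return D-prime in [0, 1], or \code{NA} if either locus is monomorphic.
#' @export
haplotypeDPrime <- function(h1, h2) {
    stopifnot(length(h1) == length(h2))
    n <- length(h1)
    f <- c(ab = sum(h1 == 0 & h2 == 0), aB = sum(h1 == 0 & h2 == 1),
           Ab = sum(h1 == 1 & h2 == 0), AB = sum(h1 == 1 & h2 == 1)) / n
    .dPrimeFromFreqs(f)
}

#' Windowed linkage-disequilibrium scan around a focal variant
#'
#' Computes pairwise LD between a focal variant and every qualifying partner
#' within \code{windowBp} of it on the same chromosome. Partners must carry a
#' non-reference call (dosage >= 1) in at least \code{minNonref} samples.
#' \code{r2} is the squared composite (genotype-dosage) correlation;
#' \code{d_prime} is derived from EM-estimated haplotype frequencies
#' ([emHaplotypeFreqs()]).
#'
#' @param cohort a \linkS4class{GenotypeCohort}.
#' @param focal variant id of the focal variant; must be present and
#'   polymorphic.
#' @param windowBp window half-width in base pairs (inclusive at exactly
#'   \code{windowBp}).
#' @param minNonref minimum number of samples with a non-reference call at
#'   the partner.
#' @return a data.frame sorted by partner position with columns
#'   \code{focal_id}, \code{partner_id}, \code{distance_bp} (signed,
#'   partner minus focal), \code{n_nonref_partner}, \code{r2},
#'   \code{d_prime}.
#' @examples
#' sim <- simulateCohort(cohortSimConfig(nSamples = 40, nVariants = 200,
#'                                       seed = 3))
#' ld <- ldScan(sim$cohort, plantedVariant(sim$truth))
#' head(ld)
#' @export
ldScan <- function(cohort, focal, windowBp = 100000, minNonref = 3) {
    stopifnot(is(cohort, "GenotypeCohort"))
    .assertScalarNumber(windowBp, "windowBp", lower = 1)
    .assertScalarNumber(minNonref, "minNonref", lower = 0, integer = TRUE)
    d <- dosage(cohort)
    gr <- rowRanges(cohort)
    vid <- mcols(gr)$variant_id
    fi <- match(focal, vid)
    if (is.na(fi))
        stop("focal variant not found: ", focal, call. = FALSE)
    gF <- d[fi, ]
    if (stats::var(gF, na.rm = TRUE) == 0 || all(is.na(gF)))
        stop("focal variant is monomorphic: ", focal, call. = FALSE)

    sameChr <- as.character(seqnames(gr)) ==
        as.character(seqnames(gr))[fi]
    dist <- start(gr) - start(gr)[fi]
    nNonref <- rowSums(!is.na(d) & d >= 1)
    cand <- which(sameChr & abs(dist) <= windowBp &
                  nNonref >= minNonref & seq_along(vid) != fi)
    cand <- cand[order(start(gr)[cand])]

    r2 <- vapply(cand, function(i) {
        r <- suppressWarnings(stats::cor(gF, d[i, ],
                                         use = "pairwise.complete.obs"))
        if (is.na(r)) NA_real_ else r^2
    }, numeric(1))
    dp <- vapply(cand, function(i) {
        f <- emHaplotypeFreqs(gF, d[i, ])
        .dPrimeFromFreqs(f)
    }, numeric(1))
    data.frame(focal_id = focal,
               partner_id = vid[cand],
               distance_bp = dist[cand],
               n_nonref_partner = nNonref[cand],
               r2 = r2,
               d_prime = dp,
               stringsAsFactors = FALSE)
}

#' Perfect-LD partners of a focal variant
#'
#' Selects from an [ldScan()] result the partners in (numerically) perfect LD
#' with the focal variant, the candidate members of a shared regional
#' haplotype.
#'
#' @param results data.frame from [ldScan()].
#' @param r2Min threshold on \code{r2}; default 0.999 guards against
#'   floating-point noise rather than demanding literal equality.
#' @return character vector of partner variant ids.
#' @export
perfectLdPartners <- function(results, r2Min = 0.999) {
    if (!nrow(results)) return(character(0))
    results$partner_id[!is.na(results$r2) & results$r2 >= r2Min]
}

#' Pairwise r-squared matrix over a region
#'
#' Symmetric matrix of squared composite genotype correlations between all
#' polymorphic variants in a region, the numeric substrate of an LD heatmap.
#'
#' @param cohort a \linkS4class{GenotypeCohort}.
#' @param chrom chromosome name; with \code{start}/\code{end} it delimits
#'   the region. Defaults to all variants.
#' @param start,end region bounds (1-based, inclusive).
#' @return a symmetric numeric matrix with unit diagonal, dimnames set to
#'   variant ids.
#' @export
ldHeatmapMatrix <- function(cohort, chrom = NULL, start = -Inf, end = Inf) {
    stopifnot(is(cohort, "GenotypeCohort"))
    d <- dosage(cohort)
    gr <- rowRanges(cohort)
    keep <- rep(TRUE, nrow(d))
    if (!is.null(chrom))
        keep <- keep & as.character(seqnames(gr)) == chrom
    keep <- keep & GenomicRanges::start(gr) >= start &
        GenomicRanges::start(gr) <= end
    vr <- apply(d, 1, stats::var, na.rm = TRUE)
    keep <- keep & !is.na(vr) & vr > 0
    if (sum(keep) < 2L)
        stop("need at least 2 polymorphic variants in the region",
             call. = FALSE)
    sub <- d[keep, , drop = FALSE]
    r <- suppressWarnings(stats::cor(t(sub),
                                     use = "pairwise.complete.obs"))
    m <- r^2
    diag(m) <- 1
    dimnames(m) <- list(rownames(sub), rownames(sub))
    m
}

#' @rdname ldHeatmapMatrix
#' @param m matrix from \code{ldHeatmapMatrix}.
#' @param path output path (TSV for the matrix, PNG for the plot).
#' @export
writeLdMatrix <- function(m, path) {
    utils::write.table(m, path, sep = "\t", quote = FALSE,
                       row.names = TRUE, col.names = NA)
    invisible(path)
}

#' @rdname ldHeatmapMatrix
#' @export
plotLdHeatmap <- function(m, path = NULL) {
    if (!is.null(path)) {
        grDevices::png(path, width = 800, height = 800)
        on.exit(grDevices::dev.off())
    }
    n <- nrow(m)
    graphics::image(seq_len(n), seq_len(n), m[, rev(seq_len(n))],
                    zlim = c(0, 1), axes = FALSE, xlab = "", ylab = "",
                    col = grDevices::hcl.colors(64, "Reds", rev = TRUE),
                    main = "Pairwise LD (r²)")
    invisible(m)
}
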