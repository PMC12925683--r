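#' Estimate pairwise kinship from genotypes
#'
#' Moment-based kinship estimation on the 0--0.5 scale using the KING-robust
#' heterozygote-concordance estimator: for a pair of samples \eqn{(i, j)},
#' \deqn{\hat\phi_{ij} = \frac{N_{Aa,Aa} - 2\,N_{AA,aa}}{N_{Aa}^{(i)} +
#'   N_{Aa}^{(j)}}}
#' where \eqn{N_{Aa,Aa}} counts sites at which both samples are heterozygous,
#' \eqn{N_{AA,aa}} counts opposite homozygotes, and the denominator counts
#' heterozygous sites of each sample, all restricted to sites genotyped in
#' both samples (pairwise deletion of missing calls). The estimator requires
#' no allele-frequency estimates and yields 0.5 for duplicates, 0.25 in
#' expectation for parent--offspring and full-sibling pairs, and 0 for
#' unrelated individuals of a homogeneous population.
#'
#' Estimates are produced for every requested minor-allele-frequency stratum:
#' a stratum with threshold \eqn{t} uses the variants whose within-cohort MAF
#' exceeds \eqn{t} (threshold 0 means all polymorphic variants).
#'
#' @param cohort a \linkS4class{GenotypeCohort}, or a variants-by-samples
#'   dosage matrix.
#' @param strata numeric vector of cohort-MAF thresholds; names are used as
#'   stratum labels, unnamed thresholds are labelled \code{"all"} (0) or
#'   \code{"maf_gt_<t>"}.
#'
#' @return a data.frame with one row per unordered sample pair per stratum:
#'   \code{sample_a}, \code{sample_b}, \code{stratum}, \code{phi},
#'   \code{n_snps_used}.
#' @references Manichaikul A et al. (2010) Robust relationship inference in
#'   genome-wide association studies. Bioinformatics 26:2867-2873.
#' @examples
#' sim <- simulateCohort(cohortSimConfig(nSamples = 10, nVariants = 500,
#'                                       nCarriers = 0, seed = 5))
#' k <- estimateKinship(sim$cohort)
#' head(k)
#' @export
estimateKinship <- function(cohort, strata = c(0, 0.1, 0.05)) {
    G <- .dosageMatrix(cohort)
    if (ncol(G) < 2L)
        stop("kinship needs at least 2 samples", call. = FALSE)
    labels <- names(strata)
    if (is.null(labels)) labels <- rep("", length(strata))
    auto <- ifelse(strata == 0, "all",
                   paste0("maf_gt_", vapply(strata, format, character(1))))
    labels <- ifelse(nzchar(labels), labels, auto)

    af <- rowMeans(G, na.rm = TRUE) / 2
    maf <- pmin(af, 1 - af)

    out <- vector("list", length(strata))
    for (s in seq_along(strata)) {
        idx <- which(!is.na(maf) & maf > strata[s])
        if (!length(idx))
            stop("stratum '", labels[s],
                 "' contains no polymorphic variant", call. = FALSE)
        out[[s]] <- cbind(.kingPairs(G[idx, , drop = FALSE]),
                          stratum = labels[s])
    }
    res <- do.call(rbind, out)
    res <- res[, c("sample_a", "sample_b", "stratum", "phi", "n_snps_used")]
    rownames(res) <- NULL
    res
}

## KING-robust over all sample pairs via matrix cross-products.
.kingPairs <- function(G) {
    M <- (!is.na(G)) * 1
    H <- (!is.na(G) & G == 1) * 1
    A0 <- (!is.na(G) & G == 0) * 1
    A2 <- (!is.na(G) & G == 2) * 1
    nHetHet <- crossprod(H)
    nOpp <- crossprod(A0, A2) + crossprod(A2, A0)
    hetPair <- crossprod(H, M)          # [i, j] = het sites of i typed in j
    denom <- hetPair + t(hetPair)
    nUsed <- crossprod(M)
    phi <- (nHetHet - 2 * nOpp) / denom
    ut <- which(upper.tri(phi), arr.ind = TRUE)
    data.frame(sample_a = colnames(G)[ut[, 1]],
               sample_b = colnames(G)[ut[, 2]],
               phi = phi[ut],
               n_snps_used = nUsed[ut],
               stringsAsFactors = FALSE)
}

#' Summarize kinship estimates and call unrelatedness
#'
#' Produces per-stratum maxima and a per-pair verdict: a pair is called
#' \code{unrelated} when its kinship in the all-variants stratum falls below
#' \code{unrelatedThreshold}, by default 0.044 (the conventional midpoint
#' between third-degree relatives and unrelated pairs).
#'
#' @param estimates data.frame from [estimateKinship()].
#' @param unrelatedThreshold kinship cutoff for the unrelated verdict.
#' @return an object of class \code{kinshipReport}: a list with elements
#'   \code{estimator} (description of the method), \code{maxima}
#'   (per-stratum maximum kinship with the attaining pair), \code{pairs}
#'   (wide per-pair table with one \code{phi_<stratum>} column per stratum
#'   and a \code{verdict} column) and \code{threshold}.
#' @examples
#' sim <- simulateCohort(cohortSimConfig(nSamples = 8, nVariants = 600,
#'                                       nCarriers = 0, seed = 11))
#' maxKinshipReport(estimateKinship(sim$cohort))
#' @export
maxKinshipReport <- function(estimates, unrelatedThreshold = 0.044) {
    if (!nrow(estimates))
        stop("no kinship estimates supplied", call. = FALSE)
    strata <- unique(estimates$stratum)
    maxima <- do.call(rbind, lapply(strata, function(s) {
        e <- estimates[estimates$stratum == s, ]
        i <- which.max(e$phi)
        data.frame(stratum = s, max_phi = e$phi[i],
                   sample_a = e$sample_a[i], sample_b = e$sample_b[i],
                   stringsAsFactors = FALSE)
    }))
    wide <- stats::reshape(
        estimates[, c("sample_a", "sample_b", "stratum", "phi")],
        direction = "wide", idvar = c("sample_a", "sample_b"),
        timevar = "stratum", v.names = "phi", sep = "_")
    names(wide) <- sub("^phi_", "phi_", names(wide))
    allCol <- if ("phi_all" %in% names(wide)) "phi_all" else
        grep("^phi_", names(wide), value = TRUE)[1]
    wide$verdict <- ifelse(wide[[allCol]] < unrelatedThreshold,
                           "unrelated", "related")
    rownames(wide) <- NULL
    structure(list(
        estimator = paste("KING-robust heterozygote-concordance moment",
                          "estimator (not PC-relate)"),
        maxima = maxima, pairs = wide, threshold = unrelatedThreshold),
        class = "kinshipReport")
}

#' @export
print.kinshipReport <- function(x, ...) {
    cat("Kinship report --", x$estimator, "\n")
    cat("Unrelated threshold:", x$threshold, "\n")
    cat("Per-stratum maxima:\n")
    print(x$maxima, row.names = FALSE)
    n <- table(x$pairs$verdict)
    cat("Verdicts:", paste(sprintf("%s (%d)", names(n), n),
                           collapse = ", "), "\n")
    invisible(x)
}

#' @rdname maxKinshipReport
#' @param report a \code{kinshipReport}.
#' @param path output TSV path.
#' @export
writeKinshipReport <- function(report, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# estimator: ", report$estimator), con)
    writeLines(paste0("# unrelated_threshold: ", report$threshold), con)
    utils::write.table(report$pairs, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}
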