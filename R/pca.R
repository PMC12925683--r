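#' Randomly subsample SNP indices
#'
#' Draws a reproducible random subset of variant indices for PCA, sampling
#' \code{round(fraction * n)} indices without replacement under a fixed seed.
#'
#' @param n total number of variants, or a \linkS4class{GenotypeCohort}
#'   whose variant count is used.
#' @param fraction proportion of variants to draw, in (0, 1].
#' @param seed integer seed fixing the draw.
#' @return a sorted integer vector of variant indices.
#' @examples
#' subsampleSnps(10000, 0.01, seed = 3)
#' @export
subsampleSnps <- function(n, fraction, seed) {
    if (is(n, "GenotypeCohort")) n <- nrow(dosage(n))
    .assertScalarNumber(n, "n", lower = 1, integer = TRUE)
    .assertScalarNumber(fraction, "fraction", lower = 1e-12, upper = 1)
    .assertScalarNumber(seed, "seed", integer = TRUE)
    size <- round(fraction * n)
    if (size < 1)
        stop("fraction ", fraction, " yields zero SNPs out of ", n,
             call. = FALSE)
    withLocalSeed(seed, sort(sample.int(n, size)))
}

#' Hardy--Weinberg-normalized PCA of a genotype matrix
#'
#' Principal component analysis of cohort genotypes under Hardy--Weinberg
#' scaling: each variant column is centered by twice its within-data
#' alternate-allele frequency \eqn{\hat p} and scaled by the binomial
#' standard deviation \eqn{\sqrt{2 \hat p (1 - \hat p)}}, so every variant
#' contributes unit variance under Hardy--Weinberg equilibrium. Scores are
#' the top-\code{k} left singular vectors of the normalized samples-by-SNPs
#' matrix, scaled by their singular values.
#'
#' Missing genotypes are mean-imputed per variant before normalization;
#' monomorphic variants (normalization undefined at \eqn{\hat p \in \{0,1\}})
#' are dropped and counted. Each component's sign is fixed so that its
#' largest-magnitude score is positive.
#'
#' @param cohort a \linkS4class{GenotypeCohort} or variants-by-samples dosage
#'   matrix.
#' @param snpIndices optional variant indices (e.g. from [subsampleSnps()]);
#'   default all variants.
#' @param k number of components to return; truncated to the matrix rank
#'   with a warning if too large.
#' @param seed seed recorded in the result when \code{snpIndices} came from
#'   a seeded subsample (bookkeeping only).
#'
#' @return a \linkS4class{HwePcaResult}.
#' @examples
#' sim <- simulateCohort(cohortSimConfig(nSamples = 40, nVariants = 300,
#'                                       nCarriers = 0, clusterFst = 0.1,
#'                                       clusterFractions = c(0.5, 0.5),
#'                                       seed = 9))
#' pca <- hweNormalizedPca(sim$cohort, k = 2)
#' pca
#' @export
hweNormalizedPca <- function(cohort, snpIndices = NULL, k = 10,
                             seed = NA_integer_) {
    G <- .dosageMatrix(cohort)
    if (ncol(G) < 2L)
        stop("PCA needs at least 2 samples", call. = FALSE)
    if (is.null(snpIndices)) snpIndices <- seq_len(nrow(G))
    if (any(snpIndices < 1L | snpIndices > nrow(G)))
        stop("snpIndices out of range", call. = FALSE)
    .assertScalarNumber(k, "k", lower = 1, integer = TRUE)
    G <- G[snpIndices, , drop = FALSE]
    nSampled <- nrow(G)

    ## mean-impute missing calls per variant
    if (anyNA(G)) {
        mu <- rowMeans(G, na.rm = TRUE)
        idx <- which(is.na(G), arr.ind = TRUE)
        G[idx] <- mu[idx[, 1]]
    }
    p <- rowMeans(G) / 2
    rowVar <- rowMeans(G^2) - rowMeans(G)^2
    poly <- is.finite(p) & p > 0 & p < 1 & rowVar > 0
    nMono <- sum(!poly)
    if (!any(poly))
        stop("all SNPs in the subsample are monomorphic", call. = FALSE)
    G <- G[poly, , drop = FALSE]
    p <- p[poly]
    Z <- (G - 2 * p) / sqrt(2 * p * (1 - p))

    X <- t(Z)                           # samples x SNPs
    sv <- svd(X)
    pos <- sv$d > max(sv$d) * 1e-12
    rank <- sum(pos)
    if (k > rank) {
        warning("k = ", k, " exceeds rank ", rank, "; truncating")
        k <- rank
    }
    scores <- sv$u[, seq_len(k), drop = FALSE] %*%
        diag(sv$d[seq_len(k)], k, k)
    ## sign convention: largest-magnitude score positive
    for (j in seq_len(k)) {
        i <- which.max(abs(scores[, j]))
        if (scores[i, j] < 0) scores[, j] <- -scores[, j]
    }
    dimnames(scores) <- list(colnames(G), paste0("PC", seq_len(k)))
    ev <- sv$d[seq_len(k)]^2 / (nrow(X) - 1)
    new("HwePcaResult",
        scores = scores,
        explainedVariance = ev,
        nSnpsSampled = as.integer(nSampled),
        nMonomorphicDropped = as.integer(nMono),
        seed = as.integer(seed))
}

#' @rdname hweNormalizedPca
#' @param result a \code{HwePcaResult}.
#' @param scoresPath,variancePath output TSV paths.
#' @export
writePcaResult <- function(result, scoresPath, variancePath) {
    sc <- data.frame(sample_id = rownames(pcaScores(result)),
                     as.data.frame(pcaScores(result)),
                     stringsAsFactors = FALSE)
    .writeTsv(sc, scoresPath)
    ev <- explainedVariance(result)
    .writeTsv(data.frame(component = paste0("PC", seq_along(ev)),
                         eigenvalue = ev,
                         proportion = ev / sum(ev)), variancePath)
    invisible(c(scoresPath, variancePath))
}
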