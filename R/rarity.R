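#' Construct a carrier table
#'
#' @param cohortCarriers,cohortNoncarriers carrier / non-carrier counts in
#'   the study cohort.
#' @param refCarriers,refNoncarriers carrier / non-carrier counts in the
#'   reference population.
#' @return a \linkS4class{CarrierTable}.
#' @examples
#' carrierTable(3, 98, 56, 589929)
#' @export
carrierTable <- function(cohortCarriers, cohortNoncarriers,
                         refCarriers, refNoncarriers) {
    new("CarrierTable",
        cohortCarriers = as.numeric(cohortCarriers),
        cohortNoncarriers = as.numeric(cohortNoncarriers),
        refCarriers = as.numeric(refCarriers),
        refNoncarriers = as.numeric(refNoncarriers))
}

setMethod("show", "CarrierTable", function(object) {
    m <- matrix(c(object@cohortCarriers, object@cohortNoncarriers,
                  object@refCarriers, object@refNoncarriers),
                2, 2, byrow = TRUE,
                dimnames = list(c("cohort", "reference"),
                                c("carriers", "noncarriers")))
    cat("CarrierTable\n")
    print(m)
})

#' Read reference-population carrier counts
#'
#' Reads a small TSV with columns \code{population}, \code{carriers},
#' \code{noncarriers} and returns the counts of the requested population.
#'
#' @param path TSV file path.
#' @param population population label to select; default the first row.
#' @return named numeric vector with elements \code{carriers} and
#'   \code{noncarriers}.
#' @export
readReferenceCounts <- function(path, population = NULL) {
    if (!file.exists(path))
        stop("reference counts file not found: ", path, call. = FALSE)
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("population", "carriers", "noncarriers")
    if (!all(need %in% colnames(df)))
        stop("reference counts file needs columns: ",
             paste(need, collapse = ", "), call. = FALSE)
    row <- if (is.null(population)) 1L else match(population, df$population)
    if (is.na(row))
        stop("population not found in ", path, ": ", population,
             call. = FALSE)
    c(carriers = df$carriers[row], noncarriers = df$noncarriers[row])
}

## Exact hypergeometric tail probabilities for a 2x2 table with fixed
## margins, evaluated in log space via dhyper/phyper. `a` may be a vector.
## Margins: K carriers in total, n cohort individuals, N overall total.
.hyperTail <- function(a, K, n, N, alternative) {
    if (alternative == "greater") {
        stats::phyper(a - 1, K, N - K, n, lower.tail = FALSE)
    } else { # two_sided: sum point probabilities <= observed's
        support <- max(0, n - (N - K)):min(K, n)
        logd <- stats::dhyper(support, K, N - K, n, log = TRUE)
        vapply(a, function(x) {
            obs <- stats::dhyper(x, K, N - K, n, log = TRUE)
            relErr <- 1 + 1e-7          # guard against ties lost to rounding
            min(1, sum(exp(logd[logd <= obs + log(relErr)])))
        }, numeric(1))
    }
}

#' Exact carrier-enrichment test
#'
#' Tests whether carriers of a variant are over-represented in the study
#' cohort relative to a reference population, by the exact conditional
#' (hypergeometric) distribution of the 2x2 carrier table with fixed
#' margins. The default one-sided alternative \code{"greater"} returns the
#' upper-tail probability \eqn{P(X \ge a)} of observing at least the
#' cohort's carrier count; \code{"two_sided"} sums the probabilities of all
#' tables no more likely than the observed one.
#'
#' Degenerate margins (a zero row or column total) carry no information and
#' return 1 with a warning.
#'
#' @param table a \linkS4class{CarrierTable}.
#' @param alternative \code{"greater"} (default) or \code{"two_sided"}.
#' @return the p-value, in (0, 1].
#' @examples
#' # 3 carriers among 101 cohort samples vs 56 among 589,985 reference
#' # individuals
#' fisherCarrierTest(carrierTable(3, 98, 56, 589929))
#' @export
fisherCarrierTest <- function(table,
                              alternative = c("greater", "two_sided")) {
    stopifnot(is(table, "CarrierTable"))
    validObject(table)
    alternative <- match.arg(alternative)
    a <- table@cohortCarriers
    n <- a + table@cohortNoncarriers
    K <- a + table@refCarriers
    N <- n + table@refCarriers + table@refNoncarriers
    if (K == 0 || K == N || n == 0 || n == N) {
        warning("degenerate margin in carrier table; returning p = 1")
        return(1)
    }
    .hyperTail(a, K, n, N, alternative)
}

#' Number of distinct trios in a cohort
#'
#' Exact binomial coefficient \eqn{\binom{n}{k}}: the number of distinct
#' subsets of \code{trioSize} samples in a cohort of \code{cohortN}.
#'
#' @param cohortN cohort size.
#' @param trioSize subset size, default 3.
#' @return an exact count; 0 with a warning when \code{trioSize > cohortN}.
#' @examples
#' nTrios(100)     # 161700
#' @export
nTrios <- function(cohortN, trioSize = 3) {
    .assertScalarNumber(cohortN, "cohortN", lower = 0, integer = TRUE)
    .assertScalarNumber(trioSize, "trioSize", lower = 0, integer = TRUE)
    if (trioSize > cohortN) {
        warning("trioSize exceeds cohortN; returning 0")
        return(0)
    }
    round(choose(cohortN, trioSize))
}

#' Construct rarity-calculation parameters
#'
#' @param nGenes number of protein-coding genes.
#' @param medianGeneLength median gene length in base pairs.
#' @param maf reference-population minor allele frequency of the variant
#'   class considered.
#' @param cohortN cohort size from which trios are drawn.
#' @param trioSize number of carriers constituting the observation.
#' @return a \linkS4class{RarityParams}.
#' @export
rarityParams <- function(nGenes = 20000, medianGeneLength = 26288,
                         maf = 5e-5, cohortN = 100, trioSize = 3) {
    new("RarityParams", nGenes = as.numeric(nGenes),
        medianGeneLength = as.numeric(medianGeneLength),
        maf = as.numeric(maf), cohortN = as.numeric(cohortN),
        trioSize = as.numeric(trioSize))
}

#' Random-occurrence probability of a shared rare variant trio
#'
#' Probability that one specific trio of cohort samples shares some rare
#' variant by chance: the effective number of variant sites considered,
#' multiplied by the probability \eqn{\mathrm{MAF}^{trioSize}} that all trio
#' members carry a given variant of that frequency.
#'
#' The effective site count is \code{nGenes * medianGeneLength / 1000} under
#' the default per-kilobase scale (\code{lengthUnit = "kb"}, roughly one
#' polymorphic site per kilobase of gene sequence), the scale consistent
#' with treating the result as a per-trio probability. The literal
#' per-base-pair scale (\code{lengthUnit = "bp"}) counts every base as a
#' potential site and is 1000-fold larger; it is provided for comparison and
#' clearly labelled in the output, since chaining it into [fdrEstimate()]
#' yields a value far above 1 and cannot be read as a probability.
#'
#' @param params a \linkS4class{RarityParams}.
#' @param lengthUnit \code{"kb"} (default) or \code{"bp"}; see Details.
#' @return a list with \code{n_snps_effective}, \code{per_trio_probability}
#'   and \code{length_unit}.
#' @examples
#' trioProbability(rarityParams())   # ~6.6e-8 per trio
#' @export
trioProbability <- function(params = rarityParams(),
                            lengthUnit = c("kb", "bp")) {
    stopifnot(is(params, "RarityParams"))
    validObject(params)
    lengthUnit <- match.arg(lengthUnit)
    len <- params@medianGeneLength /
        if (lengthUnit == "kb") 1000 else 1
    nSnps <- params@nGenes * len
    list(n_snps_effective = nSnps,
         per_trio_probability = nSnps * params@maf^params@trioSize,
         length_unit = lengthUnit)
}

#' FDR estimate over all cohort trios
#'
#' Converts the per-trio random-occurrence probability into the estimated
#' probability that \emph{any} trio of the cohort shares such a rare variant
#' by chance -- interpretable as a false discovery rate for the observed
#' trio. The primary estimate is the linear (union) bound
#' \code{min(1, p * nTrios)}; the exact complement form
#' \code{1 - (1 - p)^nTrios} is reported alongside for reference (the two
#' agree closely whenever the product is small).
#'
#' @param perTrioProbability per-trio probability, e.g. from
#'   [trioProbability()].
#' @param nTrios number of possible trios, e.g. from [nTrios()].
#' @return a list with \code{fdr} (linear form) and \code{fdr_complement}.
#' @examples
#' fdrEstimate(6.56e-8, nTrios(100))  # about 1%
#' @export
fdrEstimate <- function(perTrioProbability, nTrios) {
    .assertScalarNumber(perTrioProbability, "perTrioProbability", lower = 0)
    .assertScalarNumber(nTrios, "nTrios", lower = 0)
    list(fdr = min(1, perTrioProbability * nTrios),
         fdr_complement = 1 - (1 - min(perTrioProbability, 1))^nTrios)
}

#' Bonferroni adjustment under genome-wide test counts
#'
#' Conservative family-wise correction of a p-value under one or more
#' assumed numbers of tests: each adjusted value is
#' \code{min(1, p * count)}. Intended for genome-wide loss-of-function test
#' counts supplied as literature constants.
#'
#' @param p unadjusted p-value.
#' @param testCounts vector of assumed test counts.
#' @return named numeric vector of adjusted p-values.
#' @examples
#' bonferroniAdjust(1.57e-7, c(443769, 179774))
#' @export
bonferroniAdjust <- function(p, testCounts = c(443769, 179774)) {
    .assertScalarNumber(p, "p", lower = .Machine$double.xmin, upper = 1)
    if (any(testCounts < 1))
        stop("test counts must be >= 1", call. = FALSE)
    out <- pmin(1, p * testCounts)
    names(out) <- paste0("m_", format(testCounts, scientific = FALSE,
                                      trim = TRUE))
    out
}

#' Assemble the full rarity report
#'
#' Runs the complete inferential chain for one candidate shared variant:
#' carrier-enrichment exact test, per-trio random-occurrence probability,
#' trio count, FDR estimate and Bonferroni adjustment, bundled as a
#' \linkS4class{RarityReport} whose \code{show} method prints the results in
#' narrative order.
#'
#' @param table a \linkS4class{CarrierTable}.
#' @param params a \linkS4class{RarityParams}.
#' @param testCounts Bonferroni test counts.
#' @param alternative alternative for [fisherCarrierTest()].
#' @param lengthUnit site-count scale for [trioProbability()].
#' @return a \code{RarityReport}.
#' @examples
#' rarityReport(carrierTable(3, 98, 56, 589929))
#' @export
rarityReport <- function(table, params = rarityParams(),
                         testCounts = c(443769, 179774),
                         alternative = c("greater", "two_sided"),
                         lengthUnit = c("kb", "bp")) {
    alternative <- match.arg(alternative)
    lengthUnit <- match.arg(lengthUnit)
    p <- fisherCarrierTest(table, alternative)
    tp <- trioProbability(params, lengthUnit)
    nt <- nTrios(params@cohortN, params@trioSize)
    fdr <- fdrEstimate(tp$per_trio_probability, nt)
    bon <- bonferroniAdjust(p, testCounts)
    new("RarityReport", table = table, params = params, fisherP = p,
        alternative = alternative, nSnpsEffective = tp$n_snps_effective,
        lengthUnit = lengthUnit,
        perTrioProbability = tp$per_trio_probability,
        nTrios = nt, fdrEstimate = fdr$fdr,
        fdrComplement = fdr$fdr_complement, bonferroni = bon)
}

setMethod("show", "RarityReport", function(object) {
    t <- object@table
    cat("Rarity report for a shared rare variant\n")
    cat(sprintf("  carrier table: cohort %d/%d, reference %d/%d\n",
                as.integer(t@cohortCarriers), as.integer(t@cohortNoncarriers),
                as.integer(t@refCarriers), as.integer(t@refNoncarriers)))
    cat(sprintf("  enrichment exact test (%s): p = %.3g\n",
                object@alternative, object@fisherP))
    for (i in seq_along(object@bonferroni))
        cat(sprintf("  Bonferroni-adjusted p (%s tests): %.3g\n",
                    sub("^m_", "", names(object@bonferroni)[i]),
                    object@bonferroni[i]))
    cat(sprintf("  effective variant sites (%s scale): %s\n",
                object@lengthUnit,
                format(object@nSnpsEffective, big.mark = ",")))
    if (object@lengthUnit == "bp")
        cat("  NOTE: per-base-pair scale; the chained FDR exceeds 1 and is\n",
            "  not interpretable as a probability (reported capped at 1)\n",
            sep = "")
    cat(sprintf("  per-trio probability: %.3g\n",
                object@perTrioProbability))
    cat(sprintf("  possible trios (n = %d, k = %d): %s\n",
                as.integer(object@params@cohortN),
                as.integer(object@params@trioSize),
                format(object@nTrios, big.mark = ",")))
    cat(sprintf("  estimated FDR: %.3g (complement form %.3g)\n",
                object@fdrEstimate, object@fdrComplement))
})

#' @rdname rarityReport
#' @param report a \code{RarityReport}.
#' @param path output TSV path.
#' @export
writeRarityReport <- function(report, path) {
    stopifnot(is(report, "RarityReport"))
    rows <- data.frame(
        key = c("cohort_carriers", "cohort_noncarriers", "ref_carriers",
                "ref_noncarriers", "alternative", "fisher_p",
                paste0("bonferroni_", sub("^m_", "",
                                          names(report@bonferroni))),
                "length_unit", "n_snps_effective", "per_trio_probability",
                "n_trios", "fdr_estimate", "fdr_complement"),
        value = c(report@table@cohortCarriers,
                  report@table@cohortNoncarriers,
                  report@table@refCarriers, report@table@refNoncarriers,
                  report@alternative,
                  format(report@fisherP, digits = 15),
                  vapply(report@bonferroni, format, character(1),
                         digits = 15),
                  report@lengthUnit,
                  format(report@nSnpsEffective, digits = 15),
                  format(report@perTrioProbability, digits = 15),
                  format(report@nTrios, digits = 15),
                  format(report@fdrEstimate, digits = 15),
                  format(report@fdrComplement, digits = 15)),
        stringsAsFactors = FALSE)
    .writeTsv(rows, path)
}
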