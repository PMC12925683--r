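#' @importFrom rtracklayer import
NULL

#' Construct or read a gene panel
#'
#' \code{genePanel()} builds a \linkS4class{GenePanel} from a character vector
#' of gene symbols and optional genomic intervals. \code{readGenePanel()}
#' reads the two on-disk artifacts: a gene list (one symbol per line) and an
#' optional BED file (0-based half-open) of panel intervals.
#'
#' @param genes character vector of gene symbols.
#' @param intervals optional \code{GRanges} of panel regions.
#' @return a \code{GenePanel}.
#' @examples
#' genePanel(c("FANCI", "EPOR"))
#' @export
genePanel <- function(genes, intervals = NULL) {
    new("GenePanel", genes = unique(as.character(genes)),
        intervals = intervals)
}

#' @rdname genePanel
#' @param geneFile path to a text file with one gene symbol per line.
#' @param bedFile optional path to a BED file of panel intervals.
#' @export
readGenePanel <- function(geneFile, bedFile = NULL) {
    if (!file.exists(geneFile))
        stop("gene list not found: ", geneFile, call. = FALSE)
    genes <- readLines(geneFile)
    genes <- trimws(genes)
    genes <- genes[nzchar(genes)]
    intervals <- NULL
    if (!is.null(bedFile)) {
        if (!file.exists(bedFile))
            stop("BED file not found: ", bedFile, call. = FALSE)
        intervals <- import(bedFile, format = "BED")
    }
    genePanel(genes, intervals)
}

setMethod("show", "GenePanel", function(object) {
    cat("GenePanel:", length(object@genes), "genes")
    if (!is.null(object@intervals))
        cat(",", length(object@intervals), "intervals")
    cat("\n")
})

## Panel membership per variant: gene symbol match, or -- for variants with
## no gene annotation -- positional overlap with a panel interval.
.inPanel <- function(gr, panel) {
    gene <- mcols(gr)$gene
    hit <- !is.na(gene) & gene %in% panel@genes
    if (!is.null(panel@intervals)) {
        ov <- IRanges::overlapsAny(gr, panel@intervals, ignore.strand = TRUE)
        hit <- hit | (is.na(gene) & ov)
    }
    hit
}

#' Prioritize rare loss-of-function candidate variants
#'
#' Applies the variant-selection cascade to an annotated cohort: restrict to
#' the gene panel, retain loss-of-function consequences (stop-gain by
#' definition), apply the rare minor-allele-frequency threshold against the
#' reference-population frequency, and keep only variants carried by at least
#' one cohort sample. Carriers are samples with dosage >= 1 (heterozygous or
#' homozygous alternate).
#'
#' A variant with missing reference frequency passes the MAF filter by
#' default -- absence from the reference is itself evidence of rarity -- and
#' fails it under \code{missingMaf = "fail"}.
#'
#' @param cohort a \linkS4class{GenotypeCohort}.
#' @param panel a \linkS4class{GenePanel}.
#' @param mafThreshold reference MAF strict upper bound; default 0.0005
#'   (0.05\%).
#' @param missingMaf how to treat variants with no reference frequency:
#'   \code{"pass"} (default) or \code{"fail"}.
#' @param lofTerms consequence terms counted as loss-of-function; default
#'   \code{"stop_gained"}.
#'
#' @return a data.frame of candidates, sorted by decreasing carrier count
#'   (ties by chromosome then position), with columns \code{variant_id},
#'   \code{chrom}, \code{pos}, \code{ref}, \code{alt}, \code{gene},
#'   \code{consequence}, \code{ref_maf}, \code{carrier_count} and
#'   \code{carrier_ids} (comma-joined sample ids).
#' @examples
#' sim <- simulateCohort(cohortSimConfig(nSamples = 30, nVariants = 60,
#'                                       nCarriers = 3, seed = 2))
#' filterLofCandidates(sim$cohort, genePanel("FANCI"))
#' @export
filterLofCandidates <- function(cohort, panel, mafThreshold = 0.0005,
                                missingMaf = c("pass", "fail"),
                                lofTerms = "stop_gained") {
    stopifnot(is(cohort, "GenotypeCohort"))
    if (!is(panel, "GenePanel"))
        stop("'panel' must be a GenePanel", call. = FALSE)
    validObject(panel)
    missingMaf <- match.arg(missingMaf)
    .assertScalarNumber(mafThreshold, "mafThreshold", lower = 1e-12,
                        upper = 0.5)

    gr <- rowRanges(cohort)
    meta <- mcols(gr)
    d <- dosage(cohort)

    inPanel <- .inPanel(gr, panel)
    isLof <- !is.na(meta$consequence) & meta$consequence %in% lofTerms
    af <- meta$ref_af
    rare <- ifelse(is.na(af), missingMaf == "pass", af < mafThreshold)
    carr <- !is.na(d) & d >= 1
    nCarr <- rowSums(carr)
    keep <- which(inPanel & isLof & rare & nCarr >= 1)

    ids <- vapply(keep, function(i)
        paste(colnames(d)[carr[i, ]], collapse = ","), character(1))
    out <- data.frame(
        variant_id = meta$variant_id[keep],
        chrom = as.character(seqnames(gr))[keep],
        pos = start(gr)[keep],
        ref = meta$ref[keep],
        alt = meta$alt[keep],
        gene = meta$gene[keep],
        consequence = meta$consequence[keep],
        ref_maf = af[keep],
        carrier_count = nCarr[keep],
        carrier_ids = ids,
        stringsAsFactors = FALSE)
    out <- out[order(-out$carrier_count, out$chrom, out$pos), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' @rdname filterLofCandidates
#' @param candidates a candidate data.frame from \code{filterLofCandidates}.
#' @param path output TSV path.
#' @export
writeCandidates <- function(candidates, path) {
    .writeTsv(candidates, path)
}
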