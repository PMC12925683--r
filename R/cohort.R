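#' Construct a GenotypeCohort
#'
#' Assemble a \linkS4class{GenotypeCohort} from a dosage matrix and a variant
#' annotation table. This is the low-level constructor; most users obtain a
#' cohort from [simulateCohort()] or [readAnnotatedVcf()].
#'
#' @param dosage variants-by-samples numeric matrix with entries 0, 1, 2 or
#'   \code{NA}. Column names are taken as sample ids if present.
#' @param variants either a \code{GRanges} carrying metadata columns
#'   \code{variant_id}, \code{ref}, \code{alt}, \code{consequence},
#'   \code{gene}, \code{ref_af}, or a data.frame with those columns plus
#'   \code{chrom} and \code{pos}.
#' @param sampleIds character vector of sample ids; defaults to the dosage
#'   column names.
#'
#' @return a \code{GenotypeCohort}.
#' @examples
#' d <- matrix(c(0, 1, 2, 0), nrow = 2,
#'             dimnames = list(NULL, c("S1", "S2")))
#' v <- data.frame(chrom = "15", pos = c(100, 200),
#'                 variant_id = c("v1", "v2"), ref = c("A", "G"),
#'                 alt = c("T", "C"),
#'                 consequence = c("stop_gained", "intron_variant"),
#'                 gene = c("FANCI", NA), ref_af = c(4.276e-05, 0.2))
#' gc <- GenotypeCohort(d, v)
#' dosage(gc)
#' @export
GenotypeCohort <- function(dosage, variants, sampleIds = colnames(dosage)) {
    if (!is.matrix(dosage))
        stop("'dosage' must be a matrix (variants x samples)", call. = FALSE)
    storage.mode(dosage) <- "double"
    if (is.null(sampleIds))
        sampleIds <- sprintf("S%03d", seq_len(ncol(dosage)))
    if (is.data.frame(variants)) {
        need <- c("chrom", "pos", "variant_id", "ref", "alt",
                  "consequence", "gene", "ref_af")
        miss <- setdiff(need, colnames(variants))
        if (length(miss))
            stop("variant table lacks column(s): ",
                 paste(miss, collapse = ", "), call. = FALSE)
        gr <- GRanges(as.character(variants$chrom),
                      IRanges(start = variants$pos, width = 1L))
        mcols(gr) <- DataFrame(variant_id = as.character(variants$variant_id),
                               ref = as.character(variants$ref),
                               alt = as.character(variants$alt),
                               consequence = as.character(variants$consequence),
                               gene = as.character(variants$gene),
                               ref_af = as.numeric(variants$ref_af))
    } else if (is(variants, "GRanges")) {
        gr <- variants
    } else {
        stop("'variants' must be a GRanges or a data.frame", call. = FALSE)
    }
    if (length(gr) != nrow(dosage))
        stop("variant annotation and dosage row count differ", call. = FALSE)
    names(gr) <- mcols(gr)$variant_id
    dimnames(dosage) <- list(mcols(gr)$variant_id, sampleIds)
    se <- SummarizedExperiment(
        assays = SimpleList(dosage = dosage),
        rowRanges = gr,
        colData = DataFrame(sample_id = sampleIds, row.names = sampleIds))
    new("GenotypeCohort", se)
}

#' @rdname GenotypeCohort-class
#' @export
setMethod("dosage", "GenotypeCohort", function(x) assay(x, "dosage"))

#' @rdname GenotypeCohort-class
#' @export
setMethod("variantInfo", "GenotypeCohort", function(x) rowRanges(x))

#' @rdname GenotypeCohort-class
#' @export
setMethod("sampleIds", "GenotypeCohort", function(x) colnames(x))

#' @rdname GenotypeCohort-class
#' @export
setMethod("variantIds", "GenotypeCohort",
          function(x) mcols(rowRanges(x))$variant_id)

setMethod("show", "GenotypeCohort", function(object) {
    d <- dosage(object)
    cat("GenotypeCohort:", nrow(d), "variants x", ncol(d), "samples\n")
    csq <- mcols(rowRanges(object))$consequence
    tb <- sort(table(csq), decreasing = TRUE)
    cat("  consequences:",
        paste(sprintf("%s (%d)", names(tb), tb), collapse = ", "), "\n")
    nmiss <- sum(is.na(d))
    cat(sprintf("  missing genotypes: %d (%.2f%%)\n",
                nmiss, 100 * nmiss / length(d)))
})

## --- TruthSet accessors ---------------------------------------------------

#' @rdname TruthSet-class
#' @export
setMethod("plantedVariant", "TruthSet", function(x) x@plantedVariant)

#' @rdname TruthSet-class
#' @export
setMethod("carrierIds", "TruthSet", function(x) x@carrierIds)

#' @rdname TruthSet-class
#' @export
setMethod("haplotypePartnerIds", "TruthSet",
          function(x) x@haplotypePartnerIds)

#' @rdname TruthSet-class
#' @export
setMethod("kinshipExpectations", "TruthSet",
          function(x) x@kinshipExpectations)

#' @rdname TruthSet-class
#' @export
setMethod("clusterLabels", "TruthSet", function(x) x@clusterLabels)

setMethod("show", "TruthSet", function(object) {
    cat("TruthSet\n")
    if (length(object@plantedVariant))
        cat("  planted variant:", object@plantedVariant, "with",
            length(object@carrierIds), "carriers\n")
    else
        cat("  no planted variant\n")
    cat("  haplotype partners:",
        if (length(object@haplotypePartnerIds))
            paste(object@haplotypePartnerIds, collapse = ", ") else "none",
        "\n")
    cat("  pedigree pairs:", nrow(object@kinshipExpectations), "\n")
    cat("  clusters:", paste(sprintf("%s (%d)",
        names(table(object@clusterLabels)),
        table(object@clusterLabels)), collapse = ", "), "\n")
})

## --- HwePcaResult accessors -----------------------------------------------

#' @rdname HwePcaResult-class
#' @export
setMethod("pcaScores", "HwePcaResult", function(x) x@scores)

#' @rdname HwePcaResult-class
#' @export
setMethod("explainedVariance", "HwePcaResult",
          function(x) x@explainedVariance)

setMethod("show", "HwePcaResult", function(object) {
    k <- ncol(object@scores)
    cat("HwePcaResult:", nrow(object@scores), "samples,", k, "components\n")
    tot <- sum(object@explainedVariance)
    if (tot > 0)
        cat("  variance explained (top components): ",
            paste(sprintf("%.1f%%",
                          100 * object@explainedVariance / tot),
                  collapse = ", "), "\n", sep = "")
    cat("  SNPs sampled:", object@nSnpsSampled,
        "| monomorphic dropped:", object@nMonomorphicDropped, "\n")
})
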