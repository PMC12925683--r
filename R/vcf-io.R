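#' @importFrom Biostrings DNAStringSet
#' @importFrom VariantAnnotation VCF VCFHeader writeVcf readVcf meta geno
#'   info header ref alt geno<- info<- meta<-
#' @importFrom IRanges DataFrameList CharacterList
NULL

.VCF_INFO_HEADER <- function() {
    DataFrame(Number = c("1", "1", "1"),
              Type = c("String", "String", "Float"),
              Description = c("Predicted consequence term",
                              "Gene symbol",
                              "Reference-population alternate allele frequency"),
              row.names = c("CSQ_TERM", "GENE", "REF_AF"))
}

#' Write a cohort to an annotated VCF
#'
#' Serializes a \linkS4class{GenotypeCohort} as VCF 4.2 with per-sample
#' \code{GT} calls and the annotation INFO keys \code{CSQ_TERM} (consequence
#' term), \code{GENE} (gene symbol) and \code{REF_AF} (reference-population
#' allele frequency). Missing annotations are encoded as \code{.} and
#' round-trip as \code{NA} through [readAnnotatedVcf()].
#'
#' By default genotypes are written unphased (\code{0/1}). With
#' \code{phased = TRUE} the simulator's haplotypes (kept in
#' \code{metadata(cohort)$haplotypes}) are written as phased calls
#' (\code{0|1}), which makes direct haplotype counting possible downstream.
#'
#' @param cohort a \linkS4class{GenotypeCohort}.
#' @param path output file path.
#' @param phased write phased genotypes from stored haplotypes.
#' @return invisibly, \code{path}.
#' @seealso [readAnnotatedVcf()]
#' @export
writeCohortVcf <- function(cohort, path, phased = FALSE) {
    stopifnot(is(cohort, "GenotypeCohort"))
    d <- dosage(cohort)
    nV <- nrow(d); nS <- ncol(d)
    if (nV == 0L) {                     # header-only file
        hdrInfo <- .VCF_INFO_HEADER()
        writeLines(c(
            "##fileformat=VCFv4.2",
            sprintf("##INFO=<ID=%s,Number=%s,Type=%s,Description=\"%s\">",
                    rownames(hdrInfo), hdrInfo$Number, hdrInfo$Type,
                    hdrInfo$Description),
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
            paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO", "FORMAT", colnames(d)), collapse = "\t")),
            path)
        return(invisible(path))
    }
    if (phased) {
        haps <- metadata(cohort)$haplotypes
        if (is.null(haps))
            stop("phased output requires haplotypes in metadata(cohort)",
                 call. = FALSE)
        gt <- matrix(paste(haps$h1, haps$h2, sep = "|"), nV, nS)
        gt[is.na(d)] <- ".|."
    } else {
        gt <- matrix("./.", nV, nS)
        gt[!is.na(d) & d == 0] <- "0/0"
        gt[!is.na(d) & d == 1] <- "0/1"
        gt[!is.na(d) & d == 2] <- "1/1"
    }
    dimnames(gt) <- dimnames(d)

    gr <- rowRanges(cohort)
    meta <- mcols(gr)
    gr2 <- GRanges(seqnames(gr), IRanges(start(gr), width = 1L))
    names(gr2) <- meta$variant_id
    hdr <- VCFHeader(samples = colnames(d))
    meta(hdr) <- DataFrameList(
        fileformat = DataFrame(Value = "VCFv4.2", row.names = "fileformat"))
    info(hdr) <- .VCF_INFO_HEADER()
    geno(hdr) <- DataFrame(Number = "1", Type = "String",
                           Description = "Genotype", row.names = "GT")
    gene <- as.character(meta$gene)
    gene[is.na(gene)] <- "."
    csq <- as.character(meta$consequence)
    csq[is.na(csq)] <- "."
    vcf <- VCF(rowRanges = gr2,
               fixed = DataFrame(REF = DNAStringSet(meta$ref),
                                 ALT = as(as.character(meta$alt),
                                          "CharacterList"),
                                 QUAL = rep(NA_real_, nV),
                                 FILTER = rep(".", nV)),
               info = DataFrame(CSQ_TERM = csq, GENE = gene,
                                REF_AF = as.numeric(meta$ref_af)),
               geno = SimpleList(GT = gt),
               colData = DataFrame(Samples = seq_len(nS),
                                   row.names = colnames(d)))
    metadata(vcf)$header <- hdr
    writeVcf(vcf, path)
    invisible(path)
}

#' Read an annotated VCF into a GenotypeCohort
#'
#' Parses a VCF 4.2 file with per-sample \code{GT} calls. Multi-allelic sites
#' are split into one biallelic record per alternate allele, with the dosage
#' computed as the number of copies of that allele. The INFO keys
#' \code{CSQ_TERM}, \code{GENE} and \code{REF_AF} are consumed when present;
#' absent keys yield \code{NA} annotation. Variant ids are normalized to
#' \code{chrom:pos:ref:alt}, the same scheme the simulator uses.
#'
#' @param path VCF file path (plain or bgzipped).
#' @return a \linkS4class{GenotypeCohort}; an empty (0-variant) cohort for a
#'   header-only file.
#' @seealso [writeCohortVcf()]
#' @export
readAnnotatedVcf <- function(path) {
    if (!file.exists(path))
        stop("VCF not found: ", path, call. = FALSE)
    vcf <- readVcf(path, genome = "cohort")
    samples <- rownames(colData(vcf))
    nIn <- nrow(vcf)
    if (nIn > 0 && !"GT" %in% names(geno(vcf)))
        stop("VCF has no GT field: ", path, call. = FALSE)

    infoDf <- info(vcf)
    getInfo <- function(key, default) {
        if (key %in% colnames(infoDf)) {
            v <- infoDf[[key]]
            if (is(v, "List")) # Number=. annotations arrive as lists
                v <- vapply(v, function(x)
                    if (length(x)) as.character(x[[1]]) else NA_character_,
                    character(1))
            v
        } else rep(default, nIn)
    }
    csq <- as.character(getInfo("CSQ_TERM", NA_character_))
    gene <- as.character(getInfo("GENE", NA_character_))
    refAf <- suppressWarnings(as.numeric(getInfo("REF_AF", NA_real_)))
    csq[csq == "."] <- NA_character_
    gene[gene == "."] <- NA_character_

    chrom <- as.character(seqnames(rowRanges(vcf)))
    posn <- start(rowRanges(vcf))
    refA <- as.character(ref(vcf))
    altL <- alt(vcf)
    gt <- geno(vcf)$GT

    nalt <- if (nIn) lengths(altL) else integer(0)
    if (nIn && sum(nalt) > 0) {
        ## expand multi-allelic records: one row per alternate allele
        expIdx <- rep(seq_len(nIn), nalt)
        altIdx <- sequence(nalt)
        altChar <- unlist(lapply(altL, as.character), use.names = FALSE)
        gtExp <- gt[expIdx, , drop = FALSE]
        ## dosage per (GT string, alt index), computed once per unique key
        keyMat <- paste(gtExp, altIdx[row(gtExp)])
        uk <- unique(as.vector(keyMat))
        ud <- vapply(strsplit(uk, " "), function(p) {
            tk <- strsplit(p[1], "[/|]")[[1]]
            if (length(tk) == 0L || any(tk == ".")) NA_real_
            else sum(tk == p[2])
        }, numeric(1))
        dos <- matrix(ud[match(keyMat, uk)], nrow = length(expIdx),
                      dimnames = list(NULL, samples))
        vtab <- data.frame(
            chrom = chrom[expIdx], pos = posn[expIdx],
            variant_id = paste(chrom[expIdx], posn[expIdx], refA[expIdx],
                               altChar, sep = ":"),
            ref = refA[expIdx], alt = altChar,
            consequence = csq[expIdx], gene = gene[expIdx],
            ref_af = refAf[expIdx], stringsAsFactors = FALSE)
    } else {
        vtab <- data.frame(chrom = character(), pos = integer(),
                           variant_id = character(), ref = character(),
                           alt = character(), consequence = character(),
                           gene = character(), ref_af = numeric(),
                           stringsAsFactors = FALSE)
        dos <- matrix(numeric(0), nrow = 0, ncol = length(samples),
                      dimnames = list(NULL, samples))
    }
    GenotypeCohort(dos, vtab, sampleIds = samples)
}
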