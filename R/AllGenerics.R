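#' @rdname GenotypeCohort-class
#' @param x a \code{GenotypeCohort}.
#' @export
setGeneric("dosage", function(x) standardGeneric("dosage"))

#' @rdname GenotypeCohort-class
#' @export
setGeneric("variantInfo", function(x) standardGeneric("variantInfo"))

#' @rdname GenotypeCohort-class
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname GenotypeCohort-class
#' @export
setGeneric("variantIds", function(x) standardGeneric("variantIds"))

#' @rdname TruthSet-class
#' @param x a \code{TruthSet}.
#' @export
setGeneric("plantedVariant", function(x) standardGeneric("plantedVariant"))

#' @rdname TruthSet-class
#' @export
setGeneric("carrierIds", function(x) standardGeneric("carrierIds"))

#' @rdname TruthSet-class
#' @export
setGeneric("haplotypePartnerIds",
           function(x) standardGeneric("haplotypePartnerIds"))

#' @rdname TruthSet-class
#' @export
setGeneric("kinshipExpectations",
           function(x) standardGeneric("kinshipExpectations"))

#' @rdname TruthSet-class
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @rdname HwePcaResult-class
#' @param x a \code{HwePcaResult}.
#' @export
setGeneric("pcaScores", function(x) standardGeneric("pcaScores"))

#' @rdname HwePcaResult-class
#' @export
setGeneric("explainedVariance",
           function(x) standardGeneric("explainedVariance"))
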