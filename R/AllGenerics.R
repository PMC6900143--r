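#' @rdname SnpGeno
#' @param x an object.
#' @export
setGeneric("dosageMatrix", function(x) standardGeneric("dosageMatrix"))

#' @rdname SnpGeno
#' @export
setGeneric("snpInfo", function(x) standardGeneric("snpInfo"))

#' @rdname SnpGeno
#' @export
setGeneric("chromosomes", function(x) standardGeneric("chromosomes"))

#' @rdname SnpGeno
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname RelationshipMatrix
#' @param x an object.
#' @export
setGeneric("relValues", function(x) standardGeneric("relValues"))

#' @rdname RelationshipMatrix
#' @export
setGeneric("relMethod", function(x) standardGeneric("relMethod"))

#' @rdname RelationshipMatrix
#' @export
setGeneric("nSnpsUsed", function(x) standardGeneric("nSnpsUsed"))

#' @rdname AssocTable
#' @param x an object.
#' @export
setGeneric("assocResults", function(x) standardGeneric("assocResults"))

#' @rdname InflationReport
#' @param x an object.
#' @export
setGeneric("lambdaGenome", function(x) standardGeneric("lambdaGenome"))

#' @rdname InflationReport
#' @export
setGeneric("lambdaByChrom", function(x) standardGeneric("lambdaByChrom"))

#' @rdname ThresholdSet
#' @param x an object.
#' @export
setGeneric("thresholdNeglog10p", function(x) standardGeneric("thresholdNeglog10p"))

#' @rdname ThresholdSet
#' @export
setGeneric("significantSnps", function(x) standardGeneric("significantSnps"))

#' @rdname VarianceComponents
#' @param x an object.
#' @export
setGeneric("heritability", function(x) standardGeneric("heritability"))

#' @rdname VarianceComponents
#' @export
setGeneric("varianceComponents", function(x) standardGeneric("varianceComponents"))
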