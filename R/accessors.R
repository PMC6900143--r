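## Accessors and show methods

#' @rdname SnpGeno
#' @export
setMethod("dosageMatrix", "SnpGeno", function(x) {
    t(SummarizedExperiment::assay(x, "dosage"))
})

#' @describeIn SnpGeno SNP map as a data.frame (chrom, bp, snp), in map order.
#' @export
setMethod("snpInfo", "SnpGeno", function(x) {
    rr <- SummarizedExperiment::rowRanges(x)
    data.frame(chrom = as.character(GenomicRanges::seqnames(rr)),
               bp = GenomicRanges::start(rr),
               snp = names(rr), stringsAsFactors = FALSE)
})

#' @describeIn SnpGeno chromosome labels in order of first appearance.
#' @export
setMethod("chromosomes", "SnpGeno", function(x) {
    unique(as.character(GenomicRanges::seqnames(SummarizedExperiment::rowRanges(x))))
})

#' @rdname SnpGeno
#' @export
setMethod("sampleIds", "SnpGeno", function(x) colnames(x))

setMethod("show", "SnpGeno", function(object) {
    cat(sprintf("SnpGeno: %d individuals x %d SNPs on %d chromosome(s)\n",
                ncol(object), nrow(object), length(chromosomes(object))))
    d <- SummarizedExperiment::assay(object, "dosage")
    nm <- sum(is.na(d))
    if (nm) cat(sprintf("  %d missing dosages (%.2f%%)\n", nm, 100 * nm / length(d)))
})

#' @rdname RelationshipMatrix
#' @export
setMethod("relValues", "RelationshipMatrix", function(x) x@values)

#' @rdname RelationshipMatrix
#' @export
setMethod("relMethod", "RelationshipMatrix", function(x) x@method)

#' @rdname RelationshipMatrix
#' @export
setMethod("nSnpsUsed", "RelationshipMatrix", function(x) x@nSnpsUsed)

#' @rdname RelationshipMatrix
#' @export
setMethod("sampleIds", "RelationshipMatrix", function(x) rownames(x@values))

setMethod("show", "RelationshipMatrix", function(object) {
    cat(sprintf("RelationshipMatrix '%s': %d x %d", object@method,
                nrow(object@values), ncol(object@values)))
    if (object@nSnpsUsed > 0L) cat(sprintf(", %d SNPs", object@nSnpsUsed))
    if (length(object@excluded)) cat(sprintf(" (chromosome %s left out)",
                                             paste(object@excluded, collapse = ",")))
    cat(sprintf("\n  mean diagonal %.4f\n", mean(diag(object@values))))
})

#' @rdname AssocTable
#' @export
setMethod("assocResults", "AssocTable", function(x) x@table)

setMethod("show", "AssocTable", function(object) {
    tb <- object@table
    cat(sprintf("AssocTable: %d SNPs, relationship '%s', genomic control '%s'\n",
                nrow(tb), object@method, object@gcMode))
    if (length(object@fixedSnps))
        cat("  fixed SNP covariates:", paste(object@fixedSnps, collapse = ", "), "\n")
    if (nrow(tb)) {
        top <- tb[which.max(tb$neglog10p), ]
        cat(sprintf("  top SNP %s (chr %s, %d bp): -log10 p = %.2f\n",
                    top$snp, top$chr, top$bp, top$neglog10p))
    }
})

#' @rdname InflationReport
#' @export
setMethod("lambdaGenome", "InflationReport", function(x) x@lambdaGenome)

#' @rdname InflationReport
#' @export
setMethod("lambdaByChrom", "InflationReport", function(x) x@lambdaByChrom)

setMethod("show", "InflationReport", function(object) {
    cat(sprintf("InflationReport: genome lambda %.3f (%d SNPs)\n",
                object@lambdaGenome, object@nSnpsGenome))
    if (length(object@lambdaByChrom)) {
        cat("  per chromosome:\n")
        for (cc in names(object@lambdaByChrom))
            cat(sprintf("    %s: %.3f (%d SNPs)\n", cc,
                        object@lambdaByChrom[[cc]], object@nSnpsByChrom[[cc]]))
    }
})

#' @rdname ThresholdSet
#' @export
setMethod("thresholdNeglog10p", "ThresholdSet", function(x) x@thresholdNeglog10p)

#' @rdname ThresholdSet
#' @export
setMethod("significantSnps", "ThresholdSet", function(x) x@significantSnps)

setMethod("show", "ThresholdSet", function(object) {
    cat(sprintf("ThresholdSet '%s': -log10(p) threshold %.4g",
                object@procedure, object@thresholdNeglog10p))
    if (!is.na(object@nTests)) cat(sprintf(" (alpha %.3g, %.4g tests)",
                                           object@alpha, object@nTests))
    cat(sprintf("; %d significant SNPs\n", length(object@significantSnps)))
})

#' @rdname VarianceComponents
#' @export
setMethod("heritability", "VarianceComponents", function(x) x@h2)

#' @describeIn VarianceComponents named vector (sigmaG2, sigmaE2).
#' @export
setMethod("varianceComponents", "VarianceComponents", function(x) {
    c(sigmaG2 = x@sigmaG2, sigmaE2 = x@sigmaE2)
})

setMethod("show", "VarianceComponents", function(object) {
    cat(sprintf("VarianceComponents: sigmaG2 %.4g, sigmaE2 %.4g, h2 %.3f%s\n",
                object@sigmaG2, object@sigmaE2, object@h2,
                if (object@boundary) " (boundary)" else ""))
    cat(sprintf("  restricted logLik %.4f after %d evaluations\n",
                object@logLik, object@nIter))
})

setMethod("show", "PermutationResult", function(object) {
    cat(sprintf("PermutationResult: %d permutations, threshold (%g%%) %.3f\n",
                object@nPermutations, object@percentile, object@threshold))
    cat(sprintf("  mean lambda %.3f (sd %.3f)\n",
                mean(object@lambda), sd(object@lambda)))
})

setMethod("show", "PopulationDesign", function(object) {
    sib <- expectedSibCounts(object)
    cat(sprintf("PopulationDesign: %d sires x %d dams x %d litter(s) of E[size] %.2f\n",
                object@nSires, object@damsPerSire, object@littersPerDam,
                object@litterSize))
    cat(sprintf("  expected offspring %.0f; E[full sibs] %.2f, E[half sibs] %.2f\n",
                object@nSires * object@damsPerSire * object@littersPerDam *
                    object@litterSize, sib[["fullSibs"]], sib[["halfSibs"]]))
    cat(sprintf("  genome: %d chromosomes x %d SNPs over %.0f Mb; ldRho %.2f\n",
                object@nChromosomes, object@snpsPerChromosome,
                object@chromosomeLengthBp / 1e6, object@ldRho))
    cat(sprintf("  trait: %d QTL, h2Polygenic %.2f, seed %d\n",
                object@nQtl, object@h2Polygenic, object@seed))
})

setMethod("show", "SimulatedStudy", function(object) {
    cat("SimulatedStudy\n")
    show(object@genotypes)
    cat(sprintf("  %d pedigree records, %d phenotypes, %d QTL\n",
                nrow(object@pedigree), nrow(object@phenotype),
                nrow(object@qtlTruth)))
    vt <- object@varianceTruth
    cat(sprintf("  truth: sigmaG2 %.3f, sigmaE2 %.3f, vQtl %.3f\n",
                vt[["sigmaG2"]], vt[["sigmaE2"]], vt[["vQtl"]]))
})
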