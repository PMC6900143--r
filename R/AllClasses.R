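#' @import methods
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames rowRanges
#' @importFrom S4Vectors metadata
#' @importFrom GenomicRanges GRanges seqnames start
#' @importFrom IRanges IRanges
#' @importFrom stats var median optimize pchisq qchisq rnorm runif rbinom rpois
#'   setNames cor quantile uniroot sd
#' @importFrom utils head tail write.table read.table
NULL

## ---------------------------------------------------------------------------
## SnpGeno: dosage genotypes with a genomic SNP map
## ---------------------------------------------------------------------------

#' SnpGeno: SNP dosage genotypes with a genomic map
#'
#' A [SummarizedExperiment::RangedSummarizedExperiment] subclass holding a
#' single `"dosage"` assay (SNPs in rows, individuals in columns, values in
#' \{0, 1, 2, NA\}) and a `GRanges` SNP map (chromosome, bp position, SNP id
#' as names). Chromosome levels are kept in order of first appearance in the
#' map; no assumptions about the genome (pig, toy or otherwise) are made.
#'
#' @seealso [SnpGeno()] for construction from an individuals-by-SNPs matrix,
#'   [dosageMatrix()], [snpInfo()], [chromosomes()].
#' @export
setClass("SnpGeno", contains = "RangedSummarizedExperiment")

.validSnpGeno <- function(object) {
    msg <- NULL
    if (!"dosage" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'dosage' is required")
    else {
        d <- SummarizedExperiment::assay(object, "dosage")
        bad <- !(d %in% c(0, 1, 2) | is.na(d))
        if (any(bad))
            msg <- c(msg, "dosages must be 0, 1, 2 or NA")
    }
    rr <- SummarizedExperiment::rowRanges(object)
    if (is.null(names(rr)) || anyDuplicated(names(rr)))
        msg <- c(msg, "SNP ids (rowRanges names) must be present and unique")
    pos <- GenomicRanges::start(rr)
    chr <- as.character(GenomicRanges::seqnames(rr))
    for (cc in unique(chr)) {
        p <- pos[chr == cc]
        if (length(p) > 1L && any(diff(p) <= 0))
            msg <- c(msg, sprintf("positions not strictly increasing on chromosome %s", cc))
    }
    if (is.null(msg)) TRUE else msg
}
setValidity("SnpGeno", .validSnpGeno)

#' Construct a SnpGeno object
#'
#' @param dosage numeric matrix, individuals x SNPs, values 0/1/2 or NA.
#'   Row names (if any) are used as sample ids unless `sampleId` is given.
#' @param chrom character vector of chromosome labels per SNP. Labels are
#'   opaque; ordering follows first appearance.
#' @param bp integer vector of 1-based bp positions, strictly increasing
#'   within each chromosome.
#' @param snpId character vector of unique SNP ids; defaults to
#'   `chrom:bp` labels.
#' @param sampleId character vector of individual ids.
#' @return A [SnpGeno-class] object.
#' @examples
#' g <- SnpGeno(matrix(c(0, 1, 2, 2, 1, 0), nrow = 3),
#'              chrom = c("1", "1"), bp = c(100L, 200L))
#' dosageMatrix(g)
#' @export
SnpGeno <- function(dosage, chrom, bp, snpId = NULL, sampleId = NULL) {
    dosage <- as.matrix(dosage)
    if (length(chrom) != ncol(dosage) || length(bp) != ncol(dosage))
        stop("chrom and bp must have one entry per SNP column")
    if (is.null(snpId))
        snpId <- paste0(chrom, ":", bp)
    if (is.null(sampleId))
        sampleId <- if (!is.null(rownames(dosage))) rownames(dosage)
                    else paste0("ind", seq_len(nrow(dosage)))
    chrom <- as.character(chrom)
    rr <- GenomicRanges::GRanges(
        seqnames = factor(chrom, levels = unique(chrom)),
        ranges = IRanges::IRanges(start = as.integer(bp), width = 1L))
    names(rr) <- as.character(snpId)
    m <- t(dosage)
    dimnames(m) <- list(as.character(snpId), as.character(sampleId))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(dosage = m), rowRanges = rr)
    new("SnpGeno", se)
}

## ---------------------------------------------------------------------------
## RelationshipMatrix
## ---------------------------------------------------------------------------

#' RelationshipMatrix: pedigree or genomic kinship-like matrix
#'
#' Symmetric n x n additive-relationship matrix with a method tag: `"A"`
#' (pedigree tabular method), `"G_vanraden1"`, `"G_yang"`, or a LOCO variant
#' `"G_vanraden1_loco"` / `"G_yang_loco"` with the left-out chromosome in
#' `@excluded`. `@nSnpsUsed` records how many SNPs entered a genomic matrix
#' (0 for pedigree).
#'
#' @slot values symmetric numeric matrix with sample ids as dimnames.
#' @slot method character method tag.
#' @slot nSnpsUsed integer count of SNPs used.
#' @slot excluded character, left-out chromosome label(s) for LOCO.
#' @export
setClass("RelationshipMatrix",
    representation(values = "matrix", method = "character",
                   nSnpsUsed = "integer", excluded = "character"))

setValidity("RelationshipMatrix", function(object) {
    v <- object@values
    msg <- NULL
    if (nrow(v) != ncol(v)) msg <- c(msg, "matrix must be square")
    else if (max(abs(v - t(v))) > 1e-10) msg <- c(msg, "matrix must be symmetric (tol 1e-10)")
    if (is.null(rownames(v)) || !identical(rownames(v), colnames(v)))
        msg <- c(msg, "dimnames must carry matching sample ids")
    if (length(object@method) != 1L) msg <- c(msg, "method must be a single string")
    if (is.null(msg)) TRUE else msg
})

.RelationshipMatrix <- function(values, method, nSnpsUsed = 0L, excluded = character()) {
    values <- (values + t(values)) / 2  # kill numerical asymmetry from BLAS
    new("RelationshipMatrix", values = values, method = method,
        nSnpsUsed = as.integer(nSnpsUsed), excluded = excluded)
}

## ---------------------------------------------------------------------------
## VarianceComponents
## ---------------------------------------------------------------------------

#' VarianceComponents: REML estimates for the polygenic mixed model
#'
#' @slot sigmaG2 genetic variance (>= 0; 0 at the boundary).
#' @slot sigmaE2 residual variance (> 0).
#' @slot h2 narrow-sense heritability sigmaG2 / (sigmaG2 + sigmaE2).
#' @slot logLik restricted log-likelihood at the optimum.
#' @slot nIter number of objective evaluations used by the optimizer.
#' @slot boundary TRUE when sigmaG2 was projected to the zero boundary.
#' @export
setClass("VarianceComponents",
    representation(sigmaG2 = "numeric", sigmaE2 = "numeric", h2 = "numeric",
                   logLik = "numeric", nIter = "integer", boundary = "logical"))

setValidity("VarianceComponents", function(object) {
    msg <- NULL
    if (object@sigmaG2 < 0) msg <- c(msg, "sigmaG2 must be >= 0")
    if (object@sigmaE2 <= 0) msg <- c(msg, "sigmaE2 must be > 0")
    if (is.null(msg)) TRUE else msg
})

## ---------------------------------------------------------------------------
## AssocTable
## ---------------------------------------------------------------------------

#' AssocTable: per-SNP mixed-model association results
#'
#' One row per tested SNP, sorted by (chromosome, bp), with GCTA-mlma-style
#' columns: `chr`, `snp`, `bp`, `freq`, `b`, `se`, `chi2`, `p`, `neglog10p`.
#' After genomic control the pre-control statistics are retained in
#' `chi2_raw` / `p_raw` / `neglog10p_raw` and `@gcMode` records the stratum
#' used, so control can never be applied twice.
#'
#' @slot table data.frame of association records.
#' @slot method relationship protocol used for the scan.
#' @slot vc list of [VarianceComponents-class] (one per LOCO chromosome, or
#'   a single element named "genome").
#' @slot fixedSnps SNP ids fitted as fixed covariates (excluded from testing).
#' @slot gcMode "none", "genome" or "per_chromosome".
#' @export
setClass("AssocTable",
    representation(table = "data.frame", method = "character", vc = "list",
                   fixedSnps = "character", gcMode = "character"))

setValidity("AssocTable", function(object) {
    tb <- object@table
    need <- c("chr", "snp", "bp", "freq", "b", "se", "chi2", "p", "neglog10p")
    msg <- NULL
    if (!all(need %in% names(tb)))
        msg <- c(msg, paste("missing columns:", paste(setdiff(need, names(tb)), collapse = ", ")))
    else if (nrow(tb)) {
        if (any(tb$p <= 0 | tb$p > 1)) msg <- c(msg, "p must lie in (0, 1]")
        if (any(tb$chi2 < 0)) msg <- c(msg, "chi2 must be >= 0")
        if (max(abs(tb$neglog10p + log10(tb$p))) > 1e-8)
            msg <- c(msg, "neglog10p must equal -log10(p)")
        if (anyDuplicated(tb$snp)) msg <- c(msg, "duplicate SNP ids")
    }
    if (!object@gcMode %in% c("none", "genome", "per_chromosome"))
        msg <- c(msg, "gcMode must be none/genome/per_chromosome")
    if (is.null(msg)) TRUE else msg
})

.AssocTable <- function(table, method, vc = list(), fixedSnps = character(),
                        gcMode = "none") {
    o <- order(match(table$chr, unique(table$chr)), table$bp)
    table <- table[o, , drop = FALSE]
    rownames(table) <- NULL
    new("AssocTable", table = table, method = method, vc = vc,
        fixedSnps = fixedSnps, gcMode = gcMode)
}

## ---------------------------------------------------------------------------
## InflationReport
## ---------------------------------------------------------------------------

#' InflationReport: genomic inflation factors by stratum
#'
#' Genome-wide and per-chromosome genomic inflation factors: the median of
#' the observed 1-df chi-square statistics divided by the median of the
#' chi-square(1) distribution. Raw (unfloored) lambdas are stored; flooring
#' at 1 happens only when control is applied.
#'
#' @slot lambdaGenome genome-wide lambda.
#' @slot lambdaByChrom named per-chromosome lambdas.
#' @slot nSnpsGenome,nSnpsByChrom SNP counts per stratum.
#' @slot expectedMedian the chi-square(1) median constant used.
#' @export
setClass("InflationReport",
    representation(lambdaGenome = "numeric", lambdaByChrom = "numeric",
                   nSnpsGenome = "integer", nSnpsByChrom = "integer",
                   expectedMedian = "numeric"))

setValidity("InflationReport", function(object) {
    if (any(c(object@lambdaGenome, object@lambdaByChrom) <= 0))
        "all lambdas must be > 0" else TRUE
})

## ---------------------------------------------------------------------------
## ThresholdSet
## ---------------------------------------------------------------------------

#' ThresholdSet: a significance threshold and the SNPs it declares
#'
#' @slot procedure one of "permutation", "bonferroni_total", "bonferroni_me",
#'   "fdr_bh", "fdr_by".
#' @slot alpha the type-1 / FDR level.
#' @slot nTests number of tests used (m, or real-valued Me; NA for
#'   permutation).
#' @slot thresholdNeglog10p the -log10(p) cutoff (+Inf when an FDR procedure
#'   declares nothing).
#' @slot significantSnps ids of SNPs declared significant (empty when no
#'   association table was supplied).
#' @export
setClass("ThresholdSet",
    representation(procedure = "character", alpha = "numeric",
                   nTests = "numeric", thresholdNeglog10p = "numeric",
                   significantSnps = "character"))

setValidity("ThresholdSet", function(object) {
    ok <- c("permutation", "bonferroni_total", "bonferroni_me", "fdr_bh", "fdr_by")
    msg <- NULL
    if (!object@procedure %in% ok) msg <- c(msg, "unknown procedure")
    if (!is.na(object@alpha) && (object@alpha <= 0 || object@alpha >= 1))
        msg <- c(msg, "alpha must lie in (0, 1)")
    if (is.null(msg)) TRUE else msg
})

## ---------------------------------------------------------------------------
## PermutationResult
## ---------------------------------------------------------------------------

#' PermutationResult: phenotype-permutation null distribution of the scan
#'
#' For each permutation replicate the phenotype is shuffled over individuals
#' and the full single-SNP scan re-run; the replicate's maximum -log10(p) and
#' genomic inflation factor are recorded. The threshold is the nearest-rank
#' percentile (default 95th) of the ordered maxima.
#'
#' @slot nPermutations number of replicates.
#' @slot maxNeglog10p per-replicate maximum -log10(p).
#' @slot lambda per-replicate genome-wide inflation factor.
#' @slot percentile the percentile used for the threshold.
#' @slot threshold the -log10(p) significance threshold.
#' @slot seed the seed the shuffle stream was drawn from.
#' @export
setClass("PermutationResult",
    representation(nPermutations = "integer", maxNeglog10p = "numeric",
                   lambda = "numeric", percentile = "numeric",
                   threshold = "numeric", seed = "integer"))

setValidity("PermutationResult", function(object) {
    msg <- NULL
    if (length(object@maxNeglog10p) != object@nPermutations)
        msg <- c(msg, "one recorded maximum per permutation required")
    if (length(object@lambda) != object@nPermutations)
        msg <- c(msg, "one lambda per permutation required")
    if (is.null(msg)) TRUE else msg
})

## ---------------------------------------------------------------------------
## PopulationDesign
## ---------------------------------------------------------------------------

#' PopulationDesign: parameters of the simulated breeding population
#'
#' Describes a single-generation hierarchical mating design (each sire mated
#' to `damsPerSire` dams, each dam producing `littersPerDam` litters of
#' `litterSize` offspring by the same sire), the founder-haplotype LD model
#' (first-order Markov chain with adjacent-site allelic correlation `ldRho`
#' and per-site frequencies drawn from Uniform(`mafMin`, 0.5)), the genome
#' (`nChromosomes` x `snpsPerChromosome` SNPs over `chromosomeLengthBp` bp,
#' recombination at 1 cM/Mbp), and the trait architecture (`qtlEffects`
#' allele-substitution effects plus a polygenic background with heritability
#' `h2Polygenic`).
#'
#' `litterSize` may be fractional: each litter's size is drawn as
#' `floor(litterSize)` plus a Bernoulli remainder, so the expected full-sib
#' count matches the design in expectation.
#'
#' @seealso [populationDesign()], [expectedSibCounts()], [simulateStudy()].
#' @export
setClass("PopulationDesign",
    representation(nSires = "integer", damsPerSire = "integer",
                   littersPerDam = "integer", litterSize = "numeric",
                   nChromosomes = "integer", snpsPerChromosome = "integer",
                   chromosomeLengthBp = "numeric", ldRho = "numeric",
                   mafMin = "numeric", nQtl = "integer", qtlEffects = "numeric",
                   h2Polygenic = "numeric", seed = "integer"))

setValidity("PopulationDesign", function(object) {
    msg <- NULL
    cnt <- c(object@nSires, object@damsPerSire, object@littersPerDam,
             object@nChromosomes, object@snpsPerChromosome)
    if (any(cnt < 1L)) msg <- c(msg, "counts must be positive")
    if (object@litterSize < 1) msg <- c(msg, "litterSize must be >= 1")
    if (object@snpsPerChromosome < 2L) msg <- c(msg, "need >= 2 SNPs per chromosome")
    if (object@ldRho < 0 || object@ldRho >= 1) msg <- c(msg, "ldRho must lie in [0, 1)")
    if (object@mafMin <= 0 || object@mafMin > 0.5) msg <- c(msg, "mafMin must lie in (0, 0.5]")
    if (object@h2Polygenic < 0 || object@h2Polygenic >= 1)
        msg <- c(msg, "h2Polygenic must lie in [0, 1)")
    if (length(object@qtlEffects) != object@nQtl)
        msg <- c(msg, "qtlEffects must have nQtl entries")
    if (is.null(msg)) TRUE else msg
})

#' Create a population design
#'
#' Defaults emulate a single-breed pig nucleus: 20 sires x 15 dams each, one
#' litter of expected size 3.2 (so on average ~2.2 full sibs and 42 half sibs
#' per offspring), ~960 genotyped offspring from 320 founders, 5 chromosomes
#' of 100 Mb with 400 SNPs each, adjacent-site founder LD 0.7 (r2 ~ 0.49
#' between neighbours, decaying geometrically), and a trait with three
#' moderate QTL (allele-substitution effects -0.13, 0.34, -0.15) over a
#' polygenic background of heritability 0.3.
#'
#' @param nSires,damsPerSire,littersPerDam,litterSize mating design counts;
#'   `litterSize` may be fractional (expected litter size).
#' @param nChromosomes,snpsPerChromosome,chromosomeLengthBp genome layout.
#' @param ldRho adjacent-site allelic correlation of founder haplotypes, in
#'   \[0, 1).
#' @param mafMin lower bound of the founder allele-frequency draw, in
#'   (0, 0.5].
#' @param qtlEffects numeric allele-substitution effects (phenotype units);
#'   QTL SNPs are picked at spread-out positions by the simulator.
#' @param h2Polygenic polygenic heritability in \[0, 1).
#' @param seed integer master seed; every stage derives its own substream.
#' @return A [PopulationDesign-class] object.
#' @export
populationDesign <- function(nSires = 20L, damsPerSire = 15L, littersPerDam = 1L,
                             litterSize = 3.2, nChromosomes = 5L,
                             snpsPerChromosome = 400L,
                             chromosomeLengthBp = 1e8, ldRho = 0.7,
                             mafMin = 0.05, qtlEffects = c(-0.13, 0.34, -0.15),
                             h2Polygenic = 0.3, seed = 1L) {
    new("PopulationDesign", nSires = as.integer(nSires),
        damsPerSire = as.integer(damsPerSire),
        littersPerDam = as.integer(littersPerDam),
        litterSize = as.numeric(litterSize),
        nChromosomes = as.integer(nChromosomes),
        snpsPerChromosome = as.integer(snpsPerChromosome),
        chromosomeLengthBp = as.numeric(chromosomeLengthBp),
        ldRho = as.numeric(ldRho), mafMin = as.numeric(mafMin),
        nQtl = length(qtlEffects), qtlEffects = as.numeric(qtlEffects),
        h2Polygenic = as.numeric(h2Polygenic), seed = as.integer(seed))
}

## ---------------------------------------------------------------------------
## SimulatedStudy
## ---------------------------------------------------------------------------

#' SimulatedStudy: one simulated dataset with its generating truth
#'
#' @slot genotypes [SnpGeno-class] dosages of the phenotyped individuals.
#' @slot pedigree data.frame (id, sire, dam; NA = unknown), parents first.
#' @slot phenotype data.frame (id, value), one record per genotyped offspring.
#' @slot qtlTruth data.frame (snp, index, effect) of the causal SNPs.
#' @slot varianceTruth named numeric: sigmaG2, sigmaE2, vQtl (realized QTL
#'   variance), h2Polygenic (realized polygenic fraction).
#' @export
setClass("SimulatedStudy",
    representation(genotypes = "SnpGeno", pedigree = "data.frame",
                   phenotype = "data.frame", qtlTruth = "data.frame",
                   varianceTruth = "numeric"))

setValidity("SimulatedStudy", function(object) {
    msg <- NULL
    m <- ncol(dosageMatrix(object@genotypes))
    if (nrow(object@qtlTruth) && any(object@qtlTruth$index < 1 | object@qtlTruth$index > m))
        msg <- c(msg, "qtlTruth indices out of range")
    if (!all(object@phenotype$id %in% colnames(SummarizedExperiment::assay(object@genotypes, "dosage"))))
        msg <- c(msg, "phenotyped individuals must be genotyped")
    if (is.null(msg)) TRUE else msg
})
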