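## End-to-end pipeline: (optional) simulation -> relationship -> MLMA ->
## genomic control -> thresholds -> regions, with files and a JSON summary.

#' Build a run configuration
#'
#' @param genotypes,phenotype,pedigree input paths (genotypes as VCF or
#'   dosage TSV + `snpMap`); all ignored when `simulate` is given.
#' @param snpMap SNP map TSV path for dosage input.
#' @param simulate optional [PopulationDesign-class]; when present the
#'   inputs are simulated and written to `outDir`.
#' @param outDir output directory (created if missing).
#' @param relationship `"full_G"`, `"LOCO_G"` or `"A"` polygenic covariance
#'   protocol for the scan.
#' @param grmMethod `"yang"` or `"vanraden1"` scaling for genomic kinships.
#' @param gcMode genomic control applied to the scan: `"none"`, `"genome"`
#'   or `"per_chromosome"`.
#' @param alpha significance level for all threshold procedures.
#' @param procedures subset of `c("permutation", "bonferroni_total",
#'   "bonferroni_me", "fdr_bh", "fdr_by")`.
#' @param nPermutations permutation replicates when `"permutation"` is
#'   requested.
#' @param seed master seed; recorded in the summary and all headers.
#' @return a validated config list of class `mlmaSigConfig`.
#' @export
runConfig <- function(genotypes = NULL, phenotype = NULL, pedigree = NULL,
                      snpMap = NULL, simulate = NULL, outDir = "mlma_out",
                      relationship = c("full_G", "LOCO_G", "A"),
                      grmMethod = c("yang", "vanraden1"),
                      gcMode = c("none", "genome", "per_chromosome"),
                      alpha = 0.05,
                      procedures = c("bonferroni_total", "bonferroni_me",
                                     "fdr_bh", "fdr_by"),
                      nPermutations = 100L, seed = 1L) {
    relationship <- match.arg(relationship)
    grmMethod <- match.arg(grmMethod)
    gcMode <- match.arg(gcMode)
    known <- c("permutation", "bonferroni_total", "bonferroni_me",
               "fdr_bh", "fdr_by")
    if (length(setdiff(procedures, known)))
        stop("unknown procedures: ", paste(setdiff(procedures, known),
                                           collapse = ", "))
    if (is.null(simulate)) {
        for (p in c(genotypes, phenotype))
            if (!is.null(p) && !file.exists(p)) stop("missing input file: ", p)
        if (is.null(genotypes) || is.null(phenotype))
            stop("either simulate or genotype+phenotype paths are required")
    }
    structure(list(genotypes = genotypes, phenotype = phenotype,
                   pedigree = pedigree, snpMap = snpMap, simulate = simulate,
                   outDir = outDir, relationship = relationship,
                   grmMethod = grmMethod, gcMode = gcMode, alpha = alpha,
                   procedures = procedures,
                   nPermutations = as.integer(nPermutations),
                   seed = as.integer(seed)),
              class = "mlmaSigConfig")
}

#' Read a run configuration from YAML
#'
#' Keys mirror the [runConfig()] arguments; a `simulate:` block holds
#' [populationDesign()] fields.
#'
#' @param path YAML (or key: value) file.
#' @return a config list, as [runConfig()].
#' @export
readRunConfig <- function(path) {
    y <- yaml::read_yaml(path)
    if (!is.null(y$simulate)) {
        y$simulate$seed <- y$simulate$seed %||% y$seed %||% 1L
        y$simulate <- do.call(populationDesign, y$simulate)
    }
    do.call(runConfig, y)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.stageLog <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
        stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
    message(sprintf("[%s] done in %.1f s", stage,
                    proc.time()[["elapsed"]] - t0))
    res
}

#' Run the full significance-testing pipeline
#'
#' Executes (optional) simulation, relationship construction, the
#' mixed-model scan under the configured protocol, genomic inflation
#' reporting (and optional control), the requested threshold procedures and
#' QTL-region clustering; writes the association table, threshold table,
#' region list and a machine-readable JSON summary to `outDir`. Identical
#' config and seed give a byte-identical summary.
#'
#' @param config list from [runConfig()] or [readRunConfig()].
#' @return (invisibly) a list with the fitted objects: `assoc`, `inflation`,
#'   `thresholds`, `regions`, and `permutation`/`study` when applicable.
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "mlmaSigConfig"))
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    out <- function(f) file.path(config$outDir, f)
    study <- NULL

    if (!is.null(config$simulate)) {
        study <- .stageLog("simulate", simulateStudy(config$simulate))
        geno <- study@genotypes
        pheno <- study@phenotype
        ped <- study@pedigree
        writeDosageTsv(geno, out("genotypes.tsv"))
        writeSnpMap(geno, out("snp_map.tsv"))
        writeGenotypesVcf(geno, out("genotypes.vcf"))
        writePhenotype(pheno, out("phenotype.tsv"))
        writePedigree(ped, out("pedigree.tsv"))
    } else {
        geno <- .stageLog("read", readGenotypes(config$genotypes,
                                                mapPath = config$snpMap))
        pheno <- readPhenotype(config$phenotype)
        ped <- if (!is.null(config$pedigree)) readPedigree(config$pedigree)
               else NULL
    }

    assoc <- .stageLog("mlma", switch(config$relationship,
        full_G = {
            rel <- if (config$grmMethod == "yang") grmYang(geno)
                   else grmVanRaden1(geno)
            gwasScan(pheno, geno, rel)
        },
        LOCO_G = gwasLoco(pheno, geno, method = config$grmMethod),
        A = {
            if (is.null(ped)) stop("relationship 'A' needs a pedigree")
            rel <- subsetRelationship(pedigreeA(ped),
                                      intersect(sampleIds(geno), pheno$id))
            gwasScan(pheno, geno, rel)
        }))

    inflation <- .stageLog("genomic_control", inflationFactor(assoc))
    assocUsed <- if (config$gcMode != "none")
        applyGenomicControl(assoc, config$gcMode) else assoc
    writeAssoc(assocUsed, out("assoc.tsv"))

    thresholds <- list()
    permres <- NULL
    pv <- setNames(assocResults(assoc)$p, assocResults(assoc)$snp)
    for (proc in config$procedures) {
        thresholds[[proc]] <- .stageLog(proc, switch(proc,
            bonferroni_total = bonferroniThreshold(config$alpha, length(pv),
                                                   assoc = assocUsed),
            bonferroni_me = {
                me <- meFromGrm(grmVanRaden1(geno))
                bonferroniThreshold(config$alpha, me, assoc = assocUsed,
                                    procedure = "bonferroni_me")
            },
            # FDR on raw p-values: genomic control and FDR both rescale the
            # null distribution and are confounded when combined
            fdr_bh = fdrBH(pv, config$alpha, ids = names(pv)),
            fdr_by = fdrBY(pv, config$alpha, ids = names(pv)),
            permutation = {
                permres <- permutationThreshold(
                    pheno, geno,
                    rel = NULL,
                    nPermutations = config$nPermutations,
                    seed = .substream(config$seed, "permutation"),
                    protocol = if (config$relationship == "LOCO_G") "loco"
                               else "full",
                    method = config$grmMethod)
                new("ThresholdSet", procedure = "permutation",
                    alpha = 1 - permres@percentile / 100,
                    nTests = NA_real_,
                    thresholdNeglog10p = permres@threshold,
                    significantSnps = .sigSet(assocUsed, permres@threshold))
            }))
    }

    thrTab <- data.frame(
        procedure = names(thresholds),
        nTests = vapply(thresholds, function(t) t@nTests, 0),
        threshold = vapply(thresholds, function(t) t@thresholdNeglog10p, 0),
        nSignificant = vapply(thresholds,
                              function(t) length(t@significantSnps), 0L),
        stringsAsFactors = FALSE)
    data.table::fwrite(thrTab, out("thresholds.tsv"), sep = "\t", quote = FALSE)

    regions <- .stageLog("regions", {
        lapply(thresholds, function(t)
            clusterRegions(assocUsed, t@thresholdNeglog10p))
    })
    regTab <- do.call(rbind, lapply(names(regions), function(nm) {
        r <- regions[[nm]]
        if (!nrow(r)) return(NULL)
        cbind(procedure = nm, r, stringsAsFactors = FALSE)
    }))
    if (is.null(regTab))
        regTab <- data.frame(procedure = character(), chrom = character())
    data.table::fwrite(regTab, out("regions.tsv"), sep = "\t", quote = FALSE)

    summary <- list(
        seed = config$seed,
        relationship = config$relationship,
        grmMethod = config$grmMethod,
        gcMode = config$gcMode,
        nIndividuals = length(intersect(sampleIds(geno), pheno$id)),
        nSnps = length(pv),
        lambdaGenome = inflation@lambdaGenome,
        lambdaByChromosome = as.list(inflation@lambdaByChrom),
        thresholds = lapply(thresholds, function(t) list(
            threshold = t@thresholdNeglog10p,
            nTests = if (is.na(t@nTests)) NULL else t@nTests,
            nSignificant = length(t@significantSnps))),
        nRegions = lapply(regions, nrow))
    if (!is.null(permres))
        summary$permutation <- list(
            nPermutations = permres@nPermutations,
            meanLambda = mean(permres@lambda),
            sdLambda = sd(permres@lambda),
            threshold = permres@threshold)
    jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)

    invisible(list(study = study, assoc = assocUsed, inflation = inflation,
                   thresholds = thresholds, regions = regions,
                   permutation = permres))
}
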