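## Pedigreed population simulator: hierarchical mating design, founder
## haplotypes with first-order Markov LD, gene dropping with Haldane
## recombination, and QTL + polygenic phenotypes.

# Named substreams off the master seed, so stages can be regenerated
# independently. Kept below 2^31 - 1.
.substream <- function(seed, stage) {
    off <- c(haplotypes = 104729L, pedigree = 224737L, drop = 350377L,
             phenotype = 479909L, qtl = 611953L, permutation = 746773L)
    if (!stage %in% names(off)) stop("unknown substream: ", stage)
    as.integer((as.numeric(seed) * 2654435L + off[[stage]]) %% 2147483647)
}

#' Expected sibling counts under a population design
#'
#' Closed-form expectations for the number of full and half sibs of a
#' randomly chosen offspring. All litters of a dam are by her one sire, so
#' full sibs come from the own litter (size-biased when `litterSize` is
#' fractional) plus the dam's other litters; half sibs are all offspring of
#' the sire's other dams.
#'
#' @param design a [PopulationDesign-class].
#' @return named numeric: `fullSibs`, `halfSibs`.
#' @examples
#' expectedSibCounts(populationDesign(litterSize = 3)) # 2 and 42
#' @export
expectedSibCounts <- function(design) {
    L <- design@litterSize
    k <- floor(L); f <- L - k
    # size-biased within-litter sib count E[L(L-1)]/E[L] for L = k + Bern(f)
    own <- if (L == k) k - 1 else k * (k - 1 + 2 * f) / (k + f)
    full <- own + (design@littersPerDam - 1L) * L
    half <- (design@damsPerSire - 1L) * design@littersPerDam * L
    c(fullSibs = full, halfSibs = half)
}

#' Build the pedigree of a hierarchical mating design
#'
#' Founders (sires and dams, both parents unknown) followed by one offspring
#' generation: each sire is mated to `damsPerSire` dams, each dam produces
#' `littersPerDam` litters by that sire, each litter of size
#' `floor(litterSize)` plus a Bernoulli remainder. Records are topologically
#' ordered (parents before offspring); either both parents are known or
#' neither is.
#'
#' @param design a [PopulationDesign-class].
#' @return data.frame with columns `id`, `sire`, `dam` (character, NA =
#'   unknown) and a logical `founder` column.
#' @export
buildPedigree <- function(design) {
    set.seed(.substream(design@seed, "pedigree"))
    sires <- sprintf("S%03d", seq_len(design@nSires))
    dams <- sprintf("D%03d", seq_len(design@nSires * design@damsPerSire))
    damSire <- rep(sires, each = design@damsPerSire)
    k <- floor(design@litterSize); f <- design@litterSize - k
    recs <- list(data.frame(id = c(sires, dams), sire = NA_character_,
                            dam = NA_character_, stringsAsFactors = FALSE))
    cnt <- 0L
    for (d in seq_along(dams)) {
        for (l in seq_len(design@littersPerDam)) {
            size <- k + (f > 0 && runif(1) < f)
            if (size < 1L) next
            ids <- sprintf("O%05d", cnt + seq_len(size))
            cnt <- cnt + size
            recs[[length(recs) + 1L]] <- data.frame(
                id = ids, sire = damSire[d], dam = dams[d],
                stringsAsFactors = FALSE)
        }
    }
    ped <- do.call(rbind, recs)
    ped$founder <- is.na(ped$sire) & is.na(ped$dam)
    rownames(ped) <- NULL
    ped
}

#' Realized sibling counts from a pedigree
#'
#' Brute-force count of full sibs (same sire and same dam) and half sibs
#' (exactly one shared parent) per non-founder, averaged.
#'
#' @param pedigree data.frame as returned by [buildPedigree()].
#' @return named numeric: mean `fullSibs` and `halfSibs` per offspring.
#' @export
realizedSibCounts <- function(pedigree) {
    off <- pedigree[!is.na(pedigree$sire) & !is.na(pedigree$dam), ]
    if (!nrow(off)) return(c(fullSibs = 0, halfSibs = 0))
    famFull <- paste(off$sire, off$dam)
    full <- table(famFull)[famFull] - 1L
    bySire <- table(off$sire)[off$sire]
    byDam <- table(off$dam)[off$dam]
    # sibs sharing the sire or the dam but not both
    half <- (bySire - 1L) + (byDam - 1L) - 2L * full
    c(fullSibs = mean(full), halfSibs = mean(half))
}

#' Simulate founder haplotypes with first-order Markov LD
#'
#' Binary haplotypes per chromosome. Site `j` has a stationary allele
#' frequency drawn from Uniform(`mafMin`, 0.5); conditional on site `j-1`
#' the allele at `j` is drawn so that the allelic correlation between
#' adjacent sites equals `ldRho` (transition probabilities clipped to
#' \[0, 1\] when the target correlation is unattainable for a frequency
#' pair, which caps the realized correlation at its Frechet bound). Under
#' homogeneous frequencies the expected r2 between sites `k` apart is
#' `ldRho^(2k)`, a monotone geometric decay.
#'
#' @param design a [PopulationDesign-class].
#' @param nHaplotypes number of haplotypes to draw; defaults to two per
#'   founder of the mating design.
#' @return list with `haplotypes` (nHaplotypes x nSnps 0/1 matrix), `freq`
#'   (stationary frequencies) and `map` (data.frame chrom, bp, snp).
#' @export
simulateFounderHaplotypes <- function(design,
                                      nHaplotypes = 2L * design@nSires *
                                          (1L + design@damsPerSire)) {
    if (design@snpsPerChromosome < 2L) stop("need >= 2 SNPs per chromosome")
    if (design@ldRho < 0 || design@ldRho >= 1) stop("ldRho must lie in [0, 1)")
    set.seed(.substream(design@seed, "haplotypes"))
    mPer <- design@snpsPerChromosome
    rho <- design@ldRho
    haps <- vector("list", design@nChromosomes)
    freqs <- vector("list", design@nChromosomes)
    maps <- vector("list", design@nChromosomes)
    for (cc in seq_len(design@nChromosomes)) {
        p <- runif(mPer, design@mafMin, 0.5)
        bp <- sort(sample.int(design@chromosomeLengthBp, mPer))
        H <- matrix(0L, nHaplotypes, mPer)
        H[, 1] <- rbinom(nHaplotypes, 1L, p[1])
        for (j in 2:mPer) {
            s <- sqrt(p[j] * (1 - p[j]) / (p[j - 1] * (1 - p[j - 1])))
            p11 <- min(1, max(0, p[j] + rho * (1 - p[j - 1]) * s))
            p10 <- min(1, max(0, p[j] - rho * p[j - 1] * s))
            H[, j] <- rbinom(nHaplotypes, 1L, ifelse(H[, j - 1] == 1L, p11, p10))
        }
        haps[[cc]] <- H
        freqs[[cc]] <- p
        maps[[cc]] <- data.frame(chrom = as.character(cc), bp = bp,
                                 snp = sprintf("snp_%d_%d", cc, seq_len(mPer)),
                                 stringsAsFactors = FALSE)
    }
    list(haplotypes = do.call(cbind, haps),
         freq = unlist(freqs),
         map = do.call(rbind, maps))
}

# One recombinant gamete from a parent's two haplotypes.
# morgans/bp positions per chromosome are precomputed by the caller.
.gamete <- function(h1, h2, chromIdx, chromBp, morgans, cmPerMbp) {
    out <- integer(length(h1))
    for (cc in seq_along(chromIdx)) {
        idx <- chromIdx[[cc]]
        bp <- chromBp[[cc]]
        phase <- rep(rbinom(1L, 1L, 0.5), length(idx))
        if (cmPerMbp > 0) {
            nCo <- rpois(1L, morgans[cc])
            if (nCo > 0) {
                co <- sort(runif(nCo, 0, max(bp)))
                phase <- (phase + findInterval(bp, co)) %% 2L
            }
        }
        out[idx] <- ifelse(phase == 1L, h1[idx], h2[idx])
    }
    out
}

#' Drop genes through a pedigree
#'
#' Founders receive haplotype pairs from the simulated pool; every offspring
#' receives one recombinant gamete from each parent, with crossovers placed
#' by a Poisson process at `cmPerMbp` cM/Mbp (Haldane model, no
#' interference). Dosage is the sum of the two inherited alleles.
#'
#' @param design a [PopulationDesign-class].
#' @param founderHaps result of [simulateFounderHaplotypes()].
#' @param pedigree data.frame from [buildPedigree()]; parents must precede
#'   offspring and each individual must have both parents known or neither.
#' @param cmPerMbp recombination rate (default 1 cM/Mbp; 0 disables
#'   recombination so each gamete is an intact parental haplotype).
#' @return A [SnpGeno-class] with one row per pedigree member, plus the full
#'   haplotypes in `metadata()` (`hap1`, `hap2`) for downstream gene-flow.
#' @export
dropGenes <- function(design, founderHaps, pedigree, cmPerMbp = 1) {
    oneParent <- xor(is.na(pedigree$sire), is.na(pedigree$dam))
    if (any(oneParent))
        stop("individuals with exactly one known parent are not supported: ",
             paste(head(pedigree$id[oneParent]), collapse = ", "))
    set.seed(.substream(design@seed, "drop"))
    map <- founderHaps$map
    m <- nrow(map)
    n <- nrow(pedigree)
    chromLv <- unique(map$chrom)
    chromIdx <- lapply(chromLv, function(cc) which(map$chrom == cc))
    chromBp <- lapply(chromIdx, function(ii) map$bp[ii])
    morgans <- vapply(chromBp, function(bp) max(bp) * cmPerMbp * 1e-8, 0)
    H1 <- matrix(0L, n, m); H2 <- matrix(0L, n, m)
    rownames(H1) <- rownames(H2) <- pedigree$id
    founders <- which(is.na(pedigree$sire))
    if (2L * length(founders) > nrow(founderHaps$haplotypes))
        stop("founder haplotype pool too small")
    H1[founders, ] <- founderHaps$haplotypes[2L * seq_along(founders) - 1L, ]
    H2[founders, ] <- founderHaps$haplotypes[2L * seq_along(founders), ]
    rowOf <- setNames(seq_len(n), pedigree$id)
    for (i in seq_len(n)) {
        if (is.na(pedigree$sire[i])) next
        s <- rowOf[[pedigree$sire[i]]]
        d <- rowOf[[pedigree$dam[i]]]
        if (is.null(s) || is.null(d) || s >= i || d >= i)
            stop("pedigree must list parents before offspring")
        H1[i, ] <- .gamete(H1[s, ], H2[s, ], chromIdx, chromBp, morgans, cmPerMbp)
        H2[i, ] <- .gamete(H1[d, ], H2[d, ], chromIdx, chromBp, morgans, cmPerMbp)
    }
    g <- SnpGeno(H1 + H2, chrom = map$chrom, bp = map$bp, snpId = map$snp,
                 sampleId = pedigree$id)
    S4Vectors::metadata(g) <- list(hap1 = H1, hap2 = H2)
    g
}

#' Simulate a quantitative phenotype with QTL and a polygenic background
#'
#' `y = sum_q x_q beta_q + g + e` with `e ~ N(0, sigmaE2)` and a polygenic
#' term `g` of variance `sigmaG2` chosen so that the polygenic fraction of
#' the total variance equals `h2Polygenic`:
#' `sigmaG2 = h2 (vQtl + sigmaE2) / (1 - h2)`. The polygenic term is drawn
#' either by pedigree gene flow (`mode = "pedigree"`: founders
#' `N(0, sigmaG2)`, offspring mid-parent plus Mendelian-sampling
#' `N(0, sigmaG2 / 2)`) or as the sum of many small random SNP effects
#' rescaled to `sigmaG2` exactly (`mode = "snp"`).
#'
#' @param genotypes a [SnpGeno-class] (all individuals to phenotype).
#' @param qtlIndex integer SNP column indices of the causal variants.
#' @param qtlEffects allele-substitution effects, same length.
#' @param h2Polygenic polygenic fraction of the phenotypic variance, \[0, 1).
#' @param sigmaE2 residual variance (> 0).
#' @param pedigree required for `mode = "pedigree"`.
#' @param mode `"pedigree"` or `"snp"` polygenic model.
#' @param seed integer seed for this stage.
#' @return list with `phenotype` (data.frame id, value) and `varianceTruth`
#'   (named numeric: sigmaG2, sigmaE2, vQtl, h2Polygenic).
#' @export
simulatePhenotype <- function(genotypes, qtlIndex = integer(), qtlEffects = numeric(),
                              h2Polygenic = 0.3, sigmaE2 = 0.6,
                              pedigree = NULL, mode = c("pedigree", "snp"),
                              seed = 1L) {
    mode <- match.arg(mode)
    if (length(qtlIndex) != length(qtlEffects))
        stop("qtlIndex and qtlEffects must have equal length")
    if (h2Polygenic < 0 || h2Polygenic >= 1)
        stop("requested h2Polygenic unattainable: must lie in [0, 1)")
    if (sigmaE2 < 0) stop("sigmaE2 must be >= 0")
    X <- dosageMatrix(genotypes)
    n <- nrow(X)
    if (length(qtlIndex) && (min(qtlIndex) < 1 || max(qtlIndex) > ncol(X)))
        stop("qtlIndex out of range")
    set.seed(seed)
    yQtl <- if (length(qtlIndex)) as.vector(X[, qtlIndex, drop = FALSE] %*% qtlEffects)
            else rep(0, n)
    vQtl <- if (length(qtlIndex)) var(yQtl) else 0
    sigmaG2 <- if (h2Polygenic > 0) h2Polygenic * (vQtl + sigmaE2) / (1 - h2Polygenic)
               else 0
    g <- rep(0, n)
    if (sigmaG2 > 0) {
        if (mode == "pedigree") {
            if (is.null(pedigree)) stop("pedigree mode needs a pedigree")
            gp <- setNames(rep(NA_real_, nrow(pedigree)), pedigree$id)
            for (i in seq_len(nrow(pedigree))) {
                if (is.na(pedigree$sire[i]))
                    gp[i] <- rnorm(1, 0, sqrt(sigmaG2))
                else
                    gp[i] <- 0.5 * (gp[[pedigree$sire[i]]] + gp[[pedigree$dam[i]]]) +
                        rnorm(1, 0, sqrt(sigmaG2 / 2))
            }
            g <- gp[rownames(X)]
            if (anyNA(g)) stop("pedigree does not cover all genotyped individuals")
        } else {
            u <- rnorm(ncol(X))
            Z <- scale(X, center = TRUE, scale = FALSE)
            Z[is.na(Z)] <- 0
            gRaw <- as.vector(Z %*% u)
            vg <- var(gRaw)
            if (vg <= 0) stop("no polymorphic SNPs to carry the polygenic term")
            g <- gRaw * sqrt(sigmaG2 / vg)
        }
    }
    e <- if (sigmaE2 > 0) rnorm(n, 0, sqrt(sigmaE2)) else rep(0, n)
    y <- yQtl + as.numeric(g) + e
    vt <- c(sigmaG2 = sigmaG2, sigmaE2 = sigmaE2, vQtl = vQtl,
            h2Polygenic = if (sigmaG2 + sigmaE2 + vQtl > 0)
                sigmaG2 / (sigmaG2 + sigmaE2 + vQtl) else 0)
    list(phenotype = data.frame(id = rownames(X), value = as.numeric(y),
                                stringsAsFactors = FALSE),
         varianceTruth = vt)
}

# Pick QTL SNPs: spread across chromosomes, offspring MAF >= 0.1 preferred.
.pickQtl <- function(geno, nQtl, seed) {
    if (nQtl == 0L) return(integer())
    set.seed(.substream(seed, "qtl"))
    info <- snpInfo(geno)
    X <- dosageMatrix(geno)
    p <- colMeans(X, na.rm = TRUE) / 2
    ok <- which(pmin(p, 1 - p) >= 0.1)
    if (length(ok) < nQtl) ok <- which(pmin(p, 1 - p) > 0)
    chrOf <- info$chrom[ok]
    # round-robin over chromosomes so QTL are spread out
    chosen <- integer()
    lv <- unique(chrOf)
    while (length(chosen) < nQtl && length(ok)) {
        for (cc in lv) {
            cand <- setdiff(ok[chrOf == cc], chosen)
            if (length(cand)) chosen <- c(chosen, sample(cand, 1L))
            if (length(chosen) == nQtl) break
        }
        if (all(ok %in% chosen)) break
    }
    sort(chosen[seq_len(min(nQtl, length(chosen)))])
}

#' Simulate a complete study
#'
#' Chains [buildPedigree()], [simulateFounderHaplotypes()], [dropGenes()]
#' and [simulatePhenotype()] under the design's master seed. Genotypes and
#' phenotypes are restricted to the offspring generation (the "genotyped
#' animals"); the pedigree retains the founders. The residual variance is
#' set so the total phenotypic variance is ~1: `sigmaE2 = 1 - h2 - vQtl`.
#'
#' @param design a [PopulationDesign-class].
#' @param polygenicMode `"pedigree"` (gene flow) or `"snp"` (sum of small
#'   SNP effects).
#' @param cmPerMbp recombination rate for gene dropping.
#' @return A [SimulatedStudy-class].
#' @examples
#' st <- simulateStudy(populationDesign(nSires = 4L, damsPerSire = 3L,
#'                                      snpsPerChromosome = 50L,
#'                                      nChromosomes = 2L, seed = 7L))
#' st
#' @export
simulateStudy <- function(design, polygenicMode = c("pedigree", "snp"),
                          cmPerMbp = 1) {
    polygenicMode <- match.arg(polygenicMode)
    ped <- buildPedigree(design)
    haps <- simulateFounderHaplotypes(design)
    genoAll <- dropGenes(design, haps, ped, cmPerMbp = cmPerMbp)
    offIds <- ped$id[!ped$founder]
    geno <- genoAll[, offIds]
    S4Vectors::metadata(geno) <- list()  # haplotypes not needed downstream
    geno <- new("SnpGeno", geno)
    qtlIdx <- .pickQtl(geno, design@nQtl, design@seed)
    eff <- design@qtlEffects[seq_along(qtlIdx)]
    X <- dosageMatrix(geno)
    vQtl <- if (length(qtlIdx))
        var(as.vector(X[, qtlIdx, drop = FALSE] %*% eff)) else 0
    sigmaE2 <- 1 - design@h2Polygenic - vQtl
    if (sigmaE2 <= 0)
        stop("QTL variance plus polygenic heritability exceeds the unit ",
             "phenotypic variance; reduce qtlEffects or h2Polygenic")
    sim <- simulatePhenotype(geno, qtlIdx, eff,
                             h2Polygenic = design@h2Polygenic,
                             sigmaE2 = sigmaE2, pedigree = ped,
                             mode = polygenicMode,
                             seed = .substream(design@seed, "phenotype"))
    qtlTruth <- data.frame(snp = snpInfo(geno)$snp[qtlIdx], index = qtlIdx,
                           effect = eff, stringsAsFactors = FALSE)
    new("SimulatedStudy", genotypes = geno,
        pedigree = ped[, c("id", "sire", "dam", "founder")],
        phenotype = sim$phenotype, qtlTruth = qtlTruth,
        varianceTruth = sim$varianceTruth)
}
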