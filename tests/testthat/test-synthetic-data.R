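test_that("founder haplotypes realize the requested adjacent-site LD", {
    # independence case
    d0 <- populationDesign(nChromosomes = 1L, snpsPerChromosome = 40L,
                           ldRho = 0, seed = 3L)
    h0 <- simulateFounderHaplotypes(d0, nHaplotypes = 10000L)
    r2 <- sapply(seq_len(39), function(j)
        cor(h0$haplotypes[, j], h0$haplotypes[, j + 1])^2)
    expect_lt(mean(r2), 0.003)

    # Markov closed form rho^2 at homogeneous frequencies
    d1 <- populationDesign(nChromosomes = 1L, snpsPerChromosome = 40L,
                           ldRho = 0.95, mafMin = 0.5, seed = 3L)
    h1 <- simulateFounderHaplotypes(d1, nHaplotypes = 10000L)
    r2 <- sapply(seq_len(39), function(j)
        cor(h1$haplotypes[, j], h1$haplotypes[, j + 1])^2)
    expect_equal(mean(r2), 0.95^2, tolerance = 0.02 / 0.9025)

    # a copied column is in perfect LD with itself
    dup <- cbind(h1$haplotypes[, 1], h1$haplotypes[, 1])
    expect_identical(cor(dup[, 1], dup[, 2])^2, 1)

    # r2 decays geometrically with marker distance
    r2lag <- sapply(1:5, function(k)
        mean(sapply(seq_len(40 - k), function(j)
            cor(h1$haplotypes[, j], h1$haplotypes[, j + k])^2)))
    expect_true(all(diff(r2lag) < 0))
})

test_that("pedigree realizes the designed sib counts", {
    # no litters beyond a singleton: no full sibs
    d <- populationDesign(nSires = 5L, damsPerSire = 3L, littersPerDam = 1L,
                          litterSize = 1, seed = 2L)
    expect_equal(unname(realizedSibCounts(buildPedigree(d))[["fullSibs"]]), 0)

    # hierarchical design 20 x 15 x 3: brute-force sib counting
    d2 <- populationDesign(nSires = 20L, damsPerSire = 15L, litterSize = 3,
                           seed = 2L)
    ped <- buildPedigree(d2)
    off <- ped[!ped$founder, ]
    full <- half <- 0
    for (i in seq_len(nrow(off))) {
        sameS <- off$sire == off$sire[i]
        sameD <- off$dam == off$dam[i]
        full <- full + sum(sameS & sameD) - 1L
        half <- half + sum(xor(sameS, sameD))
    }
    expect_equal(full / nrow(off), 2)
    expect_equal(half / nrow(off), 42)
    expect_equal(unname(realizedSibCounts(ped)),
                 c(full / nrow(off), half / nrow(off)))

    # the default design reproduces the study population's average of
    # ~2.2 full sibs per individual
    dDef <- populationDesign(seed = 9L)
    expect_equal(unname(realizedSibCounts(buildPedigree(dDef))[["fullSibs"]]),
                 2.2, tolerance = 0.3 / 2.2)
    sib <- expectedSibCounts(dDef)
    expect_equal(unname(sib[["fullSibs"]]), 2.25, tolerance = 1e-12)
    expect_equal(unname(sib[["halfSibs"]]), 44.8, tolerance = 1e-12)
})

test_that("gene dropping transmits parental haplotypes correctly", {
    d <- populationDesign(nSires = 10L, damsPerSire = 4L, litterSize = 3,
                          nChromosomes = 2L, snpsPerChromosome = 60L,
                          seed = 8L)
    ped <- buildPedigree(d)
    haps <- simulateFounderHaplotypes(d)

    # zero recombination: each offspring gamete is an intact parental
    # haplotype per chromosome
    g0 <- dropGenes(d, haps, ped, cmPerMbp = 0)
    H1 <- S4Vectors::metadata(g0)$hap1
    H2 <- S4Vectors::metadata(g0)$hap2
    info <- snpInfo(g0)
    offRows <- which(!ped$founder)
    for (i in offRows[1:10]) {
        s <- match(ped$sire[i], ped$id)
        for (cc in unique(info$chrom)) {
            idx <- info$chrom == cc
            expect_true(identical(H1[i, idx], H1[s, idx]) ||
                        identical(H1[i, idx], H2[s, idx]))
        }
    }

    # fixation: both parents homozygous => offspring dosage 2
    g1 <- dropGenes(d, haps, ped, cmPerMbp = 1)
    X <- dosageMatrix(g1)
    for (i in offRows[1:20]) {
        s <- match(ped$sire[i], ped$id); dm <- match(ped$dam[i], ped$id)
        fixed <- X[s, ] == 2 & X[dm, ] == 2
        if (any(fixed)) expect_true(all(X[i, fixed] == 2))
    }

    # an individual with exactly one known parent is rejected
    bad <- ped
    bad$dam[which(!bad$founder)[1]] <- NA
    expect_error(dropGenes(d, haps, bad), "one known parent")
})

test_that("full sibs share half their genome on average", {
    d <- populationDesign(nSires = 20L, damsPerSire = 5L, litterSize = 4,
                          nChromosomes = 3L, snpsPerChromosome = 100L,
                          seed = 21L)
    ped <- buildPedigree(d)
    g <- dropGenes(d, simulateFounderHaplotypes(d), ped)
    off <- ped[!ped$founder, ]
    G <- grmVanRaden1(g)
    v <- relValues(G)
    fam <- split(off$id, paste(off$sire, off$dam))
    rel <- unlist(lapply(fam, function(ids) {
        if (length(ids) < 2) return(NULL)
        prs <- combn(ids, 2)
        v[cbind(prs[1, ], prs[2, ])]
    }))
    expect_gt(length(rel), 500)
    expect_equal(mean(rel), 0.5, tolerance = 0.05 / 0.5)
})

test_that("gene dropping conserves allele frequencies", {
    d <- populationDesign(nSires = 25L, damsPerSire = 20L, litterSize = 4,
                          nChromosomes = 2L, snpsPerChromosome = 60L,
                          seed = 13L)
    ped <- buildPedigree(d)
    g <- dropGenes(d, simulateFounderHaplotypes(d), ped)
    X <- dosageMatrix(g)
    pF <- colMeans(X[ped$founder, ]) / 2
    pO <- colMeans(X[!ped$founder, ]) / 2
    expect_gte(sum(!ped$founder), 2000)
    expect_lt(mean(abs(pF - pO)), 0.05)
    expect_lt(max(abs(pF - pO)), 0.1)
})

test_that("phenotype simulation realizes the requested architecture", {
    st <- tinyStudy()
    geno <- st@genotypes
    X <- dosageMatrix(geno)

    # pure noise: no QTL, no polygenic background
    s0 <- simulatePhenotype(geno, h2Polygenic = 0, sigmaE2 = 2, seed = 4L)
    expect_equal(var(s0$phenotype$value), 2, tolerance = 0.25)
    expect_equal(unname(s0$varianceTruth[["sigmaG2"]]), 0)

    # a single QTL contributes 2p(1-p)beta^2 variance
    j <- which.min(abs(colMeans(X) / 2 - 0.3))[1]
    s1 <- simulatePhenotype(geno, qtlIndex = j, qtlEffects = 0.34,
                            h2Polygenic = 0, sigmaE2 = 0.5, seed = 4L)
    p <- mean(X[, j]) / 2
    expect_equal(unname(s1$varianceTruth[["vQtl"]]), 2 * p * (1 - p) * 0.34^2,
                 tolerance = 0.15)

    # noise-free single-QTL phenotype is collinear with its dosage
    s2 <- simulatePhenotype(geno, qtlIndex = j, qtlEffects = 0.34,
                            h2Polygenic = 0, sigmaE2 = 0, seed = 4L)
    expect_equal(cor(s2$phenotype$value, X[, j]), 1, tolerance = 1e-12)

    # impossible architectures are refused
    expect_error(simulatePhenotype(geno, h2Polygenic = 1, sigmaE2 = 1),
                 "unattainable")
})

test_that("seeded simulation is bit-reproducible", {
    d <- populationDesign(nSires = 5L, damsPerSire = 3L, litterSize = 2,
                          nChromosomes = 2L, snpsPerChromosome = 30L,
                          seed = 77L)
    s1 <- simulateStudy(d)
    s2 <- simulateStudy(d)
    expect_identical(dosageMatrix(s1@genotypes), dosageMatrix(s2@genotypes))
    expect_identical(s1@phenotype, s2@phenotype)
    expect_identical(s1@qtlTruth, s2@qtlTruth)
})
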