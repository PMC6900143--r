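test_that("REML degenerates gracefully under an identity kinship", {
    set.seed(10)
    n <- 60
    y <- rnorm(n, 5, 2)
    ids <- sprintf("i%03d", seq_len(n))
    ph <- data.frame(id = ids, value = y)
    vc <- remlFit(ph, identityRel(n, ids))
    # with K = I the split sigmaG2/sigmaE2 is unidentifiable; the boundary
    # solution sigmaG2 = 0 with sigmaE2 = residual variance is returned
    expect_equal(vc@sigmaG2, 0)
    expect_true(vc@boundary)
    expect_equal(vc@sigmaE2, var(y), tolerance = 1e-6)
})

test_that("REML is scale-equivariant and improves on its start points", {
    st <- tinyStudy()
    G <- grmYang(st@genotypes)
    ph <- st@phenotype
    vc1 <- remlFit(ph, G)
    ph2 <- ph; ph2$value <- 3 * ph$value
    vc2 <- remlFit(ph2, G)
    expect_equal(vc2@sigmaG2, 9 * vc1@sigmaG2, tolerance = 1e-4)
    expect_equal(vc2@sigmaE2, 9 * vc1@sigmaE2, tolerance = 1e-4)
    expect_equal(vc2@h2, vc1@h2, tolerance = 1e-5)

    # the optimum dominates the zero-heritability start point
    ctxIds <- intersect(sampleIds(G), ph$id)
    K <- relValues(G)[ctxIds, ctxIds]
    eg <- eigen(K, symmetric = TRUE)
    yt <- crossprod(eg$vectors, ph$value[match(ctxIds, ph$id)])
    Wt <- crossprod(eg$vectors, matrix(1, length(ctxIds), 1))
    atZero <- mlmaSig:::.remlObjective(log(1e-8), yt, Wt,
                                       pmax(eg$values, 0),
                                       length(ctxIds) - 1L)
    expect_gte(vc1@logLik, as.numeric(atZero) - 1e-6)
})

test_that("REML recovers a simulated polygenic heritability", {
    d <- populationDesign(nSires = 10L, damsPerSire = 8L, litterSize = 5,
                          nChromosomes = 3L, snpsPerChromosome = 150L,
                          qtlEffects = numeric(0), h2Polygenic = 0.3,
                          seed = 31L)
    st <- simulateStudy(d, polygenicMode = "snp")
    vc <- remlFit(st@phenotype, grmYang(st@genotypes))
    expect_equal(vc@h2, 0.3, tolerance = 0.15 / 0.3)
})

test_that("the scan reduces exactly to OLS under an identity kinship", {
    set.seed(11)
    n <- 50
    X <- matrix(rbinom(n * 25, 2, 0.4), n, 25)
    g <- makeGeno(X)
    ids <- sampleIds(g)
    y <- rnorm(n)
    ph <- data.frame(id = ids, value = y)
    I <- identityRel(n, ids)
    at <- assocScan(ph, g, I, remlFit(ph, I))
    tb <- assocResults(at)
    mi <- match(tb$snp, colnames(dosageMatrix(g)))
    ols <- t(sapply(mi, function(j)
        summary(lm(y ~ X[, j]))$coefficients[2, 1:2]))
    expect_equal(tb$b, unname(ols[, 1]), tolerance = 1e-8)
    expect_equal(tb$se, unname(ols[, 2]), tolerance = 1e-8)
})

test_that("a strong simulated effect is the scan's top hit", {
    st <- tinyStudy()
    X <- dosageMatrix(st@genotypes)
    j <- which.min(abs(colMeans(X) / 2 - 0.35))[1]
    set.seed(12)
    ph <- data.frame(id = rownames(X),
                     value = 0.34 * X[, j] + rnorm(nrow(X), 0, 0.05))
    at <- gwasScan(ph, st@genotypes, grmYang(st@genotypes))
    tb <- assocResults(at)
    expect_identical(tb$snp[which.max(tb$chi2)], colnames(X)[j])
})

test_that("p-values are invariant to phenotype shifts and relabeling", {
    st <- tinyStudy()
    G <- grmYang(st@genotypes)
    ph <- st@phenotype
    base <- gwasScan(ph, st@genotypes, G)
    shifted <- ph; shifted$value <- ph$value + 100
    at2 <- gwasScan(shifted, st@genotypes, G)
    expect_equal(assocResults(base)$p, assocResults(at2)$p,
                 tolerance = 1e-8)
    # consistent relabeling: shuffle phenotype row order only
    at3 <- gwasScan(ph[sample(nrow(ph)), ], st@genotypes, G)
    expect_equal(assocResults(base)$p, assocResults(at3)$p,
                 tolerance = 1e-10)
})

test_that("fixed SNP covariates remove their own association peak", {
    st <- tinyStudy()
    X <- dosageMatrix(st@genotypes)
    j <- which.min(abs(colMeans(X) / 2 - 0.35))[1]
    set.seed(13)
    ph <- data.frame(id = rownames(X),
                     value = 0.5 * X[, j] + rnorm(nrow(X), 0, 0.5))
    G <- grmYang(st@genotypes)
    at0 <- gwasScan(ph, st@genotypes, G)
    tb0 <- assocResults(at0)
    top <- tb0$snp[which.max(tb0$neglog10p)]
    peak <- max(tb0$neglog10p)
    at1 <- gwasScan(ph, st@genotypes, G, fixedSnps = top)
    tb1 <- assocResults(at1)
    expect_false(top %in% tb1$snp)  # fixed SNP is not tested
    topRow <- tb0[tb0$snp == top, ]
    near <- tb1$chr == topRow$chr & abs(tb1$bp - topRow$bp) <= 5e5
    expect_true(all(tb1$neglog10p[near] < peak))
})

test_that("LOCO scanning uses the off-chromosome kinship", {
    st <- tinyStudy()
    ph <- st@phenotype
    at <- gwasLoco(ph, st@genotypes)
    tb <- assocResults(at)
    expect_setequal(tb$snp, snpInfo(st@genotypes)$snp)
    expect_named(at@vc, chromosomes(st@genotypes), ignore.order = TRUE)

    # per definition: chromosome 1 statistics equal a manual scan under the
    # GRM built from the other chromosomes
    rel <- grmLoco(st@genotypes, "1")
    vc <- remlFit(ph, rel)
    manual <- assocResults(assocScan(ph, st@genotypes, rel, vc,
                                     snps = snpInfo(st@genotypes)$snp[
                                         snpInfo(st@genotypes)$chrom == "1"]))
    expect_equal(tb[tb$chr == "1", ], manual[manual$chr == "1", ],
                 tolerance = 1e-10)
})

test_that("a null scan on unrelated individuals is calibrated", {
    set.seed(14)
    n <- 300; m <- 4000
    X <- matrix(rbinom(n * m, 2, runif(m, 0.1, 0.5)), n, m, byrow = TRUE)
    g <- makeGeno(X)
    ph <- data.frame(id = sampleIds(g), value = rnorm(n))
    I <- identityRel(n, sampleIds(g))
    at <- assocScan(ph, g, I, remlFit(ph, I))
    lam <- lambdaGenome(inflationFactor(at))
    expect_equal(lam, 1, tolerance = 0.1)
})

test_that("monomorphic SNPs are dropped with a message", {
    set.seed(15)
    X <- matrix(rbinom(30 * 5, 2, 0.4), 30, 5)
    X[, 3] <- 2
    g <- makeGeno(X)
    ph <- data.frame(id = sampleIds(g), value = rnorm(30))
    I <- identityRel(30, sampleIds(g))
    expect_message(at <- assocScan(ph, g, I, remlFit(ph, I)),
                   "monomorphic")
    expect_identical(nrow(assocResults(at)), 4L)
})
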