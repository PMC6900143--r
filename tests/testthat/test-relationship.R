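test_that("VanRaden-1 GRM matches hand computation and basic structure", {
    # 2 individuals, 1 SNP, dosages 0 and 2: p = 0.5, Z = (-1, +1),
    # denominator 0.5 => G = [[2, -2], [-2, 2]]
    g <- makeGeno(matrix(c(0, 2), 2, 1))
    G <- grmVanRaden1(g)
    expect_equal(unname(relValues(G)), matrix(c(2, -2, -2, 2), 2),
                 tolerance = 1e-12)
    expect_identical(nSnpsUsed(G), 1L)

    # a duplicated individual: off-diagonal equals that individual's diagonal
    set.seed(1)
    X <- matrix(rbinom(5 * 40, 2, 0.35), 5, 40)
    X[5, ] <- X[1, ]
    G2 <- relValues(grmVanRaden1(makeGeno(X)))
    expect_equal(G2[1, 5], G2[1, 1], tolerance = 1e-12)

    # unrelated individuals at many independent SNPs: mean off-diagonal ~ 0,
    # mean diagonal ~ 1
    set.seed(2)
    Xu <- matrix(rbinom(200 * 10000, 2, runif(10000, 0.1, 0.5)),
                 200, 10000, byrow = TRUE)
    Gu <- relValues(grmVanRaden1(makeGeno(Xu)))
    expect_lt(abs(mean(Gu[upper.tri(Gu)])), 0.01)
    expect_equal(mean(diag(Gu)), 1, tolerance = 0.02)
})

test_that("Yang GRM diagonal and scaling behave as defined", {
    # single SNP at p = 0.5: heterozygote diagonal = 1 + (1 - 2 + 0.5)/0.5 = 0
    g <- makeGeno(matrix(c(0, 1, 2, 1), 4, 1))
    G <- relValues(grmYang(g))
    expect_equal(G[2, 2], 0, tolerance = 1e-12)
    expect_equal(G[4, 4], 0, tolerance = 1e-12)

    # with every SNP at p = 0.5 the Yang and VanRaden-1 off-diagonals agree
    set.seed(3)
    X <- t(replicate(6, sample(c(0, 1, 1, 2))))  # every column mean 1
    X <- t(X)
    gy <- relValues(grmYang(makeGeno(X)))
    gv <- relValues(grmVanRaden1(makeGeno(X)))
    expect_equal(gy[upper.tri(gy)], gv[upper.tri(gv)], tolerance = 1e-10)

    # permuting individuals permutes rows and columns consistently
    set.seed(4)
    X2 <- matrix(rbinom(8 * 30, 2, 0.4), 8, 30)
    G1 <- relValues(grmYang(makeGeno(X2)))
    perm <- sample(8)
    G2 <- relValues(grmYang(SnpGeno(X2[perm, ], chrom = rep("1", 30),
                                    bp = seq_len(30) * 1000,
                                    sampleId = rownames(G1)[perm])))
    expect_equal(G2[rownames(G1), rownames(G1)], G1, tolerance = 1e-12)
})

test_that("GRMs are invariant to SNP column order", {
    set.seed(5)
    X <- matrix(rbinom(10 * 50, 2, 0.3), 10, 50)
    g1 <- makeGeno(X)
    perm <- sample(50)
    # same SNPs in a different submission order (positions reassigned so the
    # map stays increasing; content identical)
    g2 <- makeGeno(X[, perm])
    expect_equal(unname(relValues(grmVanRaden1(g1))),
                 unname(relValues(grmVanRaden1(g2))), tolerance = 1e-12)
    expect_equal(unname(relValues(grmYang(g1))),
                 unname(relValues(grmYang(g2))), tolerance = 1e-12)
})

test_that("LOCO GRMs exclude exactly the target chromosome", {
    set.seed(6)
    X <- matrix(rbinom(12 * 40, 2, 0.4), 12, 40)
    # two chromosomes with identical SNP content
    g <- makeGeno(cbind(X, X), chrom = rep(c("1", "2"), each = 40),
                  bp = rep(seq_len(40) * 1000, 2))
    gl <- grmLoco(g, "1", method = "vanraden1")
    gc2 <- grmVanRaden1(g, snps = 41:80)
    expect_equal(relValues(gl), relValues(gc2), tolerance = 1e-12)
    expect_identical(gl@excluded, "1")
    expect_match(relMethod(gl), "_loco$")

    # block additivity: per-chromosome ZZ' weighted by denominator share
    # reassembles the whole-genome VanRaden GRM
    set.seed(7)
    Y <- matrix(rbinom(12 * 60, 2, 0.35), 12, 60)
    gy <- makeGeno(Y, chrom = rep(c("1", "2", "3"), each = 20),
                   bp = rep(seq_len(20) * 1000, 3))
    full <- grmVanRaden1(gy, mafMin = 0)
    parts <- lapply(c("1", "2", "3"), function(cc) {
        sub <- which(snpInfo(gy)$chrom == cc)
        gsub <- grmVanRaden1(gy, snps = sub, mafMin = 0)
        X <- dosageMatrix(gy)[, sub]
        p <- colMeans(X) / 2
        relValues(gsub) * 2 * sum(p * (1 - p))
    })
    p <- colMeans(dosageMatrix(gy)) / 2
    expect_equal(Reduce(`+`, parts) / (2 * sum(p * (1 - p))),
                 relValues(full), tolerance = 1e-10)

    # leaving out a label with no SNPs changes nothing
    gl0 <- grmLoco(gy, "absent", method = "vanraden1", mafMin = 0)
    expect_equal(relValues(gl0), relValues(full), tolerance = 1e-12)
})

test_that("pedigree A matrix follows the tabular recursion", {
    # unrelated founders
    ped0 <- data.frame(id = c("a", "b", "c"), sire = NA, dam = NA)
    expect_equal(unname(relValues(pedigreeA(ped0))), diag(3))

    # sire + dam + offspring
    trio <- data.frame(id = c("s", "d", "o"),
                       sire = c(NA, NA, "s"), dam = c(NA, NA, "d"))
    A <- relValues(pedigreeA(trio))
    expect_equal(A["o", "s"], 0.5)
    expect_equal(A["o", "o"], 1)

    # two full sibs of unrelated parents
    sibs <- data.frame(id = c("s", "d", "o1", "o2"),
                       sire = c(NA, NA, "s", "s"),
                       dam = c(NA, NA, "d", "d"))
    expect_equal(relValues(pedigreeA(sibs))["o1", "o2"], 0.5)

    # "0" is read as unknown
    z <- data.frame(id = c("s", "o"), sire = c("0", "s"), dam = c("0", "0"))
    expect_error(pedigreeA(z), NA)

    # cycles / unordered pedigrees are refused
    bad <- data.frame(id = c("o", "s", "d"), sire = c("s", NA, NA),
                      dam = c("d", NA, NA))
    expect_error(pedigreeA(bad), "parents before offspring")
})

test_that("tabular A equals twice the recursive kinship oracle", {
    for (seed in 1:4) {
        ped <- randomPedigree(n = 40, nFounders = 12, seed = seed)
        expect_equal(relValues(pedigreeA(ped)), kinshipOracle(ped),
                     tolerance = 1e-12, info = paste("seed", seed))
    }
})

test_that("eigenvalue summaries capture family concentration", {
    expect_equal(eigenSummary(identityRel(10), 1)$cumulativeProportion, 0.1)

    v <- tcrossprod(rnorm(6))
    expect_equal(eigenSummary(relFromValues(v), 1)$cumulativeProportion, 1,
                 tolerance = 1e-10)
    cp <- eigenSummary(relFromValues(v))$cumulativeProportion
    expect_true(all(diff(cp) >= -1e-12))
    expect_equal(cp[length(cp)], 1, tolerance = 1e-10)

    # sib-structured G concentrates more variance in its top eigenvalues
    # than an unrelated population of the same size
    st <- tinyStudy()
    Gfam <- grmVanRaden1(st@genotypes)
    n <- nrow(relValues(Gfam))
    set.seed(8)
    Xu <- matrix(rbinom(n * 240, 2, runif(240, 0.1, 0.5)), n, 240,
                 byrow = TRUE)
    Gun <- grmVanRaden1(makeGeno(Xu))
    top10 <- function(G) eigenSummary(G, 10)$cumulativeProportion[10]
    expect_gt(top10(Gfam), top10(Gun))
})

test_that("degenerate GRM inputs are refused", {
    mono <- makeGeno(matrix(2, 4, 3))
    expect_error(grmVanRaden1(mono), "polymorphic")
    one <- makeGeno(matrix(c(0, 1, 2, 1), 4, 1))
    expect_error(grmLoco(one, "1"), "two chromosomes")
})
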