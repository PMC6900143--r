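## Mixed linear model association: y = 1*mu + x*b + u + e with
## u ~ N(0, K sigmaG2), e ~ N(0, I sigmaE2). REML profiles the variance
## ratio on the eigenbasis of K (one O(n^3) decomposition per kinship,
## O(n) per likelihood evaluation); the per-SNP Wald test is GLS with the
## variance components held fixed at their null-model estimates.

# Eigendecomposition with bending: mildly negative eigenvalues (an expected
# artifact of the Yang diagonal estimator at modest SNP counts) are clipped
# to zero; a grossly indefinite matrix is refused.
.kinshipEigen <- function(K) {
    eg <- eigen(K, symmetric = TRUE)
    if (min(eg$values) < -0.1 * max(abs(eg$values)))
        stop("relationship matrix is negative definite beyond tolerance")
    list(values = pmax(eg$values, 0), vectors = eg$vectors)
}

.alignIds <- function(phenotype, ids) {
    ph <- phenotype[match(ids, phenotype$id), , drop = FALSE]
    if (anyNA(ph$value) || anyNA(ph$id))
        stop("phenotype must cover every analyzed individual")
    ph
}

# Restricted log-likelihood profiled over the ratio lambda = sigmaG2/sigmaE2,
# on the rotated scale: V = sigmaE2 * diag(lambda * d + 1).
.remlObjective <- function(loglam, yt, Wt, d, np) {
    w <- exp(loglam) * d + 1
    Wv <- Wt / w
    A <- crossprod(Wt, Wv)
    by <- crossprod(Wv, yt)
    a <- solve(A, by)
    r <- yt - Wt %*% a
    rss <- sum(r^2 / w)
    s2 <- rss / np
    -0.5 * (np * log(2 * pi * s2) + np + sum(log(w)) +
            determinant(A, logarithm = TRUE)$modulus)
}

# Full REML fit on pre-rotated data. Returns VarianceComponents.
.remlEig <- function(yt, Wt, d, tol = 1e-8) {
    n <- length(yt)
    np <- n - ncol(Wt)
    evals <- 0L
    obj <- function(ll) { evals <<- evals + 1L; .remlObjective(ll, yt, Wt, d, np) }
    lo <- log(1e-8); hi <- log(1e6)
    opt <- optimize(obj, c(lo, hi), maximum = TRUE, tol = tol)
    ll <- opt$maximum
    # boundary check: sigmaG2 -> 0 when the ratio runs to the lower bound
    atZero <- obj(lo)
    boundary <- atZero >= opt$objective - 1e-8 || ll <= lo + 1e-3
    lam <- if (boundary) 0 else exp(ll)
    w <- lam * d + 1
    Wv <- Wt / w
    A <- crossprod(Wt, Wv)
    a <- solve(A, crossprod(Wv, yt))
    rss <- sum((yt - Wt %*% a)^2 / w)
    sigmaE2 <- rss / np
    sigmaG2 <- lam * sigmaE2
    logLik <- if (boundary) atZero else opt$objective
    new("VarianceComponents", sigmaG2 = sigmaG2, sigmaE2 = sigmaE2,
        h2 = sigmaG2 / (sigmaG2 + sigmaE2), logLik = as.numeric(logLik),
        nIter = evals, boundary = boundary)
}

# Build the rotated scan context shared by remlFit / assocScan / permutations.
.scanContext <- function(phenotype, genotypes, rel, fixedSnps = character()) {
    ids <- intersect(sampleIds(genotypes), sampleIds(rel))
    ids <- ids[ids %in% phenotype$id]
    if (length(ids) < 3L) stop("fewer than 3 individuals shared across inputs")
    ph <- .alignIds(phenotype, ids)
    K <- relValues(rel)[ids, ids, drop = FALSE]
    eg <- .kinshipEigen(K)
    d <- eg$values
    U <- eg$vectors
    X <- dosageMatrix(genotypes)[ids, , drop = FALSE]
    info <- snpInfo(genotypes)
    freq <- colMeans(X, na.rm = TRUE) / 2
    if (anyNA(X)) {  # mean-impute for testing, matching GRM handling
        naIdx <- which(is.na(X), arr.ind = TRUE)
        X[naIdx] <- 2 * freq[naIdx[, 2]]
    }
    W <- matrix(1, length(ids), 1)
    if (length(fixedSnps)) {
        miss <- setdiff(fixedSnps, colnames(X))
        if (length(miss)) stop("unknown fixed SNPs: ", paste(miss, collapse = ", "))
        W <- cbind(W, X[, fixedSnps, drop = FALSE])
    }
    list(ids = ids, y = ph$value, U = U, d = d, X = X, info = info,
         freq = freq, W = W, Wt = crossprod(U, W), fixedSnps = fixedSnps)
}

#' REML variance components of the polygenic null model
#'
#' Fits `y = W alpha + u + e` with `u ~ N(0, K sigmaG2)` by restricted
#' maximum likelihood, rotating once onto the eigenbasis of `K` and
#' maximizing the profiled restricted likelihood over the variance ratio
#' `sigmaG2/sigmaE2` (golden-section/parabolic search; ratio bounded in
#' `[1e-8, 1e6]`, with a zero-boundary projection for `sigmaG2`).
#'
#' @param phenotype data.frame with columns `id`, `value`.
#' @param rel a [RelationshipMatrix-class]; individuals are matched by id.
#' @param covariates optional numeric matrix of extra fixed covariates with
#'   rownames = individual ids (an intercept is always included).
#' @return A [VarianceComponents-class].
#' @export
remlFit <- function(phenotype, rel, covariates = NULL) {
    ids <- intersect(sampleIds(rel), phenotype$id)
    if (length(ids) < 3L) stop("fewer than 3 individuals shared across inputs")
    ph <- .alignIds(phenotype, ids)
    K <- relValues(rel)[ids, ids, drop = FALSE]
    eg <- .kinshipEigen(K)
    d <- eg$values
    W <- matrix(1, length(ids), 1)
    if (!is.null(covariates)) {
        covariates <- as.matrix(covariates)
        if (is.null(rownames(covariates))) stop("covariates need rownames (ids)")
        W <- cbind(W, covariates[ids, , drop = FALSE])
    }
    .remlEig(crossprod(eg$vectors, ph$value), crossprod(eg$vectors, W), d)
}

# Vectorized GLS scan given rotated context and variance components.
# Returns the stats data.frame (SNPs in genotype column order).
.scanStats <- function(ctx, sigmaG2, sigmaE2, yt = NULL) {
    v <- sigmaG2 * ctx$d + sigmaE2
    if (is.null(yt)) yt <- crossprod(ctx$U, ctx$y)
    Xt <- ctx$Xt
    if (is.null(Xt)) Xt <- crossprod(ctx$U, ctx$X)
    Wt <- ctx$Wt
    Wv <- Wt / v
    A <- crossprod(Wt, Wv)
    Ainv <- solve(A)
    bWy <- crossprod(Wv, yt)
    Cm <- crossprod(Wv, Xt)                 # p x m
    xVx <- colSums(Xt^2 / v)
    xVy <- as.vector(crossprod(Xt / v, yt))
    AC <- Ainv %*% Cm
    xVxAdj <- xVx - colSums(Cm * AC)
    xVyAdj <- xVy - as.vector(crossprod(Cm, Ainv %*% bWy))
    b <- xVyAdj / xVxAdj
    # per-SNP residual rescaling of the SE: with K = I this reduces exactly
    # to ordinary least squares; with well-estimated components phi ~ 1
    yVyW <- sum(yt^2 / v) - sum(bWy * (Ainv %*% bWy))
    rssSnp <- pmax(yVyW - xVyAdj^2 / xVxAdj, 0)
    phi <- rssSnp / (length(yt) - ncol(Wt) - 1L)
    se <- sqrt(phi / xVxAdj)
    chi2 <- (b / se)^2
    lp <- pchisq(chi2, df = 1, lower.tail = FALSE, log.p = TRUE)
    p <- pmax(exp(lp), .Machine$double.xmin)  # never report exactly 0
    data.frame(b = b, se = se, chi2 = chi2, p = p, neglog10p = -log10(p))
}

#' Single-SNP mixed-model association scan
#'
#' For each SNP, the GLS estimate of the allele-substitution effect under
#' `V = sigmaG2 K + sigmaE2 I` (variance components held fixed, GCTA-MLMA
#' style), after projecting out the mean and any fixed SNP covariates; the
#' Wald statistic `(b/se)^2` is referred to chi-square with 1 df. Fixed
#' SNPs are excluded from testing; monomorphic SNPs are dropped with a
#' message. p-values are floored at the smallest positive double.
#'
#' @param phenotype data.frame (`id`, `value`).
#' @param genotypes a [SnpGeno-class].
#' @param rel the [RelationshipMatrix-class] the variance components were
#'   estimated under.
#' @param vc a [VarianceComponents-class] from [remlFit()].
#' @param fixedSnps character SNP ids fitted as fixed covariates.
#' @param snps optional subset of SNP ids to test (default: all).
#' @return An [AssocTable-class].
#' @export
assocScan <- function(phenotype, genotypes, rel, vc, fixedSnps = character(),
                      snps = NULL) {
    ctx <- .scanContext(phenotype, genotypes, rel, fixedSnps)
    test <- if (is.null(snps)) colnames(ctx$X) else as.character(snps)
    test <- setdiff(test, fixedSnps)
    mono <- names(ctx$freq)[ctx$freq <= 0 | ctx$freq >= 1]
    if (length(intersect(test, mono)))
        message(length(intersect(test, mono)), " monomorphic SNPs dropped")
    test <- setdiff(test, mono)
    if (!length(test)) stop("no testable SNPs")
    keep <- match(test, colnames(ctx$X))
    ctx$X <- ctx$X[, keep, drop = FALSE]
    ctx$freq <- ctx$freq[keep]
    st <- .scanStats(ctx, vc@sigmaG2, vc@sigmaE2)
    ii <- match(test, ctx$info$snp)
    tb <- data.frame(chr = ctx$info$chrom[ii], snp = test, bp = ctx$info$bp[ii],
                     freq = as.numeric(ctx$freq), st,
                     stringsAsFactors = FALSE)
    .AssocTable(tb, method = relMethod(rel),
                vc = list(genome = vc), fixedSnps = fixedSnps)
}

#' Fit-and-scan under one relationship matrix
#'
#' Convenience wrapper: [remlFit()] of the null model followed by
#' [assocScan()] of all SNPs under the same kinship.
#'
#' @inheritParams assocScan
#' @return An [AssocTable-class].
#' @export
gwasScan <- function(phenotype, genotypes, rel, fixedSnps = character()) {
    ctx <- .scanContext(phenotype, genotypes, rel, fixedSnps)
    vc <- .remlEig(crossprod(ctx$U, ctx$y), ctx$Wt, ctx$d)
    assocScan(phenotype, genotypes, rel, vc, fixedSnps)
}

#' Leave-one-chromosome-out mixed-model GWAS
#'
#' For each chromosome `c`: build the kinship from all other chromosomes,
#' re-estimate the variance components under it, and scan the SNPs of `c`
#' with those components. Results are concatenated; the per-chromosome
#' variance components are kept in the table's metadata.
#'
#' @inheritParams assocScan
#' @param method GRM scaling for the LOCO kinships, `"yang"` (default) or
#'   `"vanraden1"`.
#' @param mafMin MAF filter for GRM construction.
#' @return An [AssocTable-class] with method tag `"G_<method>_loco"`.
#' @export
gwasLoco <- function(phenotype, genotypes, method = c("yang", "vanraden1"),
                     fixedSnps = character(), mafMin = 0.01) {
    method <- match.arg(method)
    chroms <- chromosomes(genotypes)
    if (length(chroms) < 2L) stop("LOCO requires at least two chromosomes")
    info <- snpInfo(genotypes)
    pieces <- vector("list", length(chroms))
    vcs <- vector("list", length(chroms))
    for (k in seq_along(chroms)) {
        cc <- chroms[k]
        rel <- grmLoco(genotypes, cc, method = method, mafMin = mafMin)
        vc <- remlFit(phenotype, rel)
        at <- assocScan(phenotype, genotypes, rel, vc,
                        fixedSnps = fixedSnps,
                        snps = info$snp[info$chrom == cc])
        pieces[[k]] <- assocResults(at)
        vcs[[k]] <- vc
    }
    names(vcs) <- chroms
    .AssocTable(do.call(rbind, pieces),
                method = paste0("G_", method, "_loco"), vc = vcs,
                fixedSnps = fixedSnps)
}
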