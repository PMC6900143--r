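## The four significance-threshold procedures: Bonferroni (total SNPs or
## effective segment number Me), phenotype-permutation thresholds, and
## Benjamini-Hochberg / Benjamini-Yekutieli step-up FDR.

.sigSet <- function(assoc, thresholdNeglog10p) {
    if (is.null(assoc)) return(character())
    tb <- assocResults(assoc)
    tb$snp[tb$neglog10p >= thresholdNeglog10p]
}

#' Bonferroni significance threshold
#'
#' p-cutoff `alpha / nTests`, reported as `-log10(alpha / nTests)`.
#' `nTests` may be a real number, so the effective number of independent
#' chromosome segments (Me) can stand in for the SNP count.
#'
#' @param alpha family-wise error level in (0, 1).
#' @param nTests number of (effective) independent tests, > 0.
#' @param assoc optional [AssocTable-class]; when given, the SNPs at or
#'   above the threshold are recorded as significant.
#' @param procedure `"bonferroni_total"` (default) or `"bonferroni_me"`,
#'   a labelling choice only.
#' @return A [ThresholdSet-class].
#' @examples
#' thresholdNeglog10p(bonferroniThreshold(0.05, 34588)) # 5.84
#' @export
bonferroniThreshold <- function(alpha, nTests, assoc = NULL,
                                procedure = c("bonferroni_total", "bonferroni_me")) {
    procedure <- match.arg(procedure)
    if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
    if (nTests <= 0) stop("nTests must be > 0")
    thr <- -log10(alpha / nTests)
    new("ThresholdSet", procedure = procedure, alpha = alpha,
        nTests = as.numeric(nTests), thresholdNeglog10p = thr,
        significantSnps = .sigSet(assoc, thr))
}

#' Effective number of independent chromosome segments (Me)
#'
#' `Me = 1 / Var(G_ij)` over the strictly off-diagonal entries of a
#' whole-genome VanRaden-method-1 relationship matrix; equivalently the
#' inverse of the average genome-wide LD. The population (denominator-n)
#' variance is used by default.
#'
#' @param grm a [RelationshipMatrix-class]; intended for method
#'   `"G_vanraden1"` built from all chromosomes (a different method raises
#'   a warning).
#' @param denom `"n"` (default) or `"n-1"` variance denominator.
#' @return Me as a real number.
#' @export
meFromGrm <- function(grm, denom = c("n", "n-1")) {
    denom <- match.arg(denom)
    if (relMethod(grm) != "G_vanraden1")
        warning("Me is defined on a whole-genome VanRaden-1 GRM; got '",
                relMethod(grm), "'")
    v <- relValues(grm)
    if (nrow(v) < 3L) stop("need at least 3 individuals")
    off <- v[upper.tri(v)]
    s2 <- if (denom == "n") mean((off - mean(off))^2) else var(off)
    if (s2 <= 0) stop("off-diagonal variance is zero; Me undefined")
    1 / s2
}

#' Benjamini-Hochberg step-up FDR threshold
#'
#' p-values are ordered ascending; `k = max{i : p(i) <= i * alpha / m}`
#' (0 if none). The p-value at rank `k` is the threshold and the `k`
#' lowest-p SNPs are significant. With `k = 0` nothing is significant and
#' the threshold is reported as `+Inf` on the -log10 scale. Ties are broken
#' stably by (p, id) so the significant set is deterministic.
#'
#' @param pvalues numeric p-values in (0, 1].
#' @param alpha FDR level (default 0.05).
#' @param ids optional names for the p-values (default `p1..pm`).
#' @return A [ThresholdSet-class] with procedure `"fdr_bh"`.
#' @export
fdrBH <- function(pvalues, alpha = 0.05, ids = NULL) {
    .fdrStepUp(pvalues, alpha, ids, by = FALSE)
}

#' Benjamini-Yekutieli step-up FDR threshold
#'
#' As [fdrBH()] but with the per-rank bound `i * alpha / (m * c(m))`,
#' `c(m) = sum_{i=1}^m 1/i`, valid under arbitrary dependence; the BY
#' significant set is always a subset of the BH one.
#'
#' @inheritParams fdrBH
#' @return A [ThresholdSet-class] with procedure `"fdr_by"`.
#' @export
fdrBY <- function(pvalues, alpha = 0.05, ids = NULL) {
    .fdrStepUp(pvalues, alpha, ids, by = TRUE)
}

.fdrStepUp <- function(pvalues, alpha, ids, by) {
    if (!length(pvalues)) stop("empty p-value list")
    if (any(pvalues <= 0 | pvalues > 1)) stop("p-values must lie in (0, 1]")
    if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
    m <- length(pvalues)
    if (is.null(ids)) ids <- if (!is.null(names(pvalues))) names(pvalues)
                             else paste0("p", seq_len(m))
    o <- order(pvalues, ids)
    ps <- pvalues[o]
    cm <- if (by) sum(1 / seq_len(m)) else 1
    bound <- seq_len(m) * alpha / (m * cm)
    k <- max(c(0L, which(ps <= bound)))
    thr <- if (k == 0L) Inf else -log10(ps[k])
    sig <- if (k == 0L) character() else as.character(ids[o][seq_len(k)])
    new("ThresholdSet", procedure = if (by) "fdr_by" else "fdr_bh",
        alpha = alpha, nTests = as.numeric(m), thresholdNeglog10p = thr,
        significantSnps = sig)
}

#' Phenotype-permutation significance threshold
#'
#' The empirical critical value of the scan: phenotype values are randomly
#' shuffled over individuals, the full single-SNP mixed-model scan is
#' re-run, and the maximum -log10(p) and the replicate's genome-wide
#' inflation factor are recorded. The threshold is the nearest-rank
#' `percentile` (default 95th) of the ordered maxima. Because shuffling
#' changes the phenotype-kinship covariance, variance components are
#' re-estimated for every replicate by default (`refitReml = FALSE`
#' freezes them at the observed-data fit for speed).
#'
#' @param phenotype data.frame (`id`, `value`).
#' @param genotypes a [SnpGeno-class].
#' @param rel a [RelationshipMatrix-class]; when `NULL`, a whole-genome
#'   Yang GRM is built (`protocol = "full"`). With `protocol = "loco"`
#'   each replicate runs the full leave-one-chromosome-out scan.
#' @param nPermutations number of replicates (>= 1).
#' @param percentile percentile of the ordered maxima, in (0, 100).
#' @param seed seed for the shuffle stream.
#' @param protocol `"full"` (one kinship) or `"loco"`.
#' @param refitReml re-estimate variance components per replicate (default
#'   TRUE).
#' @param method GRM scaling when a kinship has to be built.
#' @param mafMin MAF filter for GRM construction.
#' @return A [PermutationResult-class].
#' @export
permutationThreshold <- function(phenotype, genotypes, rel = NULL,
                                 nPermutations = 100L, percentile = 95,
                                 seed = 1L, protocol = c("full", "loco"),
                                 refitReml = TRUE,
                                 method = c("yang", "vanraden1"),
                                 mafMin = 0.01) {
    protocol <- match.arg(protocol)
    method <- match.arg(method)
    if (nPermutations < 1L) stop("need at least one permutation")
    if (percentile <= 0 || percentile >= 100) stop("percentile must lie in (0, 100)")
    if (ncol(dosageMatrix(genotypes)) < 1L) stop("no SNPs to scan")

    # Pre-rotate everything that does not depend on the phenotype order:
    # one context per kinship (a single one, or one per LOCO chromosome).
    makeCtx <- function(relC, snps) {
        ctx <- .scanContext(phenotype, genotypes, relC)
        keep <- intersect(snps, colnames(ctx$X))
        keep <- keep[ctx$freq[keep] > 0 & ctx$freq[keep] < 1]
        ctx$X <- ctx$X[, keep, drop = FALSE]
        ctx$freq <- ctx$freq[keep]
        ctx$Xt <- crossprod(ctx$U, ctx$X)
        ctx
    }
    info <- snpInfo(genotypes)
    if (protocol == "full") {
        if (is.null(rel)) rel <- if (method == "yang") grmYang(genotypes, mafMin = mafMin)
                                 else grmVanRaden1(genotypes, mafMin = mafMin)
        ctxs <- list(makeCtx(rel, info$snp))
    } else {
        chroms <- chromosomes(genotypes)
        if (length(chroms) < 2L) stop("LOCO requires at least two chromosomes")
        ctxs <- lapply(chroms, function(cc)
            makeCtx(grmLoco(genotypes, cc, method = method, mafMin = mafMin),
                    info$snp[info$chrom == cc]))
    }
    vc0 <- lapply(ctxs, function(ctx)
        .remlEig(crossprod(ctx$U, ctx$y), ctx$Wt, ctx$d))

    n <- length(ctxs[[1]]$y)
    maxima <- numeric(nPermutations)
    lambdas <- numeric(nPermutations)
    set.seed(seed)
    for (r in seq_len(nPermutations)) {
        perm <- sample.int(n)
        chi2 <- numeric(0); nl10 <- numeric(0)
        for (ci in seq_along(ctxs)) {
            ctx <- ctxs[[ci]]
            yt <- crossprod(ctx$U, ctx$y[perm])
            vc <- if (refitReml) .remlEig(yt, ctx$Wt, ctx$d) else vc0[[ci]]
            st <- .scanStats(ctx, vc@sigmaG2, vc@sigmaE2, yt = yt)
            chi2 <- c(chi2, st$chi2)
            nl10 <- c(nl10, st$neglog10p)
        }
        maxima[r] <- max(nl10)
        lambdas[r] <- median(chi2) / .chisq1Median()
    }
    ord <- sort(maxima)
    thr <- ord[ceiling(percentile / 100 * nPermutations)]
    new("PermutationResult", nPermutations = as.integer(nPermutations),
        maxNeglog10p = maxima, lambda = lambdas,
        percentile = as.numeric(percentile), threshold = thr,
        seed = as.integer(seed))
}
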