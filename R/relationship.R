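## Relationship matrices: pedigree A (tabular method), genomic G (VanRaden
## method 1 and Yang et al. scalings), leave-one-chromosome-out variants,
## and eigenvalue summaries.

# Shared prep: subset SNPs, estimate allele frequencies from the analyzed
# sample, mean-impute missing dosages, drop monomorphic / low-MAF SNPs.
.grmPrep <- function(genotypes, snps = NULL, mafMin = 0.01) {
    X <- dosageMatrix(genotypes)
    if (!is.null(snps)) {
        if (is.character(snps)) snps <- match(snps, colnames(X))
        if (anyNA(snps)) stop("unknown SNP ids in subset")
        X <- X[, snps, drop = FALSE]
    }
    p <- colMeans(X, na.rm = TRUE) / 2
    keep <- which(!is.na(p) & pmin(p, 1 - p) >= mafMin & p > 0 & p < 1)
    if (!length(keep))
        stop("no polymorphic SNPs left after MAF filtering")
    X <- X[, keep, drop = FALSE]
    p <- p[keep]
    # mean imputation keeps the centering exact
    if (anyNA(X)) {
        naIdx <- which(is.na(X), arr.ind = TRUE)
        X[naIdx] <- 2 * p[naIdx[, 2]]
    }
    list(X = X, p = p)
}

#' Genomic relationship matrix, VanRaden method 1
#'
#' `G = Z Z' / (2 sum_j p_j (1 - p_j))` with `Z_ij = x_ij - 2 p_j` and
#' allele frequencies estimated from the analyzed individuals. Missing
#' dosages are mean-imputed; monomorphic and low-MAF SNPs are excluded.
#' For a population in Hardy-Weinberg equilibrium the mean diagonal is ~1.
#'
#' @param genotypes a [SnpGeno-class].
#' @param snps optional SNP subset (ids or column indices).
#' @param mafMin minimum minor-allele frequency (default 0.01).
#' @return A [RelationshipMatrix-class] with method `"G_vanraden1"`.
#' @export
grmVanRaden1 <- function(genotypes, snps = NULL, mafMin = 0.01) {
    pr <- .grmPrep(genotypes, snps, mafMin)
    Z <- sweep(pr$X, 2, 2 * pr$p)
    denom <- 2 * sum(pr$p * (1 - pr$p))
    G <- tcrossprod(Z) / denom
    .RelationshipMatrix(G, "G_vanraden1", nSnpsUsed = ncol(Z))
}

#' Genomic relationship matrix, Yang et al. scaling
#'
#' Per-SNP standardization: off-diagonals
#' `G_ik = (1/m) sum_j (x_ij - 2p_j)(x_kj - 2p_j) / (2 p_j (1 - p_j))`;
#' diagonals use the within-individual estimator
#' `G_ii = 1 + (1/m) sum_j (x_ij^2 - (1 + 2p_j) x_ij + 2 p_j^2) /
#' (2 p_j (1 - p_j))`. This is the kinship used as the polygenic covariance
#' of the association model.
#'
#' @inheritParams grmVanRaden1
#' @return A [RelationshipMatrix-class] with method `"G_yang"`.
#' @export
grmYang <- function(genotypes, snps = NULL, mafMin = 0.01) {
    pr <- .grmPrep(genotypes, snps, mafMin)
    X <- pr$X; p <- pr$p
    m <- ncol(X)
    w <- 2 * p * (1 - p)
    Zs <- sweep(sweep(X, 2, 2 * p), 2, sqrt(w), "/")
    G <- tcrossprod(Zs) / m
    diag(G) <- 1 + colMeans((t(X)^2 - (1 + 2 * p) * t(X) + 2 * p^2) / w)
    .RelationshipMatrix(G, "G_yang", nSnpsUsed = m)
}

#' Leave-one-chromosome-out genomic relationship matrix
#'
#' Builds a GRM from all SNPs except those mapped to chromosome `chrom`
#' (the chromosome whose SNPs are being tested), so the tested SNP never
#' contributes to the polygenic covariance.
#'
#' @inheritParams grmVanRaden1
#' @param chrom chromosome label to leave out.
#' @param method `"yang"` (default, the association-model kinship) or
#'   `"vanraden1"`.
#' @return A [RelationshipMatrix-class] with a `_loco` method tag and the
#'   left-out chromosome recorded.
#' @export
grmLoco <- function(genotypes, chrom, method = c("yang", "vanraden1"),
                    mafMin = 0.01) {
    method <- match.arg(method)
    info <- snpInfo(genotypes)
    if (length(unique(info$chrom)) < 2L)
        stop("LOCO requires at least two chromosomes")
    keep <- which(info$chrom != as.character(chrom))
    g <- if (method == "yang") grmYang(genotypes, keep, mafMin)
         else grmVanRaden1(genotypes, keep, mafMin)
    new("RelationshipMatrix", values = g@values,
        method = paste0(g@method, "_loco"), nSnpsUsed = g@nSnpsUsed,
        excluded = as.character(chrom))
}

#' Pedigree additive relationship matrix (tabular method)
#'
#' `a_ii = 1 + 0.5 a_sd` (0 if a parent is unknown) and
#' `a_ij = 0.5 (a_js + a_jd)` for `j` earlier than `i`, walking the
#' pedigree parents-first.
#'
#' @param pedigree data.frame with columns `id`, `sire`, `dam` (NA or "0" =
#'   unknown), topologically ordered.
#' @return A [RelationshipMatrix-class] with method `"A"`.
#' @export
pedigreeA <- function(pedigree) {
    id <- as.character(pedigree$id)
    if (anyDuplicated(id)) stop("duplicate ids in pedigree")
    clean <- function(x) {
        x <- as.character(x)
        x[x %in% c("0", "")] <- NA_character_
        x
    }
    sire <- clean(pedigree$sire); dam <- clean(pedigree$dam)
    n <- length(id)
    pos <- setNames(seq_len(n), id)
    si <- ifelse(is.na(sire), 0L, pos[sire])
    di <- ifelse(is.na(dam), 0L, pos[dam])
    if (anyNA(si) || anyNA(di)) stop("parent not found in pedigree")
    if (any(si >= seq_len(n) & si > 0L) || any(di >= seq_len(n) & di > 0L))
        stop("pedigree must list parents before offspring (no cycles)")
    A <- matrix(0, n, n, dimnames = list(id, id))
    for (i in seq_len(n)) {
        s <- si[i]; d <- di[i]
        A[i, i] <- 1 + if (s > 0L && d > 0L) 0.5 * A[s, d] else 0
        if (i > 1L) {
            j <- seq_len(i - 1L)
            aj <- 0.5 * ((if (s > 0L) A[j, s] else rep(0, i - 1L)) +
                         (if (d > 0L) A[j, d] else rep(0, i - 1L)))
            A[i, j] <- aj
            A[j, i] <- aj
        }
    }
    .RelationshipMatrix(A, "A")
}

#' Subset a relationship matrix to a set of individuals
#'
#' @param rel a [RelationshipMatrix-class].
#' @param ids individual ids to keep, in the requested order.
#' @return A [RelationshipMatrix-class] over `ids`.
#' @export
subsetRelationship <- function(rel, ids) {
    ids <- as.character(ids)
    if (!all(ids %in% rownames(rel@values))) stop("unknown individual ids")
    new("RelationshipMatrix", values = rel@values[ids, ids, drop = FALSE],
        method = rel@method, nSnpsUsed = rel@nSnpsUsed,
        excluded = rel@excluded)
}

#' Cumulative eigenvalue proportions of a relationship matrix
#'
#' Descending eigenvalues (tiny negatives from numerical noise clipped to
#' zero) and the cumulative proportion of variance the first `k` explain.
#' In a family-structured population a few eigenvalues carry a large share
#' of the variance, the spectral footprint of strong sib structure.
#'
#' @param rel a [RelationshipMatrix-class].
#' @param k number of leading eigenvalues to report (default all).
#' @return list with `values` (all eigenvalues, descending) and
#'   `cumulativeProportion` (length `k`, non-decreasing, reaching 1 at
#'   `k = n`).
#' @export
eigenSummary <- function(rel, k = nrow(relValues(rel))) {
    v <- relValues(rel)
    ev <- eigen(v, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-6 * max(abs(ev)))
        warning("matrix is noticeably non-PSD; negative eigenvalues clipped")
    ev <- pmax(ev, 0)
    cp <- cumsum(ev) / sum(ev)
    list(values = ev, cumulativeProportion = cp[seq_len(min(k, length(cp)))])
}
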