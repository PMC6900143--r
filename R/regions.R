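## Post-GWAS summaries: significant-SNP counts, QTL-region clustering and
## LD-decay curves.

#' Count SNPs at or above a significance threshold
#'
#' @param assoc an [AssocTable-class].
#' @param threshold -log10(p) cutoff; SNPs with `neglog10p >= threshold`
#'   are counted.
#' @return integer count.
#' @export
countSignificant <- function(assoc, threshold) {
    sum(assocResults(assoc)$neglog10p >= threshold)
}

#' Cluster significant SNPs into QTL regions
#'
#' Greedy peak picking: the most significant remaining SNP above the
#' threshold becomes a peak; every significant SNP within `radius` bp of
#' it on the same chromosome joins its region and is removed; repeat until
#' no significant SNP remains. Regions do not merge transitively - a
#' significant SNP farther than `radius` from every existing peak starts
#' its own region. Ties in significance are broken by lower bp. Region
#' bounds are the nominal `peak +/- radius` span.
#'
#' @param assoc an [AssocTable-class].
#' @param threshold -log10(p) significance cutoff.
#' @param radius half-width of a region in bp (default 0.5 Mb).
#' @return data.frame with one row per region (chrom, peakSnp, peakBp,
#'   peakNeglog10p, startBp, endBp, nSnps), sorted by (chromosome, start);
#'   zero rows when nothing is significant.
#' @export
clusterRegions <- function(assoc, threshold, radius = 5e5) {
    tb <- assocResults(assoc)
    sig <- tb[tb$neglog10p >= threshold, c("chr", "snp", "bp", "neglog10p")]
    out <- list()
    while (nrow(sig)) {
        i <- order(-sig$neglog10p, sig$bp)[1]
        peak <- sig[i, ]
        inReg <- sig$chr == peak$chr & abs(sig$bp - peak$bp) <= radius
        out[[length(out) + 1L]] <- data.frame(
            chrom = peak$chr, peakSnp = peak$snp, peakBp = peak$bp,
            peakNeglog10p = peak$neglog10p,
            startBp = peak$bp - radius, endBp = peak$bp + radius,
            nSnps = sum(inReg), stringsAsFactors = FALSE)
        sig <- sig[!inReg, , drop = FALSE]
    }
    if (!length(out))
        return(data.frame(chrom = character(), peakSnp = character(),
                          peakBp = integer(), peakNeglog10p = numeric(),
                          startBp = numeric(), endBp = numeric(),
                          nSnps = integer(), stringsAsFactors = FALSE))
    res <- do.call(rbind, out)
    res <- res[order(match(res$chrom, unique(assocResults(assoc)$chr)),
                     res$startBp), ]
    rownames(res) <- NULL
    res
}

#' LD decay on a chromosome
#'
#' Squared Pearson correlation (r2) of dosages for every SNP pair within
#' `maxDist` bp, averaged in contiguous distance bins of `binWidth` bp
#' starting at 0. Pairs involving a monomorphic SNP have no defined
#' correlation and are skipped (a message reports how many).
#'
#' @param genotypes a [SnpGeno-class].
#' @param chrom chromosome label.
#' @param maxDist largest pair distance considered (default 2.5 Mb).
#' @param binWidth bin width in bp (default 50 kb).
#' @return data.frame (chrom, binStart, binEnd, meanR2, nPairs); bins with
#'   no pairs have `meanR2 = NA`.
#' @export
ldDecay <- function(genotypes, chrom, maxDist = 2.5e6, binWidth = 5e4) {
    info <- snpInfo(genotypes)
    sel <- info$chrom == as.character(chrom)
    if (sum(sel) < 2L) stop("need at least 2 SNPs on the chromosome")
    X <- dosageMatrix(genotypes)[, sel, drop = FALSE]
    bp <- info$bp[sel]
    mono <- apply(X, 2, function(x) var(x, na.rm = TRUE) == 0)
    nMonoPairs <- 0L
    if (any(mono)) {
        m <- ncol(X)
        nMonoPairs <- m * (m - 1) / 2 -
            (sum(!mono) * (sum(!mono) - 1) / 2)
        message(nMonoPairs, " pairs with a monomorphic SNP skipped")
        X <- X[, !mono, drop = FALSE]
        bp <- bp[!mono]
    }
    r2 <- cor(X, use = "pairwise.complete.obs")^2
    dist <- abs(outer(bp, bp, "-"))
    ut <- upper.tri(r2)
    keep <- ut & dist <= maxDist
    d <- dist[keep]; r <- r2[keep]
    bins <- floor(d / binWidth)
    nBins <- ceiling(maxDist / binWidth)
    res <- data.frame(chrom = as.character(chrom),
                      binStart = (seq_len(nBins) - 1) * binWidth,
                      binEnd = seq_len(nBins) * binWidth,
                      meanR2 = NA_real_, nPairs = 0L,
                      stringsAsFactors = FALSE)
    agg <- tapply(r, bins, mean)
    cnt <- tapply(r, bins, length)
    idx <- as.integer(names(agg)) + 1L
    ok <- idx <= nBins
    res$meanR2[idx[ok]] <- as.numeric(agg)[ok]
    res$nPairs[idx[ok]] <- as.integer(cnt)[ok]
    res
}
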