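## Genomic control: inflation factors (genome-wide and per chromosome) and
## deflation of association statistics.

# Median of the chi-square(1) distribution, found numerically on the CDF
# rather than hard-coding 0.455. Computed once per session.
.chisq1MedianCache <- new.env(parent = emptyenv())
.chisq1Median <- function() {
    if (is.null(.chisq1MedianCache$m))
        .chisq1MedianCache$m <- uniroot(function(x) pchisq(x, df = 1) - 0.5,
                                        interval = c(1e-6, 5),
                                        tol = 1e-12)$root
    .chisq1MedianCache$m
}

#' Convert a p-value to its 1-df chi-square statistic
#'
#' Inverse upper tail of the chi-square distribution with 1 degree of
#' freedom, the statistic scale on which genomic inflation is measured.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return chi-square values (p = 1 maps to 0).
#' @examples
#' pToChi2(0.5)        # the chi-square(1) median, ~0.4549
#' pToChi2(0.3173105)  # ~1
#' @export
pToChi2 <- function(p) {
    if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
    qchisq(p, df = 1, lower.tail = FALSE)
}

#' Genomic inflation factor of a p-value vector
#'
#' `lambda = median(observed chi-square) / median(chi-square(1))`, with the
#' observed statistics obtained from the p-values via [pToChi2()].
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return the inflation factor (scalar).
#' @export
lambdaFromP <- function(p) {
    median(pToChi2(p)) / .chisq1Median()
}

#' Genomic inflation factors of an association table
#'
#' Genome-wide and per-chromosome inflation factors computed from the
#' chi-square statistics carried in the table (not from round-tripped
#' p-values). Raw, unfloored lambdas are reported; deflation (if any) is a
#' separate step, [applyGenomicControl()].
#'
#' @param assoc an [AssocTable-class].
#' @return An [InflationReport-class].
#' @export
inflationFactor <- function(assoc) {
    tb <- assocResults(assoc)
    if (!nrow(tb)) stop("empty association table")
    em <- .chisq1Median()
    chroms <- unique(tb$chr)
    byc <- vapply(chroms, function(cc) median(tb$chi2[tb$chr == cc]) / em, 0)
    nby <- vapply(chroms, function(cc) sum(tb$chr == cc), 0L)
    names(byc) <- names(nby) <- chroms
    new("InflationReport", lambdaGenome = median(tb$chi2) / em,
        lambdaByChrom = byc, nSnpsGenome = nrow(tb), nSnpsByChrom = nby,
        expectedMedian = em)
}

#' Apply genomic control to an association table
#'
#' Divides each SNP's chi-square by the inflation factor of its stratum
#' (whole genome or its chromosome), recomputes p and -log10(p), and keeps
#' the uncontrolled statistics in `chi2_raw` / `p_raw` / `neglog10p_raw`.
#' Lambdas below 1 are floored at 1 for the adjustment (deflation only;
#' significance is never inflated). A table that has already been
#' controlled is refused.
#'
#' @param assoc an [AssocTable-class] with `gcMode == "none"`.
#' @param mode `"genome"` or `"per_chromosome"` stratum for lambda.
#' @return An [AssocTable-class] with adjusted statistics.
#' @export
applyGenomicControl <- function(assoc, mode = c("genome", "per_chromosome")) {
    mode <- match.arg(mode)
    if (assoc@gcMode != "none")
        stop("genomic control was already applied (mode '", assoc@gcMode,
             "'); refusing to control twice")
    tb <- assocResults(assoc)
    ir <- inflationFactor(assoc)
    lam <- if (mode == "genome") rep(max(1, ir@lambdaGenome), nrow(tb))
           else pmax(1, ir@lambdaByChrom[tb$chr])
    tb$chi2_raw <- tb$chi2
    tb$p_raw <- tb$p
    tb$neglog10p_raw <- tb$neglog10p
    tb$chi2 <- tb$chi2 / lam
    lp <- pchisq(tb$chi2, df = 1, lower.tail = FALSE, log.p = TRUE)
    tb$p <- pmax(exp(lp), .Machine$double.xmin)
    tb$neglog10p <- -log10(tb$p)
    new("AssocTable", table = tb, method = assoc@method, vc = assoc@vc,
        fixedSnps = assoc@fixedSnps,
        gcMode = if (mode == "genome") "genome" else "per_chromosome")
}
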