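# Shared fixtures and independent oracles, all built in code.

# identity relationship over n individuals
identityRel <- function(n, ids = sprintf("i%03d", seq_len(n))) {
    v <- diag(n)
    dimnames(v) <- list(ids, ids)
    new("RelationshipMatrix", values = v, method = "A", nSnpsUsed = 0L,
        excluded = character())
}

relFromValues <- function(v, method = "G_vanraden1", nSnps = 1L) {
    if (is.null(rownames(v))) {
        ids <- sprintf("i%03d", seq_len(nrow(v)))
        dimnames(v) <- list(ids, ids)
    }
    new("RelationshipMatrix", values = v, method = method,
        nSnpsUsed = as.integer(nSnps), excluded = character())
}

makeGeno <- function(X, chrom = rep("1", ncol(X)),
                     bp = seq_len(ncol(X)) * 1000L,
                     snpId = paste0("s", seq_len(ncol(X)))) {
    colnames(X) <- snpId
    SnpGeno(X, chrom = chrom, bp = bp, snpId = snpId)
}

# association table with prescribed p-values (chi2 derived consistently)
makeAssoc <- function(p, chr = rep("1", length(p)),
                      bp = seq_along(p) * 1000L,
                      snp = paste0("s", seq_along(p)), method = "test") {
    chi2 <- qchisq(p, df = 1, lower.tail = FALSE)
    tb <- data.frame(chr = chr, snp = snp, bp = bp,
                     freq = rep(0.5, length(p)), b = sqrt(chi2), se = 1,
                     chi2 = chi2, p = p, neglog10p = -log10(p),
                     stringsAsFactors = FALSE)
    new("AssocTable", table = tb[order(match(chr, unique(chr)), bp), ],
        method = method, vc = list(), fixedSnps = character(),
        gcMode = "none")
}

# recursive kinship oracle: phi(i, j) with phi(i, i) = 0.5 (1 + phi(s, d));
# A = 2 * phi. Independent of the tabular method.
kinshipOracle <- function(ped) {
    id <- as.character(ped$id)
    sire <- as.character(ped$sire); dam <- as.character(ped$dam)
    names(sire) <- names(dam) <- id
    memo <- new.env(parent = emptyenv())
    phi <- function(a, b) {
        if (is.na(a) || is.na(b)) return(0)
        key <- paste(sort(c(a, b)), collapse = "|")
        if (!is.null(memo[[key]])) return(memo[[key]])
        ia <- match(a, id); ib <- match(b, id)
        val <- if (a == b) {
            0.5 * (1 + phi(sire[[a]], dam[[a]]))
        } else if (ia > ib) {
            0.5 * (phi(sire[[a]], b) + phi(dam[[a]], b))
        } else {
            0.5 * (phi(sire[[b]], a) + phi(dam[[b]], a))
        }
        memo[[key]] <- val
        val
    }
    n <- length(id)
    A <- matrix(0, n, n, dimnames = list(id, id))
    for (i in seq_len(n)) for (j in seq_len(i))
        A[i, j] <- A[j, i] <- 2 * phi(id[i], id[j])
    A
}

# random valid pedigree: founders first, then offspring with both parents
# drawn from strictly earlier individuals
randomPedigree <- function(n, nFounders, seed) {
    set.seed(seed)
    id <- sprintf("p%02d", seq_len(n))
    sire <- dam <- rep(NA_character_, n)
    for (i in (nFounders + 1):n) {
        pr <- sample(i - 1L, 2L, replace = FALSE)
        sire[i] <- id[pr[1]]; dam[i] <- id[pr[2]]
    }
    data.frame(id = id, sire = sire, dam = dam, stringsAsFactors = FALSE)
}

# exhaustive step-up oracle: scan every rank explicitly
bruteForceFdr <- function(p, alpha, by = FALSE) {
    m <- length(p)
    ids <- paste0("p", seq_len(m))
    o <- order(p, ids)
    ps <- p[o]
    cm <- if (by) sum(1 / seq_len(m)) else 1
    k <- 0L
    for (i in seq_len(m))
        if (ps[i] <= i * alpha / (m * cm)) k <- i
    list(k = k,
         threshold = if (k == 0L) Inf else -log10(ps[k]),
         sig = if (k == 0L) character() else ids[o][seq_len(k)])
}

# brute-force greedy interval cover over a plain data frame
bruteForceRegions <- function(tb, threshold, radius = 5e5) {
    sig <- tb[tb$neglog10p >= threshold, , drop = FALSE]
    peaks <- list()
    assigned <- rep(FALSE, nrow(sig))
    while (!all(assigned)) {
        cand <- which(!assigned)
        best <- cand[1]
        for (i in cand)
            if (sig$neglog10p[i] > sig$neglog10p[best] ||
                (sig$neglog10p[i] == sig$neglog10p[best] &&
                 sig$bp[i] < sig$bp[best])) best <- i
        member <- !assigned & sig$chr == sig$chr[best] &
            abs(sig$bp - sig$bp[best]) <= radius
        peaks[[length(peaks) + 1L]] <- list(peak = sig$snp[best],
                                            n = sum(member))
        assigned <- assigned | member
    }
    peaks
}

# small simulated study cached across tests in one run
tinyStudy <- local({
    cache <- NULL
    function() {
        if (is.null(cache))
            cache <<- simulateStudy(populationDesign(
                nSires = 8L, damsPerSire = 5L, litterSize = 3,
                nChromosomes = 3L, snpsPerChromosome = 80L, seed = 5L))
        cache
    }
})
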