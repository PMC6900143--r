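## Readers and writers: VCF / dosage-TSV genotypes, SNP map, phenotype and
## pedigree TSV, association tables (GCTA-mlma-like layout), GRM triplets.

#' Read genotypes from VCF or a dosage TSV
#'
#' VCF: diploid GT fields become alt-allele dosages 0/1/2 (`./.` becomes
#' missing); multi-allelic and non-SNP records are skipped with a message.
#' Dosage TSV: individuals in rows (first column = id), SNPs in columns
#' (header = SNP ids), with a companion SNP map (`mapPath`) giving
#' chromosome and bp per SNP.
#'
#' @param path genotype file.
#' @param format `"vcf"` or `"dosage"`; `"auto"` decides by extension.
#' @param mapPath SNP map TSV (columns chrom, snp, bp), required for
#'   dosage input.
#' @return A [SnpGeno-class].
#' @export
readGenotypes <- function(path, format = c("auto", "vcf", "dosage"),
                          mapPath = NULL) {
    format <- match.arg(format)
    if (format == "auto")
        format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "dosage"
    if (format == "vcf") .readVcfGeno(path) else .readDosageGeno(path, mapPath)
}

.readVcfGeno <- function(path) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    isSnp <- nchar(fix[, "REF"]) == 1L & nchar(fix[, "ALT"]) == 1L &
        !grepl(",", fix[, "ALT"])
    nSkip <- sum(!isSnp)
    if (nSkip) message(nSkip, " multi-allelic or non-SNP records skipped")
    if (!any(isSnp)) stop("no biallelic SNP records in VCF")
    gt <- vcfR::extract.gt(v, element = "GT")[isSnp, , drop = FALSE]
    fix <- fix[isSnp, , drop = FALSE]
    ids <- fix[, "ID"]
    noId <- is.na(ids) | ids == "."
    ids[noId] <- paste0(fix[noId, "CHROM"], ":", fix[noId, "POS"])
    if (anyDuplicated(ids)) stop("duplicated SNP ids in VCF")
    dose <- matrix(NA_real_, nrow(gt), ncol(gt))
    clean <- gsub("\\|", "/", gt)
    dose[clean %in% c("0/0")] <- 0
    dose[clean %in% c("0/1", "1/0")] <- 1
    dose[clean %in% c("1/1")] <- 2
    SnpGeno(t(dose), chrom = fix[, "CHROM"], bp = as.integer(fix[, "POS"]),
            snpId = ids, sampleId = colnames(gt))
}

.readDosageGeno <- function(path, mapPath) {
    if (is.null(mapPath)) stop("dosage input needs a SNP map (mapPath)")
    d <- data.table::fread(path, header = TRUE, data.table = FALSE)
    ids <- as.character(d[[1]])
    X <- as.matrix(d[, -1, drop = FALSE])
    rownames(X) <- ids
    map <- data.table::fread(mapPath, header = TRUE, data.table = FALSE)
    need <- c("chrom", "snp", "bp")
    if (!all(need %in% names(map))) stop("SNP map needs columns chrom, snp, bp")
    mi <- match(colnames(X), map$snp)
    if (anyNA(mi)) stop("SNP map does not cover all dosage columns")
    map <- map[mi, ]
    SnpGeno(X, chrom = as.character(map$chrom), bp = as.integer(map$bp),
            snpId = map$snp, sampleId = ids)
}

#' Write genotypes as a minimal VCF
#'
#' Unphased GT-only VCF 4.2 with placeholder A/B alleles (the simulator
#' tracks dosages, not nucleotides); missing dosages become `./.`.
#'
#' @param genotypes a [SnpGeno-class].
#' @param path output path (plain text).
#' @export
writeGenotypesVcf <- function(genotypes, path) {
    info <- snpInfo(genotypes)
    X <- dosageMatrix(genotypes)
    gtOf <- c("0/0", "0/1", "1/1")
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("##fileformat=VCFv4.2",
                 "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                 paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                         "INFO", "FORMAT", rownames(X)), collapse = "\t")), con)
    for (j in seq_len(nrow(info))) {
        g <- X[, j]
        gt <- ifelse(is.na(g), "./.", gtOf[g + 1L])
        writeLines(paste(c(info$chrom[j], info$bp[j], info$snp[j], "A", "B",
                           ".", "PASS", ".", "GT", gt), collapse = "\t"), con)
    }
    invisible(path)
}

#' @describeIn writeGenotypesVcf dosage matrix as TSV (rows = individuals,
#'   first column `id`, remaining columns = SNP ids).
#' @export
writeDosageTsv <- function(genotypes, path) {
    X <- dosageMatrix(genotypes)
    d <- data.frame(id = rownames(X), X, check.names = FALSE,
                    stringsAsFactors = FALSE)
    data.table::fwrite(d, path, sep = "\t", na = "NA", quote = FALSE)
    invisible(path)
}

#' @describeIn writeGenotypesVcf SNP map as TSV (chrom, snp, bp).
#' @export
writeSnpMap <- function(genotypes, path) {
    data.table::fwrite(snpInfo(genotypes)[, c("chrom", "snp", "bp")], path,
                       sep = "\t", quote = FALSE)
    invisible(path)
}

#' Read a phenotype TSV (columns id, value)
#'
#' @param path TSV with header columns `id` and `value`.
#' @return data.frame (id, value).
#' @export
readPhenotype <- function(path) {
    d <- data.table::fread(path, header = TRUE, data.table = FALSE)
    if (!all(c("id", "value") %in% names(d)))
        stop("phenotype file needs columns id, value")
    data.frame(id = as.character(d$id), value = as.numeric(d$value),
               stringsAsFactors = FALSE)
}

#' Read a pedigree TSV (columns id, sire, dam; 0 or empty = unknown)
#'
#' @param path TSV with header columns `id`, `sire`, `dam`.
#' @return data.frame (id, sire, dam) with NA for unknown parents.
#' @export
readPedigree <- function(path) {
    d <- data.table::fread(path, header = TRUE, data.table = FALSE,
                           colClasses = "character")
    if (!all(c("id", "sire", "dam") %in% names(d)))
        stop("pedigree file needs columns id, sire, dam")
    clean <- function(x) { x[x %in% c("0", "", "NA")] <- NA_character_; x }
    data.frame(id = as.character(d$id), sire = clean(as.character(d$sire)),
               dam = clean(as.character(d$dam)), stringsAsFactors = FALSE)
}

#' @describeIn readPhenotype write the companion TSV.
#' @param phenotype data.frame (id, value).
#' @export
writePhenotype <- function(phenotype, path) {
    data.table::fwrite(phenotype[, c("id", "value")], path, sep = "\t",
                       quote = FALSE)
    invisible(path)
}

#' @describeIn readPedigree write the companion TSV (NA written as 0).
#' @param pedigree data.frame (id, sire, dam).
#' @export
writePedigree <- function(pedigree, path) {
    d <- pedigree[, c("id", "sire", "dam")]
    d$sire[is.na(d$sire)] <- "0"
    d$dam[is.na(d$dam)] <- "0"
    data.table::fwrite(d, path, sep = "\t", quote = FALSE)
    invisible(path)
}

#' Write / read an association table
#'
#' Tab-separated, full double precision, with `#`-prefixed metadata lines
#' recording the relationship protocol, genomic-control mode, fixed SNP
#' covariates and variance components, so a round trip reproduces the
#' object.
#'
#' @param assoc an [AssocTable-class].
#' @param path output path.
#' @export
writeAssoc <- function(assoc, path) {
    con <- file(path, "w")
    on.exit(close(con))
    vcTxt <- vapply(names(assoc@vc), function(nm) {
        vc <- assoc@vc[[nm]]
        sprintf("%s:%.17g,%.17g", nm, vc@sigmaG2, vc@sigmaE2)
    }, "")
    writeLines(c(paste0("# relationship=", assoc@method),
                 paste0("# gcMode=", assoc@gcMode),
                 paste0("# fixedSnps=", paste(assoc@fixedSnps, collapse = ",")),
                 paste0("# vc=", paste(vcTxt, collapse = ";"))), con)
    tb <- assocResults(assoc)
    num <- vapply(tb, is.numeric, NA)
    fmt <- tb
    fmt[num] <- lapply(tb[num], function(x) sprintf("%.17g", x))
    fmt$bp <- as.character(tb$bp)
    writeLines(paste(names(tb), collapse = "\t"), con)
    if (nrow(fmt))
        writeLines(do.call(paste, c(unname(as.list(fmt)), sep = "\t")), con)
    invisible(path)
}

#' @rdname writeAssoc
#' @return `readAssoc` returns the reconstructed [AssocTable-class]
#'   (variance-component metadata is restored with `logLik`/iteration
#'   details dropped).
#' @export
readAssoc <- function(path) {
    lines <- readLines(path)
    meta <- grep("^#", lines, value = TRUE)
    getMeta <- function(key) {
        hit <- grep(paste0("^# ", key, "="), meta, value = TRUE)
        if (!length(hit)) "" else sub(paste0("^# ", key, "="), "", hit[1])
    }
    body <- lines[!grepl("^#", lines)]
    tb <- data.table::fread(text = paste(body, collapse = "\n"),
                            header = TRUE, data.table = FALSE)
    tb$chr <- as.character(tb$chr)
    tb$snp <- as.character(tb$snp)
    vc <- list()
    vcTxt <- getMeta("vc")
    if (nzchar(vcTxt)) {
        for (piece in strsplit(vcTxt, ";", fixed = TRUE)[[1]]) {
            kv <- strsplit(piece, ":", fixed = TRUE)[[1]]
            num <- as.numeric(strsplit(kv[2], ",", fixed = TRUE)[[1]])
            vc[[kv[1]]] <- new("VarianceComponents", sigmaG2 = num[1],
                               sigmaE2 = num[2],
                               h2 = num[1] / (num[1] + num[2]),
                               logLik = NA_real_, nIter = 0L,
                               boundary = num[1] == 0)
        }
    }
    fx <- getMeta("fixedSnps")
    fixedSnps <- if (nzchar(fx)) strsplit(fx, ",", fixed = TRUE)[[1]] else character()
    new("AssocTable", table = tb, method = getMeta("relationship"), vc = vc,
        fixedSnps = fixedSnps,
        gcMode = if (nzchar(getMeta("gcMode"))) getMeta("gcMode") else "none")
}

#' Write / read a relationship matrix as gzipped triplets
#'
#' Lower-triangle (i, j, nSnps, value) triplets with 1-based indices and a
#' `#`-prefixed header carrying method and sample ids, matching the common
#' GRM exchange format of GWAS tools.
#'
#' @param rel a [RelationshipMatrix-class].
#' @param path output path (`.gz` suggested).
#' @export
writeGrm <- function(rel, path) {
    v <- relValues(rel)
    con <- gzfile(path, "w")
    on.exit(close(con))
    writeLines(c(paste0("# method=", relMethod(rel)),
                 paste0("# excluded=", paste(rel@excluded, collapse = ",")),
                 paste0("# ids=", paste(rownames(v), collapse = ","))), con)
    idx <- which(lower.tri(v, diag = TRUE), arr.ind = TRUE)
    writeLines(sprintf("%d\t%d\t%d\t%.17g", idx[, 1], idx[, 2],
                       nSnpsUsed(rel), v[idx]), con)
    invisible(path)
}

#' @rdname writeGrm
#' @export
readGrm <- function(path) {
    lines <- readLines(path)
    meta <- grep("^#", lines, value = TRUE)
    getMeta <- function(key) {
        hit <- grep(paste0("^# ", key, "="), meta, value = TRUE)
        if (!length(hit)) "" else sub(paste0("^# ", key, "="), "", hit[1])
    }
    ids <- strsplit(getMeta("ids"), ",", fixed = TRUE)[[1]]
    tb <- data.table::fread(text = paste(lines[!grepl("^#", lines)],
                                         collapse = "\n"),
                            header = FALSE, data.table = FALSE)
    n <- length(ids)
    v <- matrix(0, n, n, dimnames = list(ids, ids))
    v[cbind(tb$V1, tb$V2)] <- tb$V4
    v[cbind(tb$V2, tb$V1)] <- tb$V4
    ex <- getMeta("excluded")
    new("RelationshipMatrix", values = v, method = getMeta("method"),
        nSnpsUsed = as.integer(tb$V3[1]),
        excluded = if (nzchar(ex)) strsplit(ex, ",")[[1]] else character())
}
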