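#' Construct a validated SummaryStats object
#'
#' Validates and canonicalizes a raw per-SNP association table. Rows failing
#' validation (chromosome outside 1-22, non-ACGT or identical alleles,
#' unparsable numerics, duplicate `(CHR,BP,A1,A2)` keys) are dropped and
#' counted in the QC log. A missing `Z` is derived from `BETA/SE`, or from
#' `P` plus the sign of a `BETA` column. P-values at or below `pFloor`
#' (including 0) are clamped to `pFloor` with a warning; where `P` and `Z`
#' disagree beyond a relative tolerance of 1e-3, `Z` is authoritative and `P`
#' is recomputed as \eqn{2\Phi(-|z|)}.
#'
#' @param table data.frame with (a superset of) columns `SNP CHR BP A1 A2 Z P
#'   N`, optionally `BETA`/`SE` instead of `Z`.
#' @param traitLabel trait name.
#' @param pFloor smallest representable p-value (keeps -log10 p finite).
#' @param n optional scalar sample size used when no `N` column is present.
#' @return a [SummaryStats-class] object sorted by `(CHR, BP)`.
#' @export
SummaryStats <- function(table, traitLabel = "trait", pFloor = 1e-300, n = NULL) {
    log <- list()
    tab <- as.data.frame(table, stringsAsFactors = FALSE)
    if (!"SNP" %in% names(tab))
        tab$SNP <- paste0(tab$CHR, ":", tab$BP)
    if (!"N" %in% names(tab)) {
        if (is.null(n)) stop("no sample-size column 'N' and no scalar `n` given")
        tab$N <- n
    }
    for (col in c("CHR", "BP", "Z", "P", "N", "BETA", "SE"))
        if (col %in% names(tab)) tab[[col]] <- suppressWarnings(as.numeric(tab[[col]]))
    if (!"Z" %in% names(tab)) tab$Z <- rep(NA_real_, nrow(tab))
    # z := beta/se where z is absent; else p + signed beta
    if (all(c("BETA", "SE") %in% names(tab))) {
        i <- is.na(tab$Z) & !is.na(tab$BETA) & !is.na(tab$SE) & tab$SE > 0
        tab$Z[i] <- tab$BETA[i] / tab$SE[i]
        if (any(i)) log$z_from_beta_se <- sum(i)
    }
    if ("BETA" %in% names(tab) && "P" %in% names(tab)) {
        i <- is.na(tab$Z) & !is.na(tab$BETA) & !is.na(tab$P) & tab$P > 0 & tab$P <= 1
        tab$Z[i] <- sign(tab$BETA[i]) * qnorm(pmax(tab$P[i], pFloor) / 2, lower.tail = FALSE)
        if (any(i)) log$z_from_p_sign <- sum(i)
    }
    if (!"P" %in% names(tab)) tab$P <- NA_real_
    for (col in c("A1", "A2")) if (col %in% names(tab)) tab[[col]] <- toupper(as.character(tab[[col]]))

    miss <- setdiff(c("CHR", "BP", "A1", "A2"), names(tab))
    if (length(miss)) stop("missing mandatory columns: ", paste(miss, collapse = ", "))

    n0 <- nrow(tab)
    keep <- !is.na(tab$CHR) & tab$CHR %in% 1:22 & !is.na(tab$BP) & tab$BP >= 1
    if (any(!keep)) log$bad_coordinates <- sum(!keep)
    tab <- tab[keep, , drop = FALSE]
    keep <- tab$A1 %in% .BASES & tab$A2 %in% .BASES & tab$A1 != tab$A2
    if (any(!keep)) log$bad_alleles <- sum(!keep)
    tab <- tab[keep, , drop = FALSE]
    keep <- is.finite(tab$Z) & is.finite(tab$N) & tab$N > 0
    if (any(!keep)) log$bad_numeric <- sum(!keep)
    tab <- tab[keep, , drop = FALSE]

    # p-value handling: clamp the floor, then enforce p ~ 2 Phi(-|z|)
    noP <- !is.finite(tab$P)
    if (any(noP)) { tab$P[noP] <- 2 * pnorm(-abs(tab$Z[noP])); log$p_from_z <- sum(noP) }
    low <- tab$P < pFloor
    if (any(low)) {
        warning(sum(low), " p-value(s) below ", pFloor, " clamped to the floor")
        tab$P[low] <- pFloor
        log$p_clamped <- sum(low)
    }
    bad <- tab$P > 1 | tab$P <= 0
    if (any(bad)) { log$bad_p <- sum(bad); tab <- tab[!bad, , drop = FALSE]; low <- low[!bad] }
    pz <- pmax(2 * pnorm(-abs(tab$Z)), pFloor)
    off <- abs(tab$P - pz) > 1e-3 * pmax(tab$P, pz) & !low
    if (any(off)) {
        tab$P[off] <- pz[off]
        log$p_recomputed_from_z <- sum(off)
        message(sum(off), " p-value(s) disagreed with z beyond tolerance; recomputed from z")
    }

    tab <- tab[order(tab$CHR, tab$BP, tab$A1, tab$A2), .SUMSTATS_COLS, drop = FALSE]
    dup <- duplicated(tab[, c("CHR", "BP", "A1", "A2")])
    if (any(dup)) { log$duplicate_keys <- sum(dup); tab <- tab[!dup, , drop = FALSE] }
    rownames(tab) <- NULL
    tab$CHR <- as.integer(tab$CHR)
    tab$BP <- as.integer(tab$BP)
    if (n0 > nrow(tab)) log$rows_dropped_total <- n0 - nrow(tab)
    new("SummaryStats", traitLabel = traitLabel, table = tab, qcLog = log)
}

#' Read GWAS summary statistics from a delimited file
#'
#' Reads a whitespace- or tab-delimited text file (gzip accepted) with a
#' header row, renames columns through `columnMap`, and validates through
#' [SummaryStats()]. Either a `Z` column, or `BETA` + `SE` (then
#' \eqn{z = \beta/se}), or `P` + a signed `BETA` must be derivable, otherwise
#' an error names the missing columns.
#'
#' @param path file path (plain or `.gz`).
#' @param columnMap named character vector mapping canonical names (`SNP`,
#'   `CHR`, `BP`, `A1`, `A2`, `Z`, `P`, `N`, `BETA`, `SE`) to the file's
#'   column names. Columns already canonically named need no entry.
#' @inheritParams SummaryStats
#' @return a [SummaryStats-class].
#' @export
readSumstats <- function(path, columnMap = NULL, traitLabel = sub("\\.[^.]*(\\.gz)?$", "", basename(path)),
                         pFloor = 1e-300, n = NULL) {
    con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
    tab <- utils::read.table(con, header = TRUE, stringsAsFactors = FALSE,
        check.names = FALSE, comment.char = "", colClasses = "character")
    if (!is.null(columnMap)) {
        miss <- setdiff(unname(columnMap), names(tab))
        if (length(miss)) stop("columnMap names absent from file: ", paste(miss, collapse = ", "))
        for (canon in names(columnMap)) names(tab)[names(tab) == columnMap[[canon]]] <- canon
    }
    if (!("Z" %in% names(tab) || all(c("BETA", "SE") %in% names(tab)) ||
          all(c("BETA", "P") %in% names(tab))))
        stop("cannot derive Z: need a Z column, or BETA+SE, or P+signed BETA")
    SummaryStats(tab, traitLabel = traitLabel, pFloor = pFloor, n = n)
}

#' Write summary statistics in the canonical format
#'
#' Tab-delimited table with fixed header `SNP CHR BP A1 A2 Z P N`.
#'
#' @param x a [SummaryStats-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSumstats <- function(x, path) {
    stopifnot(is(x, "SummaryStats"))
    utils::write.table(x@table, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Harmonize two summary-statistics tables onto a shared variant set
#'
#' Intersects both tables on `(CHR, BP)` and re-orients trait 2 to trait 1's
#' allele coding: when trait 2's alleles are swapped the z-sign is flipped
#' and alleles reordered; when they sit on the opposite strand they are
#' complemented first (with a sign flip if also swapped). Strand-ambiguous
#' palindromic variants (A/T, C/G) are removed when `dropAmbiguous` is TRUE,
#' since their orientation cannot be resolved from alleles alone.
#' Irreconcilable allele sets are dropped and counted.
#'
#' @param t1,t2 validated [SummaryStats-class] objects.
#' @param dropAmbiguous drop A/T and C/G variants (default TRUE).
#' @return a [HarmonizedPair-class]; its `log` lists counts of shared,
#'   sign-flipped, strand-flipped, ambiguous and irreconcilable variants.
#' @export
harmonize <- function(t1, t2, dropAmbiguous = TRUE) {
    stopifnot(is(t1, "SummaryStats"), is(t2, "SummaryStats"))
    a <- t1@table; b <- t2@table
    # one record per position within each table (multi-allelic sites dropped)
    a <- a[!(duplicated(a[, c("CHR", "BP")]) | duplicated(a[, c("CHR", "BP")], fromLast = TRUE)), ]
    b <- b[!(duplicated(b[, c("CHR", "BP")]) | duplicated(b[, c("CHR", "BP")], fromLast = TRUE)), ]
    key <- function(d) paste(d$CHR, d$BP, sep = ":")
    i <- match(key(a), key(b))
    sel <- !is.na(i)
    a <- a[sel, , drop = FALSE]; b <- b[i[sel], , drop = FALSE]
    log <- list(shared_positions = nrow(a))

    same <- a$A1 == b$A1 & a$A2 == b$A2
    swap <- a$A1 == b$A2 & a$A2 == b$A1
    cb1 <- unname(.COMPLEMENT[b$A1]); cb2 <- unname(.COMPLEMENT[b$A2])
    flip <- !same & !swap & a$A1 == cb1 & a$A2 == cb2
    flipswap <- !same & !swap & a$A1 == cb2 & a$A2 == cb1
    ambiguous <- a$A1 == unname(.COMPLEMENT[a$A2])   # palindromic in trait 1 coding

    keep <- same | swap | flip | flipswap
    log$irreconcilable_dropped <- sum(!keep)
    if (dropAmbiguous) {
        log$ambiguous_dropped <- sum(ambiguous & keep)
        keep <- keep & !ambiguous
    }
    a <- a[keep, , drop = FALSE]; b <- b[keep, , drop = FALSE]
    doFlip <- (swap | flipswap)[keep]
    log$sign_flipped <- sum(doFlip)
    log$strand_flipped <- sum((flip | flipswap)[keep])
    b$Z[doFlip] <- -b$Z[doFlip]
    b$A1 <- a$A1; b$A2 <- a$A2
    rownames(a) <- rownames(b) <- NULL
    new("HarmonizedPair",
        trait1 = new("SummaryStats", traitLabel = t1@traitLabel, table = a, qcLog = t1@qcLog),
        trait2 = new("SummaryStats", traitLabel = t2@traitLabel, table = b, qcLog = t2@qcLog),
        log = log)
}

#' Default regions excluded from model fitting
#'
#' The extended MHC (chr6:25-35 Mb) and the chr8 inversion (chr8:7-13 Mb),
#' regions of long-range complex LD conventionally excluded when *fitting*
#' mixture models and FDR grids. Discovery and locus reporting keep these
#' regions (flagged), since joint loci can legitimately fall inside them.
#'
#' @return data.frame with columns `chrom`, `lo`, `hi` (1-based inclusive).
#' @export
defaultExcludedRegions <- function() {
    data.frame(chrom = c(6L, 8L), lo = c(25e6, 7e6), hi = c(35e6, 13e6))
}

#' Remove variants falling inside genomic regions
#'
#' @param x a [SummaryStats-class] or [HarmonizedPair-class].
#' @param regions data.frame with columns `chrom`, `lo`, `hi` (1-based
#'   inclusive intervals), e.g. [defaultExcludedRegions()].
#' @return object of the same class with in-region variants removed and the
#'   removal count appended to the log.
#' @export
excludeRegions <- function(x, regions = defaultExcludedRegions()) {
    if (is(x, "HarmonizedPair")) {
        keep <- .outsideRegions(x@trait1@table, regions)
        log <- x@log; log$region_excluded <- sum(!keep)
        return(new("HarmonizedPair",
            trait1 = .subsetSumstats(x@trait1, keep), trait2 = .subsetSumstats(x@trait2, keep),
            log = log))
    }
    stopifnot(is(x, "SummaryStats"))
    keep <- .outsideRegions(x@table, regions)
    out <- .subsetSumstats(x, keep)
    out@qcLog$region_excluded <- sum(!keep)
    out
}

.outsideRegions <- function(tab, regions) {
    keep <- rep(TRUE, nrow(tab))
    for (r in seq_len(nrow(regions)))
        keep <- keep & !(tab$CHR == regions$chrom[r] & tab$BP >= regions$lo[r] & tab$BP <= regions$hi[r])
    keep
}

.subsetSumstats <- function(x, idx) {
    tab <- x@table[idx, , drop = FALSE]
    rownames(tab) <- NULL
    new("SummaryStats", traitLabel = x@traitLabel, table = tab, qcLog = x@qcLog)
}

#' Flag variants inside complex-LD regions
#'
#' @param x a [SummaryStats-class] table or a data.frame with `CHR`/`BP`.
#' @param regions as in [excludeRegions()].
#' @return logical vector, TRUE where the variant lies inside a region.
#' @export
inRegions <- function(x, regions = defaultExcludedRegions()) {
    tab <- if (is(x, "SummaryStats")) x@table else x
    !.outsideRegions(tab, regions)
}

#' Align summary statistics (or a harmonized pair) to an LD panel
#'
#' Intersects on `(CHR, BP)` and returns both objects restricted to the
#' common variants, in panel order, so row i of the table corresponds to
#' column i of the panel matrix.
#'
#' @param x a [SummaryStats-class] or [HarmonizedPair-class].
#' @param panel an [LDPanel-class].
#' @return list with elements `x` (same class, subset and reordered) and
#'   `panel` (subset [LDPanel-class]).
#' @export
matchToPanel <- function(x, panel) {
    tab <- if (is(x, "HarmonizedPair")) x@trait1@table else x@table
    pk <- paste(panel@variants$CHR, panel@variants$BP, sep = ":")
    tk <- paste(tab$CHR, tab$BP, sep = ":")
    i <- match(pk, tk)
    keepPanel <- which(!is.na(i))
    ord <- i[keepPanel]
    newPanel <- panel[keepPanel]
    if (is(x, "HarmonizedPair")) {
        out <- new("HarmonizedPair",
            trait1 = .subsetSumstats(x@trait1, ord), trait2 = .subsetSumstats(x@trait2, ord),
            log = x@log)
    } else out <- .subsetSumstats(x, ord)
    list(x = out, panel = newPanel)
}
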