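#' Construct an LD panel
#'
#' @param variants data.frame with columns `SNP`, `CHR`, `BP` (1-based).
#' @param R square sparse (or dense) matrix of signed allelic correlations,
#'   unit diagonal, symmetric, aligned to `variants`.
#' @param window physical window (bp) beyond which correlations are zero.
#' @return an [LDPanel-class].
#' @export
LDPanel <- function(variants, R, window = 1e6) {
    R <- methods::as(methods::as(methods::as(R, "dMatrix"), "generalMatrix"), "CsparseMatrix")
    new("LDPanel", variants = as.data.frame(variants), R = R, window = window)
}

#' @describeIn LDPanel subset a panel to the variants in `i` (integer or
#'   logical index); the correlation matrix is restricted accordingly.
#' @param x,i panel and index.
#' @param j,drop,... ignored (matrix-style calls are one-dimensional here).
#' @export
setMethod("[", "LDPanel", function(x, i, j, ..., drop = FALSE) {
    v <- x@variants[i, , drop = FALSE]
    rownames(v) <- NULL
    new("LDPanel", variants = v, R = x@R[i, i, drop = FALSE], window = x@window)
})

#' @rdname ldScores
#' @export
setMethod("ldScores", "LDPanel", function(panel) {
    unname(Matrix::colSums(panel@R * panel@R))
})

#' Write / read an LD panel as sparse triplets
#'
#' `writeLDPanel` writes `<prefix>.ld.tsv` with columns `i j r` (1-based
#' indices, strictly upper-triangular entries; the unit diagonal is implied)
#' and a sidecar variant index `<prefix>.varindex.tsv` with `SNP CHR BP`.
#' `readLDPanel` reconstructs the symmetric panel.
#'
#' @param panel an [LDPanel-class].
#' @param prefix file-path prefix for the two files.
#' @param window stored physical window (bp) for the reconstructed panel.
#' @return `writeLDPanel`: the prefix, invisibly. `readLDPanel`: an
#'   [LDPanel-class].
#' @export
writeLDPanel <- function(panel, prefix) {
    tr <- Matrix::summary(methods::as(panel@R, "TsparseMatrix"))
    tr <- tr[tr$i < tr$j, , drop = FALSE]
    utils::write.table(data.frame(i = tr$i, j = tr$j, r = tr$x),
        paste0(prefix, ".ld.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(panel@variants[, c("SNP", "CHR", "BP")],
        paste0(prefix, ".varindex.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(prefix)
}

#' @rdname writeLDPanel
#' @export
readLDPanel <- function(prefix, window = 1e6) {
    v <- utils::read.table(paste0(prefix, ".varindex.tsv"), header = TRUE,
        stringsAsFactors = FALSE)
    tr <- utils::read.table(paste0(prefix, ".ld.tsv"), header = TRUE)
    m <- nrow(v)
    R <- Matrix::sparseMatrix(i = c(tr$i, tr$j, seq_len(m)),
        j = c(tr$j, tr$i, seq_len(m)), x = c(tr$r, tr$r, rep(1, m)), dims = c(m, m))
    LDPanel(v, R, window = window)
}

#' Random pruning of an LD panel
#'
#' Visits variants in a seeded random order and keeps a variant iff it is not
#' in LD above `r2Threshold` with any already-kept variant. The result is a
#' maximal independent set at the threshold; repeating with different seeds
#' ("random pruning") de-correlates downstream empirical-cdf estimation.
#'
#' @param panel an [LDPanel-class].
#' @param r2Threshold squared-correlation threshold in (0, 1).
#' @param seed integer seed for the visiting order.
#' @return increasing integer vector of kept variant indices.
#' @export
randomPrune <- function(panel, r2Threshold = 0.1, seed = 1L) {
    stopifnot(r2Threshold > 0, r2Threshold < 1)
    m <- nVariants(panel)
    ord <- withSeed(seed, sample.int(m)) - 1L
    keep <- cpp_random_prune(panel@R@p, panel@R@i, panel@R@x, ord, r2Threshold)
    which(keep)
}

#' Greedy LD clumping
#'
#' Iteratively selects the most significant unassigned variant as a
#' representative and assigns to it all (candidate) variants with
#' \eqn{r^2 \ge} `r2Threshold`; repeats until all candidates are assigned.
#' Ties in significance are broken by ascending `(CHR, BP)`, making the
#' result deterministic. This is the clumping primitive behind the
#' FUMA-style independent-significant and lead-SNP tiers.
#'
#' @param scores per-variant significance, lower is better (p or FDR);
#'   length equal to the panel, `NA` outside `candidates`.
#' @param panel an [LDPanel-class].
#' @param r2Threshold assignment threshold on r-squared.
#' @param candidates integer indices of the variants to clump (default: all
#'   with non-missing scores).
#' @return list with `representatives` (indices in selection order) and
#'   `assignment` (integer vector over the panel: representative index per
#'   candidate, `NA` elsewhere).
#' @export
greedyClump <- function(scores, panel, r2Threshold = 0.6, candidates = which(!is.na(scores))) {
    m <- nVariants(panel)
    stopifnot(length(scores) == m)
    v <- panel@variants
    isCand <- rep(FALSE, m); isCand[candidates] <- TRUE
    ord <- candidates[order(scores[candidates], v$CHR[candidates], v$BP[candidates])]
    repOf <- cpp_greedy_clump(panel@R@p, panel@R@i, panel@R@x, ord - 1L, isCand, r2Threshold)
    assignment <- ifelse(repOf >= 0L, repOf + 1L, NA_integer_)
    reps <- unique(assignment[ord])
    list(representatives = reps, assignment = assignment)
}
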