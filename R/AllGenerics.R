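#' @name pleiomix-accessors
#' @title Accessors for pleiomix classes
#' @description Small accessor generics: `traitLabel()` returns the trait
#'   name, `nVariants()` the number of variants, `sumstatsTable()` the
#'   canonical data frame, `qcLog()` the validation log, `panelVariants()` /
#'   `panelMatrix()` the LD panel index and sparse correlation matrix,
#'   `fitParams()` the parameter object of a fit.
#' @param x object.
#' @return The slot content named above.
NULL

#' @rdname pleiomix-accessors
#' @export
setGeneric("traitLabel", function(x) standardGeneric("traitLabel"))
#' @rdname pleiomix-accessors
#' @export
setGeneric("nVariants", function(x) standardGeneric("nVariants"))
#' @rdname pleiomix-accessors
#' @export
setGeneric("sumstatsTable", function(x) standardGeneric("sumstatsTable"))
#' @rdname pleiomix-accessors
#' @export
setGeneric("qcLog", function(x) standardGeneric("qcLog"))
#' @rdname pleiomix-accessors
#' @export
setGeneric("panelVariants", function(x) standardGeneric("panelVariants"))
#' @rdname pleiomix-accessors
#' @export
setGeneric("panelMatrix", function(x) standardGeneric("panelMatrix"))
#' @rdname pleiomix-accessors
#' @export
setGeneric("fitParams", function(x) standardGeneric("fitParams"))

#' Compute per-variant LD scores
#'
#' The LD score of variant j is \eqn{\ell_j = \sum_k r^2_{jk}} over its
#' neighbourhood, including the self term, so \eqn{\ell_j \ge 1}. LD scores
#' are the regressor in LD-score regression.
#'
#' @param panel an [LDPanel-class].
#' @return numeric vector of LD scores aligned to the panel.
#' @examples
#' pan <- makeBlockPanel(n_blocks = 2, block_size = 2, rho = 0.5, seed = 1)
#' ldScores(pan)  # 1 + 0.25 each
#' @export
setGeneric("ldScores", function(panel) standardGeneric("ldScores"))

#' @rdname pleiomix-accessors
#' @export
setMethod("traitLabel", "SummaryStats", function(x) x@traitLabel)
#' @rdname pleiomix-accessors
#' @export
setMethod("nVariants", "SummaryStats", function(x) nrow(x@table))
#' @rdname pleiomix-accessors
#' @export
setMethod("sumstatsTable", "SummaryStats", function(x) x@table)
#' @rdname pleiomix-accessors
#' @export
setMethod("qcLog", "SummaryStats", function(x) x@qcLog)
#' @rdname pleiomix-accessors
#' @export
setMethod("nVariants", "LDPanel", function(x) nrow(x@variants))
#' @rdname pleiomix-accessors
#' @export
setMethod("panelVariants", "LDPanel", function(x) x@variants)
#' @rdname pleiomix-accessors
#' @export
setMethod("panelMatrix", "LDPanel", function(x) x@R)
#' @rdname pleiomix-accessors
#' @export
setMethod("nVariants", "HarmonizedPair", function(x) nrow(x@trait1@table))
#' @rdname pleiomix-accessors
#' @export
setMethod("fitParams", "MixerFit", function(x) x@params)

#' @rdname pleiomix-accessors
#' @param name trait slot, `"trait1"` or `"trait2"`.
#' @export
pairTrait <- function(x, name = c("trait1", "trait2")) {
    stopifnot(is(x, "HarmonizedPair"))
    slot(x, match.arg(name))
}

setMethod("show", "SummaryStats", function(object) {
    cat("SummaryStats '", object@traitLabel, "': ", nrow(object@table),
        " variants on ", length(unique(object@table$CHR)), " chromosome(s)\n", sep = "")
    if (length(object@qcLog)) {
        drops <- unlist(object@qcLog)
        cat("  QC log:", paste(names(drops), drops, sep = "=", collapse = ", "), "\n")
    }
})

setMethod("show", "HarmonizedPair", function(object) {
    cat("HarmonizedPair <", object@trait1@traitLabel, ", ", object@trait2@traitLabel,
        ">: ", nrow(object@trait1@table), " shared variants\n", sep = "")
})

setMethod("show", "LDPanel", function(object) {
    nnz <- length(object@R@x)
    cat("LDPanel: ", nrow(object@variants), " variants, ",
        nnz, " stored correlations (mean neighbourhood ",
        sprintf("%.1f", nnz / max(1, nrow(object@variants))), ")\n", sep = "")
})

setMethod("show", "MixerFit", function(object) {
    p <- object@params
    cat("MixerFit (", if (is(p, "UnivariateMixtureParams")) "univariate" else "bivariate",
        "): logLik = ", sprintf("%.2f", object@loglik), ", AIC = ", sprintf("%.2f", object@aic),
        ", n = ", object@nVariantsUsed, if (!object@converged) " [NOT CONVERGED]" else "",
        "\n", sep = "")
    est <- as.list(p)
    se <- object@se
    for (nm in names(est))
        cat(sprintf("  %-13s %.4g%s\n", nm, est[[nm]],
            if (nm %in% names(se) && is.finite(se[[nm]])) sprintf(" (se %.2g)", se[[nm]]) else ""))
})

setMethod("show", "FDRGrid", function(object) {
    cat("FDRGrid: condFDR(", object@primary, " | secondary), ",
        length(object@log10p1), " x ", length(object@strata), " cells, ",
        object@meta$pruneIters %||% 1, " pruning iteration(s)\n", sep = "")
})

setMethod("show", "QQCurves", function(object) {
    cat("QQCurves for '", object@primary, "': strata p2 <= {",
        paste(object@thresholds, collapse = ", "), "}, n = {",
        paste(object@nSnps, collapse = ", "), "}\n", sep = "")
})

#' @export
#' @method as.list UnivariateMixtureParams
as.list.UnivariateMixtureParams <- function(x, ...)
    list(pi = x@pi, sigmaBetaSq = x@sigmaBetaSq, sigma0Sq = x@sigma0Sq)

#' @export
#' @method as.list BivariateMixtureParams
as.list.BivariateMixtureParams <- function(x, ...)
    list(pi1 = x@pi1, pi2 = x@pi2, pi12 = x@pi12,
        sigmaBetaSq1 = x@sigmaBetaSq1, sigmaBetaSq2 = x@sigmaBetaSq2,
        rho12 = x@rho12, sigma0Sq1 = x@sigma0Sq1, sigma0Sq2 = x@sigma0Sq2,
        rho0 = x@rho0)

setMethod("as.list", "UnivariateMixtureParams", as.list.UnivariateMixtureParams)
setMethod("as.list", "BivariateMixtureParams", as.list.BivariateMixtureParams)

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so library code has no RNG side effects
withSeed <- function(seed, expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    expr
}
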