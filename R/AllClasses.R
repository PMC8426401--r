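#' @import methods
#' @importFrom stats pnorm qnorm dnorm optim median sd mad quantile rnorm runif
#'   setNames complete.cases cor approx uniroot p.adjust
#' @importFrom utils read.table write.table head tail
#' @useDynLib pleiomix, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importClassesFrom Matrix Matrix dgCMatrix
NULL

.SUMSTATS_COLS <- c("SNP", "CHR", "BP", "A1", "A2", "Z", "P", "N")
.BASES <- c("A", "C", "G", "T")

#' Per-trait GWAS summary statistics
#'
#' One row per SNP with the canonical columns `SNP CHR BP A1 A2 Z P N`:
#' identifier, chromosome (1-22), 1-based position, effect allele, other
#' allele, signed association z-score, p-value in (0, 1], effective sample
#' size. Rows are sorted by `(CHR, BP)` and `(CHR, BP, A1, A2)` keys are
#' unique. Create with [readSumstats()] or from a validated data frame with
#' [SummaryStats()].
#'
#' @slot traitLabel single character, trait name used in reports.
#' @slot table data.frame with the canonical columns.
#' @slot qcLog named list of row counts dropped or altered during validation.
#' @aliases SummaryStats
#' @export
setClass("SummaryStats",
    representation(traitLabel = "character", table = "data.frame", qcLog = "list"),
    prototype(traitLabel = "trait", qcLog = list()))

setValidity("SummaryStats", function(object) {
    tab <- object@table
    msg <- character()
    if (length(object@traitLabel) != 1L) msg <- c(msg, "traitLabel must be a single string")
    miss <- setdiff(.SUMSTATS_COLS, names(tab))
    if (length(miss)) return(paste("missing columns:", paste(miss, collapse = ", ")))
    if (nrow(tab)) {
        if (!all(tab$CHR %in% 1:22)) msg <- c(msg, "CHR must be an integer in 1-22")
        if (!all(tab$A1 %in% .BASES & tab$A2 %in% .BASES)) msg <- c(msg, "alleles must be A/C/G/T")
        if (any(tab$A1 == tab$A2)) msg <- c(msg, "A1 must differ from A2")
        if (any(tab$P <= 0 | tab$P > 1)) msg <- c(msg, "P must lie in (0, 1]")
        if (is.unsorted(order(tab$CHR, tab$BP)[seq_len(0)]) ||
            any(diff(tab$CHR * 1e10 + tab$BP) < 0)) msg <- c(msg, "rows must be sorted by (CHR, BP)")
        if (anyDuplicated(tab[, c("CHR", "BP", "A1", "A2")])) msg <- c(msg, "duplicate (CHR,BP,A1,A2) keys")
    }
    if (length(msg)) msg else TRUE
})

#' Allele-harmonized pair of summary-statistics tables
#'
#' Both tables are restricted to the shared `(CHR, BP)` variant set, in
#' identical order, with trait 2 re-oriented to trait 1's `(A1, A2)` alleles
#' (z-sign flipped where the alleles were swapped or strand-flipped). Built by
#' [harmonize()].
#'
#' @slot trait1,trait2 [SummaryStats-class] objects of equal length with
#'   matching coordinates and alleles row by row.
#' @slot log named list of counts (shared, swapped, strand-flipped, ambiguous
#'   or irreconcilable variants dropped).
#' @export
setClass("HarmonizedPair",
    representation(trait1 = "SummaryStats", trait2 = "SummaryStats", log = "list"))

setValidity("HarmonizedPair", function(object) {
    t1 <- object@trait1@table; t2 <- object@trait2@table
    if (nrow(t1) != nrow(t2)) return("tables differ in length")
    if (nrow(t1) && !(all(t1$CHR == t2$CHR) && all(t1$BP == t2$BP) &&
                      all(t1$A1 == t2$A1) && all(t1$A2 == t2$A2)))
        return("rows are not variant- and allele-aligned")
    TRUE
})

#' Sparse LD reference panel
#'
#' Signed allelic correlations between variants, held as a sparse symmetric
#' matrix aligned to a variant index. Neighbourhoods are confined to one
#' chromosome and (by construction) to a physical window. Supports LD scores,
#' random pruning and greedy clumping.
#'
#' @slot variants data.frame with columns `SNP`, `CHR`, `BP`, aligned to the
#'   matrix rows.
#' @slot R symmetric sparse `dgCMatrix` of signed correlations, unit diagonal.
#' @slot window physical window (bp) beyond which correlations are zero.
#' @export
setClass("LDPanel",
    representation(variants = "data.frame", R = "Matrix", window = "numeric"),
    prototype(window = 1e6))

setValidity("LDPanel", function(object) {
    msg <- character()
    v <- object@variants
    if (!all(c("SNP", "CHR", "BP") %in% names(v))) return("variants needs SNP, CHR, BP")
    if (nrow(v) != nrow(object@R) || nrow(object@R) != ncol(object@R))
        return("variant index and correlation matrix dimensions disagree")
    d <- Matrix::diag(object@R)
    if (nrow(v) && (max(abs(d - 1)) > 1e-8)) msg <- c(msg, "diagonal must be 1")
    if (nrow(v) && max(abs(object@R@x)) > 1 + 1e-8) msg <- c(msg, "|r| must be <= 1")
    # spot-check symmetry and same-chromosome confinement on a few columns
    if (nrow(v) > 1) {
        jj <- unique(round(seq(1, nrow(v), length.out = min(5, nrow(v)))))
        for (j in jj) {
            nb <- which(object@R[, j] != 0)
            if (!all(v$CHR[nb] == v$CHR[j])) { msg <- c(msg, "neighbourhoods cross chromosomes"); break }
            if (max(abs(object@R[j, nb] - object@R[nb, j])) > 1e-8) { msg <- c(msg, "matrix not symmetric"); break }
        }
    }
    if (length(msg)) msg else TRUE
})

#' Univariate causal mixture parameters
#'
#' Point-normal model for one trait: a variant is causal with probability
#' `pi`, and causal effects are N(0, `sigmaBetaSq`) per standardized genotype;
#' z-scores carry residual variance `sigma0Sq` (1 = no inflation).
#'
#' @slot pi causal-variant fraction in \[0, 1\].
#' @slot sigmaBetaSq causal effect-size variance (> 0).
#' @slot sigma0Sq residual z variance (> 0; ~1 for a calibrated GWAS).
#' @export
setClass("UnivariateMixtureParams",
    representation(pi = "numeric", sigmaBetaSq = "numeric", sigma0Sq = "numeric"))

setValidity("UnivariateMixtureParams", function(object) {
    ok <- is.finite(object@pi) && object@pi >= 0 && object@pi <= 1 &&
        is.finite(object@sigmaBetaSq) && object@sigmaBetaSq > 0 &&
        is.finite(object@sigma0Sq) && object@sigma0Sq > 0
    if (ok) TRUE else "need pi in [0,1], sigmaBetaSq > 0, sigma0Sq > 0 (all finite)"
})

#' Bivariate causal mixture parameters
#'
#' Four-component model for two traits: null, trait-1-only (`pi1`),
#' trait-2-only (`pi2`) and shared (`pi12`) causal components. Shared effects
#' are bivariate normal with correlation `rho12`; residual z-scores are
#' bivariate normal with variances `sigma0Sq1/2` and cross-trait correlation
#' `rho0` (e.g. from sample overlap).
#'
#' @slot pi1,pi2,pi12 component probabilities, `pi1 + pi2 + pi12 <= 1`.
#' @slot sigmaBetaSq1,sigmaBetaSq2 per-trait causal effect variances (> 0).
#' @slot rho12 effect-size correlation within the shared component, \[-1, 1\].
#' @slot sigma0Sq1,sigma0Sq2 residual z variances.
#' @slot rho0 residual cross-trait correlation, \[-1, 1\].
#' @export
setClass("BivariateMixtureParams",
    representation(pi1 = "numeric", pi2 = "numeric", pi12 = "numeric",
        sigmaBetaSq1 = "numeric", sigmaBetaSq2 = "numeric", rho12 = "numeric",
        sigma0Sq1 = "numeric", sigma0Sq2 = "numeric", rho0 = "numeric"))

setValidity("BivariateMixtureParams", function(object) {
    p <- c(object@pi1, object@pi2, object@pi12)
    ok <- all(is.finite(p)) && all(p >= 0) && sum(p) <= 1 + 1e-12 &&
        object@sigmaBetaSq1 > 0 && object@sigmaBetaSq2 > 0 &&
        object@sigma0Sq1 > 0 && object@sigma0Sq2 > 0 &&
        abs(object@rho12) <= 1 && abs(object@rho0) <= 1
    if (ok) TRUE else "component probabilities must be >= 0 and sum <= 1; variances > 0; |rho| <= 1"
})

#' Fitted causal mixture model
#'
#' Result of [fitUnivariate()] or [fitBivariate()]: point estimates (medians
#' over random-pruning repetitions), spread-based standard errors,
#' log-likelihood and AIC (`AIC = 2k - 2 logLik`), and fitting metadata.
#'
#' @slot params a [UnivariateMixtureParams-class] or
#'   [BivariateMixtureParams-class] object.
#' @slot se named numeric vector of standard errors (spread across pruning
#'   repetitions; `NA` when a single repetition was run).
#' @slot loglik,aic log-likelihood at the point estimate and its AIC.
#' @slot k number of free parameters.
#' @slot nVariantsUsed variants entering the likelihood.
#' @slot seed seed used for pruning/subsampling.
#' @slot converged logical; FALSE flags an optimizer that hit its iteration cap.
#' @slot details list: per-repetition estimates, constrained-model AICs, options.
#' @export
setClass("MixerFit",
    representation(params = "ANY", se = "numeric", loglik = "numeric", aic = "numeric",
        k = "numeric", nVariantsUsed = "numeric", seed = "numeric",
        converged = "logical", details = "list"))

setValidity("MixerFit", function(object) {
    if (is.finite(object@loglik) && abs(object@aic - (2 * object@k - 2 * object@loglik)) > 1e-6)
        return("AIC must equal 2k - 2 logLik")
    TRUE
})

#' Stratified condFDR lookup grid
#'
#' Empirical lookup table mapping (p1, p2) to the conditional FDR of the
#' primary trait given the secondary trait, estimated from the stratified
#' empirical cdf of p1 within nested p2 strata, averaged over random-pruning
#' iterations. `Fhat` holds the raw stratified cdf; `condfdr` holds
#' `p1 / max(Fhat, floor)` after monotone enforcement along the p1 axis and
#' clamping to (0, 1].
#'
#' @slot log10p1 grid of -log10 p1 values (rows).
#' @slot strata -log10 p2 stratum thresholds (columns), 0 = all SNPs.
#' @slot Fhat,condfdr numeric matrices `length(log10p1) x length(strata)`.
#' @slot primary label of the primary (p1) trait.
#' @slot meta list: pruning iterations, r2 threshold, seed, excluded regions,
#'   per-stratum SNP counts.
#' @export
setClass("FDRGrid",
    representation(log10p1 = "numeric", strata = "numeric", Fhat = "matrix",
        condfdr = "matrix", primary = "character", meta = "list"))

setValidity("FDRGrid", function(object) {
    msg <- character()
    if (!all(dim(object@Fhat) == c(length(object@log10p1), length(object@strata))))
        return("Fhat dimensions must match grid")
    if (any(object@Fhat < -1e-12 | object@Fhat > 1 + 1e-12)) msg <- c(msg, "Fhat outside [0,1]")
    if (any(object@condfdr <= 0 | object@condfdr > 1)) msg <- c(msg, "condFDR outside (0,1]")
    # cdf of p1 must not increase as -log10 p1 grows (smaller p1 => smaller cdf)
    if (ncol(object@Fhat) && any(apply(object@Fhat, 2, function(col) any(diff(col) > 1e-12))))
        msg <- c(msg, "Fhat must be non-increasing in -log10 p1")
    if (length(msg)) msg else TRUE
})

#' Conditional Q-Q curves
#'
#' Observed versus expected -log10 p quantiles of the primary trait within
#' nested secondary-trait p-value strata. Built by [conditionalQQ()].
#'
#' @slot curves named list (one element per stratum) of data.frames with
#'   columns `expected` and `observed` (-log10 p, ascending).
#' @slot thresholds secondary-trait p-value thresholds defining the strata.
#' @slot nSnps SNP count per stratum.
#' @slot lowCount logical per stratum; TRUE flags strata below 100 SNPs.
#' @slot primary label of the primary trait.
#' @export
setClass("QQCurves",
    representation(curves = "list", thresholds = "numeric", nSnps = "numeric",
        lowCount = "logical", primary = "character"))
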