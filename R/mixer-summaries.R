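#' Number of causal variants explaining 90% of SNP heritability
#'
#' Under the point-normal model the realized causal effects are Gaussian, so
#' the smallest set of variants capturing a fraction `q` of
#' \eqn{\sum \beta^2} is the upper order-statistic tail: solving
#' \eqn{2[t\phi(t) + 1 - \Phi(t)] = q} for \eqn{t^*}, that set has expected
#' size \eqn{2(1-\Phi(t^*)) \cdot \pi M} (multiplier ~0.446 at q = 0.9).
#' The alternative `"expected"` definition, where every causal variant
#' contributes its expectation, returns `q * pi * M`.
#'
#' @param params a [UnivariateMixtureParams-class] or
#'   [BivariateMixtureParams-class]; for the latter a count is returned per
#'   Venn component (unique1, unique2, shared).
#' @param M total number of variants in the reference.
#' @param q heritability fraction to capture (default 0.9).
#' @param method `"realized"` (order-statistic tail, default) or
#'   `"expected"`.
#' @return variant count (or named vector of counts per component).
#' @examples
#' p <- new("UnivariateMixtureParams", pi = 3e-3, sigmaBetaSq = 1e-3, sigma0Sq = 1)
#' nExplaining90(p, M = 1e5)
#' @export
nExplaining90 <- function(params, M, q = 0.9, method = c("realized", "expected")) {
    method <- match.arg(method)
    mult <- if (method == "realized") {
        tStar <- stats::uniroot(function(t) 2 * (t * dnorm(t) + pnorm(-t)) - q,
            c(0, 10), tol = 1e-12)$root
        2 * pnorm(-tStar)
    } else q
    if (is(params, "UnivariateMixtureParams")) return(mult * params@pi * M)
    stopifnot(is(params, "BivariateMixtureParams"))
    c(unique1 = mult * params@pi1 * M, unique2 = mult * params@pi2 * M,
        shared = mult * params@pi12 * M)
}

#' Model-implied genetic correlation
#'
#' Under the four-component mixture with equal effect variance within trait,
#' \deqn{r_g = \frac{\rho_{12}\,\pi_{12}}{\sqrt{(\pi_1+\pi_{12})(\pi_2+\pi_{12})}}.}
#'
#' @param params a [BivariateMixtureParams-class].
#' @return the genetic correlation.
#' @export
modelRg <- function(params) {
    stopifnot(is(params, "BivariateMixtureParams"))
    den <- sqrt((params@pi1 + params@pi12) * (params@pi2 + params@pi12))
    if (den == 0) stop("genetic correlation undefined: no causal variants in either trait")
    params@rho12 * params@pi12 / den
}

#' Fraction of shared variants with concordant effect directions
#'
#' For bivariate-normal effects with correlation \eqn{\rho_{12}}, the
#' probability of same-sign effects is the orthant probability
#' \eqn{1/2 + \arcsin(\rho_{12})/\pi}.
#'
#' @param rho12 effect correlation in \[-1, 1\].
#' @return concordant fraction in \[0, 1\].
#' @export
concordantFraction <- function(rho12) {
    stopifnot(abs(rho12) <= 1)
    0.5 + asin(rho12) / pi
}

#' Dice coefficient of polygenic overlap
#'
#' Standard overlap summary for the Venn output:
#' \eqn{2\pi_{12} / (\pi_1 + \pi_2 + 2\pi_{12})}.
#'
#' @param params a [BivariateMixtureParams-class].
#' @return the Dice coefficient in \[0, 1\].
#' @export
diceCoefficient <- function(params) {
    stopifnot(is(params, "BivariateMixtureParams"))
    den <- params@pi1 + params@pi2 + 2 * params@pi12
    if (den == 0) stop("Dice coefficient undefined: all component probabilities are zero")
    2 * params@pi12 / den
}
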