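#' Options controlling mixture-model fitting
#'
#' Numerical and resampling settings for [fitUnivariate()], [fitBivariate()]
#' and the likelihood evaluators. Defaults balance accuracy against run time
#' on desk-scale panels; all are overridable.
#'
#' Likelihood densities are obtained by inverting the model characteristic
#' function on a fixed trapezoidal t-grid, which is spectrally accurate for
#' these Gaussian-mixture CFs. The 1-D grid spans `[0, uniTmax]` with
#' `uniNt` points; the 2-D grid uses spacing `bivDt` up to `bivTmax` on a
#' half plane (the other half follows by symmetry). The aliasing period of
#' the discretized inversion is `2*pi/bivDt`; variants with `|z| > zMax` are
#' excluded from fitting subsets so the grid stays well inside it.
#'
#' @param pruneR2 r-squared threshold for random pruning of the fitting set.
#' @param pruneReps random-pruning repetitions; the point estimate is the
#'   per-parameter median and the SE the standard deviation across draws.
#' @param maxVariants cap on variants entering one likelihood (subsampled
#'   with the fit seed beyond this).
#' @param zMax |z| cap for fitting subsets.
#' @param nBins number of geometric r-squared bins for LD neighbourhoods.
#' @param r2Min neighbourhood r-squared below this is ignored.
#' @param uniNt,uniTmax 1-D inversion grid size and extent.
#' @param bivDt,bivTmax 2-D inversion grid spacing and extent.
#' @param maxit Nelder-Mead iteration cap per start.
#' @param nStarts refined optimizer starts kept from the coarse grid.
#' @return named list of options.
#' @export
mixerOptions <- function(pruneR2 = 0.1, pruneReps = 20, maxVariants = 10000,
                         zMax = 12, nBins = 24, r2Min = 1e-4,
                         uniNt = 512, uniTmax = 16,
                         bivDt = 0.175, bivTmax = 9,
                         maxit = 400, nStarts = 2) {
    as.list(environment())
}

# ---- LD neighbourhood binning -------------------------------------------

# Bin each subset variant's LD neighbourhood (including self, r = 1) into
# geometric r^2 bins and deduplicate identical profiles. The characteristic
# function then only needs one evaluation per unique profile.
.mixerLikData <- function(panel, idx, nBins, r2Min) {
    Rsub <- panel@R[, idx, drop = FALSE]
    edges <- 10^seq(log10(r2Min), 0, length.out = nBins + 1)
    r2 <- Rsub@x^2
    colIdx <- rep(seq_along(idx), diff(Rsub@p))
    keep <- r2 >= r2Min
    r2 <- r2[keep]; colIdx <- colIdx[keep]
    bin <- pmin(pmax(findInterval(r2, edges, rightmost.closed = TRUE), 1L), nBins)
    cnt <- matrix(0L, length(idx), nBins)
    tb <- table(factor(colIdx, seq_along(idx)), factor(bin, seq_len(nBins)))
    cnt[] <- as.integer(tb)
    r2mid <- vapply(seq_len(nBins), function(b) {
        v <- r2[bin == b]
        if (length(v)) mean(v) else sqrt(edges[b] * edges[b + 1])
    }, numeric(1))
    key <- do.call(paste, c(as.data.frame(cnt), sep = ","))
    uk <- !duplicated(key)
    list(C = cnt[uk, , drop = FALSE], pattern = match(key, key[uk]), r2mid = r2mid)
}

# ---- univariate likelihood ----------------------------------------------

.uniGrid <- function(opts) {
    t <- seq(0, opts$uniTmax, length.out = opts$uniNt)
    dt <- t[2] - t[1]
    w <- rep(dt / pi, opts$uniNt); w[c(1, opts$uniNt)] <- w[1] / 2
    list(t = t, w = w)
}

# weighted CF values per unique LD pattern on the 1-D grid; rows are
# patterns, columns grid points, trapezoid weights folded in
.uniW <- function(pi1, sbsq, s0sq, lik, nEff, grid) {
    a <- nEff * lik$r2mid * sbsq
    tsqHalf <- grid$t^2 / 2
    Lb <- log(outer(rep(1 - pi1, length(a)), rep(1, length(tsqHalf))) +
              pi1 * exp(-outer(a, tsqHalf)))
    G <- lik$C %*% Lb
    W <- exp(sweep(G, 2, s0sq * tsqHalf))
    sweep(W, 2, grid$w, `*`)
}

# density of each z_j under the univariate point-normal mixture via CF
# inversion; returns the vector of densities
.uniDensity <- function(pi1, sbsq, s0sq, lik, nEff, grid) {
    cpp_uni_density(.uniW(pi1, sbsq, s0sq, lik, nEff, grid),
        grid$t, lik$z, lik$pattern - 1L)
}

# P(|z| <= c) per unique pattern: the box integral of the inverted CF,
# int_{-c}^{c} cos(t z) dz = 2 sin(t c)/t
.uniBoxProb <- function(W, grid, c) {
    s <- ifelse(grid$t > 0, 2 * sin(grid$t * c) / grid$t, 2 * c)
    as.numeric(W %*% s)
}

#' Univariate mixture log-likelihood of signed z-scores
#'
#' Sums \eqn{\log f_j(z_j)} where the per-variant density is obtained by
#' inverting the characteristic function
#' \deqn{\varphi_j(t) = e^{-\sigma_0^2 t^2/2} \prod_{k \in LD(j)}
#'   \left[(1-\pi) + \pi\, e^{-n r_{jk}^2 \sigma_\beta^2 t^2/2}\right]}
#' on a fixed trapezoidal grid. Exact for point-normal mixtures with
#' independent causal draws.
#'
#' @param params a [UnivariateMixtureParams-class].
#' @param z signed z-scores aligned to the panel.
#' @param panel an [LDPanel-class] aligned to `z`.
#' @param n per-variant (or scalar) sample size; the median is used.
#' @param options see [mixerOptions()].
#' @param subset optional variant indices to evaluate on (default all).
#' @return the log-likelihood (a single number).
#' @export
univariateLoglik <- function(params, z, panel, n, options = mixerOptions(),
                             subset = seq_along(z)) {
    stopifnot(is(params, "UnivariateMixtureParams"), length(z) == nVariants(panel))
    lik <- .mixerLikData(panel, subset, options$nBins, options$r2Min)
    lik$z <- z[subset]
    f <- .uniDensity(params@pi, params@sigmaBetaSq, params@sigma0Sq,
        lik, stats::median(n), .uniGrid(options))
    bad <- which(!is.finite(f) | f <= 0)
    if (length(bad)) stop("non-finite density at variant index ", subset[bad[1]])
    sum(log(f))
}

# ---- bivariate likelihood -----------------------------------------------

.bivGrid <- function(opts) {
    t1 <- seq(0, opts$bivTmax, by = opts$bivDt)
    t2 <- seq(-opts$bivTmax, opts$bivTmax, by = opts$bivDt)
    w1 <- rep(2, length(t1)); w1[1] <- 1     # half-plane doubling, t1 = 0 once
    list(t1 = t1, t2 = t2,
        w = as.vector(outer(w1, rep(1, length(t2)))) * opts$bivDt^2 / (2 * pi)^2)
}

# weighted 2-D CF values per unique pattern (half-plane grid, doubling
# weights folded in)
.bivW <- function(p, lik, n1, n2, grid) {
    nt1 <- length(grid$t1); nt2 <- length(grid$t2)
    t1sqH <- grid$t1^2 / 2; t2sqH <- grid$t2^2 / 2
    tt <- outer(grid$t1, grid$t2)
    a1 <- n1 * lik$r2mid * p$sigmaBetaSq1
    a2 <- n2 * lik$r2mid * p$sigmaBetaSq2
    pi0 <- 1 - p$pi1 - p$pi2 - p$pi12
    nb <- length(a1)
    Lb <- matrix(0, nb, nt1 * nt2)
    ones2 <- rep(1, nt2); ones1 <- rep(1, nt1)
    for (b in seq_len(nb)) {
        E1 <- exp(-a1[b] * t1sqH); E2 <- exp(-a2[b] * t2sqH)
        # shared-component quadratic form in one exponent (numerically safe:
        # the form is positive semi-definite for |rho12| <= 1)
        Q12 <- outer(a1[b] * t1sqH, ones2) + outer(ones1, a2[b] * t2sqH) +
            p$rho12 * sqrt(a1[b] * a2[b]) * tt
        Fb <- pi0 + p$pi1 * outer(E1, ones2) + p$pi2 * outer(ones1, E2) +
            p$pi12 * exp(-Q12)
        Lb[b, ] <- log(Fb)
    }
    resid <- -(outer(p$sigma0Sq1 * t1sqH, rep(1, nt2)) +
               outer(rep(1, nt1), p$sigma0Sq2 * t2sqH) +
               p$rho0 * sqrt(p$sigma0Sq1 * p$sigma0Sq2) * tt)
    G <- lik$C %*% Lb
    W <- exp(sweep(G, 2, as.vector(resid), `+`))
    sweep(W, 2, grid$w, `*`)
}

# per-variant density f_j(z1, z2) under the four-component mixture
.bivDensity <- function(p, lik, n1, n2, grid) {
    cpp_biv_density(.bivW(p, lik, n1, n2, grid),
        grid$t1, grid$t2, lik$z1, lik$z2, lik$pattern - 1L)
}

# P(|z1| <= c, |z2| <= c) per unique pattern from the 2-D box integral
.bivBoxProb <- function(W, grid, c) {
    s1 <- ifelse(grid$t1 > 0, 2 * sin(grid$t1 * c) / grid$t1, 2 * c)
    s2 <- ifelse(grid$t2 != 0, 2 * sin(grid$t2 * c) / grid$t2, 2 * c)
    as.numeric(W %*% as.vector(outer(s1, s2)))
}

#' Bivariate mixture log-likelihood of a harmonized z-score pair
#'
#' Sums \eqn{\log f_j(z_{1j}, z_{2j})} where the joint density inverts the
#' 2-D characteristic function whose per-LD-partner factor is
#' \deqn{(1-\pi_1-\pi_2-\pi_{12}) + \pi_1 e^{-a_1 t_1^2/2} + \pi_2
#'   e^{-a_2 t_2^2/2} + \pi_{12} e^{-(a_1 t_1^2 + 2\rho_{12}\sqrt{a_1 a_2}
#'   t_1 t_2 + a_2 t_2^2)/2}}
#' with \eqn{a_t = n_t r_{jk}^2 \sigma_{\beta t}^2}, multiplied by the
#' residual bivariate-normal factor with \eqn{(\sigma_{01}^2, \sigma_{02}^2,
#' \rho_0)}, inverted on a 2-D trapezoidal grid.
#'
#' @param params a [BivariateMixtureParams-class].
#' @param pair a [HarmonizedPair-class] aligned to the panel.
#' @param panel an [LDPanel-class].
#' @param options see [mixerOptions()].
#' @param subset optional variant indices.
#' @return the log-likelihood.
#' @export
bivariateLoglik <- function(params, pair, panel, options = mixerOptions(),
                            subset = seq_len(nVariants(pair))) {
    stopifnot(is(params, "BivariateMixtureParams"), nVariants(pair) == nVariants(panel))
    lik <- .mixerLikData(panel, subset, options$nBins, options$r2Min)
    lik$z1 <- pair@trait1@table$Z[subset]
    lik$z2 <- pair@trait2@table$Z[subset]
    f <- .bivDensity(as.list(params), lik,
        stats::median(pair@trait1@table$N), stats::median(pair@trait2@table$N),
        .bivGrid(options))
    bad <- which(!is.finite(f) | f <= 0)
    if (length(bad)) stop("non-finite density at variant index ", subset[bad[1]])
    sum(log(f))
}
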