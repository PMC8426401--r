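# internal: fitting subset for one pruning repetition
.fitSubset <- function(panel, opts, seed) {
    idx <- randomPrune(panel, opts$pruneR2, seed)
    if (length(idx) > opts$maxVariants)
        idx <- sort(withSeed(seed + 7919L, sample(idx, opts$maxVariants)))
    idx
}

.safeLog <- function(f) sum(log(pmax(f, 1e-320)))

# censored univariate log-likelihood: variants with |z| > zMax contribute
# their tail probability log P(|z| > zMax) rather than a density, keeping the
# strongest signals in the likelihood without evaluating the inversion grid
# beyond its aliasing range
.uniCensLoglik <- function(pi1, sbsq, s0sq, lik, nEff, grid, zMax, kept) {
    W <- .uniW(pi1, sbsq, s0sq, lik, nEff, grid)
    f <- cpp_uni_density(W, grid$t, lik$z[kept], lik$pattern[kept] - 1L)
    ll <- .safeLog(f)
    if (!all(kept)) {
        pB <- pmin(.uniBoxProb(W, grid, zMax), 1)
        ll <- ll + sum(log(pmax(1 - pB[lik$pattern[!kept]], 1e-320)))
    }
    ll
}

# censored bivariate log-likelihood; censoring applies when either |z|
# exceeds zMax (box probability complement)
.bivCensLoglik <- function(p, lik, n1, n2, grid, zMax, kept) {
    W <- .bivW(p, lik, n1, n2, grid)
    f <- cpp_biv_density(W, grid$t1, grid$t2, lik$z1[kept], lik$z2[kept],
        lik$pattern[kept] - 1L)
    ll <- .safeLog(f)
    if (!all(kept)) {
        pB <- pmin(.bivBoxProb(W, grid, zMax), 1)
        ll <- ll + sum(log(pmax(1 - pB[lik$pattern[!kept]], 1e-320)))
    }
    ll
}

#' Fit the univariate causal mixture model
#'
#' Maximizes the characteristic-function likelihood of signed z-scores over
#' \eqn{(\pi, \sigma_\beta^2, \sigma_0^2)} on a random-pruned variant subset,
#' repeated over `pruneReps` pruning draws. The point estimate is the
#' per-parameter median across draws and the SE its standard deviation,
#' reflecting the variability induced by the random-pruning process.
#' Optimization is derivative-free (Nelder-Mead) from data-driven multistarts
#' on a coarse \eqn{\pi} grid, with a moment-matched \eqn{\sigma_\beta^2}
#' initialization.
#'
#' @param table a [SummaryStats-class] aligned to the panel (same variants,
#'   same order; see [matchToPanel()]).
#' @param panel an [LDPanel-class].
#' @param options see [mixerOptions()].
#' @param seed base seed; pruning draw r uses `seed + r`.
#' @return a [MixerFit-class]; `details` holds per-draw estimates, the subset
#'   sizes, and `aicNull`, the AIC of the no-causal-variant model
#'   (Gaussian with free variance) on the same subset.
#' @export
fitUnivariate <- function(table, panel, options = mixerOptions(), seed = 1L) {
    stopifnot(is(table, "SummaryStats"), nVariants(table) == nVariants(panel))
    z <- table@table$Z
    nEff <- stats::median(table@table$N)
    grid <- .uniGrid(options)
    ell <- ldScores(panel)

    perRep <- vector("list", options$pruneReps)
    logliks <- numeric(options$pruneReps)
    conv <- logical(options$pruneReps)
    firstLik <- NULL
    firstKept <- NULL
    for (r in seq_len(options$pruneReps)) {
        idx <- .fitSubset(panel, options, seed + r)
        lik <- .mixerLikData(panel, idx, options$nBins, options$r2Min)
        lik$z <- z[idx]
        kept <- abs(lik$z) <= options$zMax
        if (r == 1L) { firstLik <- lik; firstKept <- kept }
        meanEll <- mean(ell[idx])
        zsq <- mean(pmin(lik$z, options$zMax)^2)

        negll <- function(x) {
            p <- 0.5 * stats::plogis(x[1]); sb <- exp(x[2]); s0 <- 0.8 + 1.7 * stats::plogis(x[3])
            if (!is.finite(p) || !is.finite(sb)) return(1e10)
            -.uniCensLoglik(p, sb, s0, lik, nEff, grid, options$zMax, kept)
        }
        starts <- lapply(c(1e-5, 1e-4, 1e-3, 1e-2), function(p0) {
            sb0 <- max((zsq - 1) / (nEff * p0 * meanEll), 1e-12)
            c(stats::qlogis(min(p0 / 0.5, 0.999)), log(sb0), stats::qlogis((1.0 - 0.8) / 1.7))
        })
        coarse <- vapply(starts, negll, numeric(1))
        keep <- order(coarse)[seq_len(min(options$nStarts, length(starts)))]
        best <- NULL
        for (s in keep) {
            o <- stats::optim(starts[[s]], negll, method = "Nelder-Mead",
                control = list(maxit = options$maxit, reltol = 1e-9))
            if (is.null(best) || o$value < best$value) best <- o
        }
        x <- best$par
        perRep[[r]] <- c(pi = 0.5 * stats::plogis(x[1]), sigmaBetaSq = exp(x[2]),
            sigma0Sq = 0.8 + 1.7 * stats::plogis(x[3]), n = length(idx))
        logliks[r] <- -best$value
        conv[r] <- best$convergence == 0
    }
    est <- do.call(rbind, perRep)
    med <- apply(est[, 1:3, drop = FALSE], 2, stats::median)
    se <- if (nrow(est) > 1) apply(est[, 1:3, drop = FALSE], 2, stats::sd)
          else setNames(rep(NA_real_, 3), colnames(est)[1:3])
    params <- new("UnivariateMixtureParams", pi = med[["pi"]],
        sigmaBetaSq = med[["sigmaBetaSq"]], sigma0Sq = med[["sigma0Sq"]])
    ll <- .uniCensLoglik(params@pi, params@sigmaBetaSq, params@sigma0Sq,
        firstLik, nEff, grid, options$zMax, firstKept)
    # null-constrained comparator: pi = 0 collapses to N(0, sigma0^2)
    s0hat <- mean(firstLik$z^2)
    llNull <- sum(stats::dnorm(firstLik$z, 0, sqrt(s0hat), log = TRUE))
    if (!all(conv)) warning("optimizer hit the iteration cap in ",
        sum(!conv), " of ", length(conv), " pruning draws")
    new("MixerFit", params = params, se = se, loglik = ll, aic = 2 * 3 - 2 * ll,
        k = 3, nVariantsUsed = length(firstLik$z), seed = seed, converged = all(conv),
        details = list(perRep = est, aicNull = 2 * 1 - 2 * llNull,
            nEff = nEff, options = options))
}

#' Fit the bivariate causal mixture model
#'
#' Maximizes the bivariate characteristic-function likelihood over
#' \eqn{(\pi_1, \pi_2, \pi_{12}, \rho_{12}, \rho_0)} with the per-trait
#' effect and residual variances held at their univariate estimates (a
#' 9-parameter problem reduced to 5). Repeated over random-pruning draws as
#' in [fitUnivariate()]. Model fit is reported as the AIC difference between
#' the free model and two constrained comparators: no shared component
#' (\eqn{\pi_{12} = 0}) and maximal admissible overlap
#' (\eqn{\pi_{12} = \min} of the two univariate polygenicities).
#'
#' @param pair a [HarmonizedPair-class] aligned to the panel.
#' @param panel an [LDPanel-class].
#' @param univariateFits list of two [MixerFit-class] objects (trait 1, 2).
#' @param options see [mixerOptions()].
#' @param seed base seed for pruning draws.
#' @return a [MixerFit-class] with a [BivariateMixtureParams-class] in
#'   `params`; `details$aicConstrained` holds the comparator AICs
#'   (`none`, `max`) and `details$deltaAIC` the differences
#'   (constrained minus full; positive favours the full model).
#' @export
fitBivariate <- function(pair, panel, univariateFits, options = mixerOptions(),
                         seed = 1L) {
    stopifnot(is(pair, "HarmonizedPair"), nVariants(pair) == nVariants(panel),
        length(univariateFits) == 2)
    u1 <- univariateFits[[1]]@params; u2 <- univariateFits[[2]]@params
    z1 <- pair@trait1@table$Z; z2 <- pair@trait2@table$Z
    n1 <- stats::median(pair@trait1@table$N); n2 <- stats::median(pair@trait2@table$N)
    grid <- .bivGrid(options)
    fixed <- list(sigmaBetaSq1 = u1@sigmaBetaSq, sigmaBetaSq2 = u2@sigmaBetaSq,
        sigma0Sq1 = u1@sigma0Sq, sigma0Sq2 = u2@sigma0Sq)
    piTot1 <- u1@pi; piTot2 <- u2@pi
    # residual correlation initialized from clearly-null z pairs
    nullish <- abs(z1) < 2 & abs(z2) < 2
    rho0Init <- if (sum(nullish) > 50) stats::cor(z1[nullish], z2[nullish]) else 0

    mkNegll <- function(lik, kept, mask) {
        # mask: named list of fixed values for any of pi1, pi2, pi12, rho12, rho0
        function(x) {
            th <- .bivTheta(x, mask)
            s <- th$pi1 + th$pi2 + th$pi12
            if (s > 0.99) return(1e10 * (1 + s))
            p <- c(fixed, th)
            -.bivCensLoglik(p, lik, n1, n2, grid, options$zMax, kept)
        }
    }

    perRep <- vector("list", options$pruneReps)
    conv <- logical(options$pruneReps)
    firstLik <- NULL; firstKept <- NULL
    for (r in seq_len(options$pruneReps)) {
        idx <- .fitSubset(panel, options, seed + r)
        lik <- .mixerLikData(panel, idx, options$nBins, options$r2Min)
        lik$z1 <- z1[idx]; lik$z2 <- z2[idx]
        kept <- abs(lik$z1) <= options$zMax & abs(lik$z2) <= options$zMax
        if (r == 1L) { firstLik <- lik; firstKept <- kept }
        negll <- mkNegll(lik, kept, list())
        starts <- lapply(c(0.2, 0.8), function(frac) {
            p12 <- max(frac * min(piTot1, piTot2), 1e-7)
            .bivX(list(pi1 = max(piTot1 - p12, 1e-7), pi2 = max(piTot2 - p12, 1e-7),
                pi12 = p12, rho12 = 0.3, rho0 = rho0Init))
        })
        coarse <- vapply(starts, negll, numeric(1))
        keepS <- order(coarse)[seq_len(min(options$nStarts, length(starts)))]
        best <- NULL
        for (s in keepS) {
            o <- stats::optim(starts[[s]], negll, method = "Nelder-Mead",
                control = list(maxit = options$maxit, reltol = 1e-9))
            if (is.null(best) || o$value < best$value) best <- o
        }
        th <- .bivTheta(best$par, list())
        perRep[[r]] <- c(unlist(th), n = length(idx))
        conv[r] <- best$convergence == 0
    }
    est <- do.call(rbind, perRep)
    med <- apply(est[, 1:5, drop = FALSE], 2, stats::median)
    se <- if (nrow(est) > 1) apply(est[, 1:5, drop = FALSE], 2, stats::sd)
          else setNames(rep(NA_real_, 5), colnames(est)[1:5])
    params <- new("BivariateMixtureParams", pi1 = med[["pi1"]], pi2 = med[["pi2"]],
        pi12 = med[["pi12"]], rho12 = med[["rho12"]], rho0 = med[["rho0"]],
        sigmaBetaSq1 = fixed$sigmaBetaSq1, sigmaBetaSq2 = fixed$sigmaBetaSq2,
        sigma0Sq1 = fixed$sigma0Sq1, sigma0Sq2 = fixed$sigma0Sq2)
    ll <- .bivCensLoglik(c(fixed, as.list(params)[c("pi1", "pi2", "pi12", "rho12", "rho0")]),
        firstLik, n1, n2, grid, options$zMax, firstKept)
    aic <- 2 * 5 - 2 * ll

    # constrained comparators on the first pruning subset
    fitMasked <- function(mask, x0) {
        o <- stats::optim(x0, mkNegll(firstLik, firstKept, mask), method = "Nelder-Mead",
            control = list(maxit = options$maxit, reltol = 1e-9))
        -o$value
    }
    llNone <- fitMasked(list(pi12 = 1e-12, rho12 = 0),
        .bivX(list(pi1 = max(piTot1, 1e-7), pi2 = max(piTot2, 1e-7), rho0 = rho0Init)))
    p12max <- max(min(piTot1, piTot2), 1e-7)
    llMax <- fitMasked(list(pi12 = p12max,
            pi1 = max(piTot1 - p12max, 1e-9), pi2 = max(piTot2 - p12max, 1e-9)),
        .bivX(list(rho12 = 0.3, rho0 = rho0Init)))
    aicCon <- c(none = 2 * 3 - 2 * llNone, max = 2 * 3 - 2 * llMax)
    if (!all(conv)) warning("optimizer hit the iteration cap in ",
        sum(!conv), " of ", length(conv), " pruning draws")
    new("MixerFit", params = params, se = se, loglik = ll, aic = aic,
        k = 5, nVariantsUsed = length(firstLik$z1), seed = seed, converged = all(conv),
        details = list(perRep = est, aicConstrained = aicCon,
            deltaAIC = aicCon - aic, options = options))
}

# free-parameter transform for the bivariate optimizer: pi via scaled logistic
# (upper bound 0.5 each), rho via tanh; masked entries are fixed
.BIV_NAMES <- c("pi1", "pi2", "pi12", "rho12", "rho0")
.bivTheta <- function(x, mask) {
    th <- list()
    i <- 0L
    for (nm in .BIV_NAMES) {
        if (nm %in% names(mask)) { th[[nm]] <- mask[[nm]]; next }
        i <- i + 1L
        th[[nm]] <- if (startsWith(nm, "pi")) 0.5 * stats::plogis(x[i]) else tanh(x[i])
    }
    th
}
.bivX <- function(init) {
    # init holds starting values for the FREE parameters only, in .BIV_NAMES order
    x <- numeric(0)
    for (nm in .BIV_NAMES) {
        if (!nm %in% names(init)) next
        v <- init[[nm]]
        x <- c(x, if (startsWith(nm, "pi")) stats::qlogis(min(max(v / 0.5, 1e-12), 1 - 1e-12))
                  else atanh(min(max(v, -0.999), 0.999)))
    }
    x
}
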