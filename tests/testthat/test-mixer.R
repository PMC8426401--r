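# ---- likelihood densities ------------------------------------------------

test_that("null mixture collapses to the Gaussian log-likelihood", {
    pan <- makeBlockPanel(20, 10, rho = 0.7, seed = 1)
    m <- nVariants(pan)
    set.seed(8)
    z <- rnorm(m, 0, 1.1)
    ll <- univariateLoglik(uniParams(pi = 1e-300, sb = 1e-4, s0 = 1.21), z, pan, n = 1e5)
    ll0 <- sum(dnorm(z, 0, 1.1, log = TRUE))
    expect_lt(abs(ll - ll0) / m, 1e-6)
})

test_that("a fully causal isolated variant has a single-convolution normal density", {
    pan1 <- makeBlockPanel(1, 1, rho = 0, seed = 1)
    prm <- uniParams(pi = 1 - 1e-12, sb = 2e-5, s0 = 1)
    for (zv in c(0, 1.5, 4)) {
        ll <- univariateLoglik(prm, zv, pan1, n = 1e5)
        expect_lt(abs(ll - dnorm(zv, 0, sqrt(1 + 1e5 * 2e-5), log = TRUE)), 1e-8)
    }
})

test_that("univariate density matches the frozen Monte-Carlo convolution oracle", {
    # oracle: 2e6 draws of delta ~ Bern(0.4), beta ~ N(0, 5e-4) on a 5-variant
    # rho = 0.6 block, density of z_3 at 1.0 with n = 1e4 (seed 99)
    fz <- 0.17320661; fse <- 1.002e-4
    pan5 <- makeBlockPanel(1, 5, rho = 0.6, seed = 1)
    ll <- univariateLoglik(uniParams(pi = 0.4, sb = 5e-4, s0 = 1),
        c(0, 0, 1, 0, 0), pan5, n = 1e4, subset = 3)
    expect_lt(abs(exp(ll) - fz), 3 * fse)
})

test_that("bivariate density matches the frozen Monte-Carlo oracle and factorizes", {
    # oracle: 2e6 draws of the four-component mixture on the same block,
    # joint density at (1, 1), rho12 = 0.6 (seed 2)
    fz <- 0.034845871; fse <- 2.913e-5
    pan5 <- makeBlockPanel(1, 5, rho = 0.6, seed = 1)
    pair5 <- pairFromZ(pan5, c(0, 0, 1, 0, 0), c(0, 0, 1, 0, 0), n = 1e4)
    prm <- bivParams(pi1 = 0.15, pi2 = 0.1, pi12 = 0.2, sb1 = 5e-4, sb2 = 7e-4,
        rho12 = 0.6)
    ll <- bivariateLoglik(prm, pair5, pan5, subset = 3)
    expect_lt(abs(exp(ll) - fz), 3 * fse)

    # independence factorization: pi12 = 0, rho12 = rho0 = 0 on a shared grid
    pan <- makeBlockPanel(8, 10, rho = 0.7, seed = 1)
    set.seed(1)
    z1 <- rnorm(80); z2 <- rnorm(80)
    pair <- pairFromZ(pan, z1, z2, n = 1e4)
    optsB <- mixerOptions(bivDt = 0.175, bivTmax = 9)
    nt <- length(seq(0, optsB$bivTmax, by = optsB$bivDt))
    optsU <- mixerOptions(uniNt = nt, uniTmax = (nt - 1) * optsB$bivDt)
    bp <- bivParams(pi1 = 2e-3, pi2 = 4e-3, pi12 = 1e-300, sb1 = 5e-4, sb2 = 8e-4,
        s01 = 1.05, s02 = 0.98)
    llb <- bivariateLoglik(bp, pair, pan, optsB)
    ll1 <- univariateLoglik(uniParams(2e-3, 5e-4, 1.05), z1, pan, 1e4, optsU)
    ll2 <- univariateLoglik(uniParams(4e-3, 8e-4, 0.98), z2, pan, 1e4, optsU)
    expect_lt(abs(llb - ll1 - ll2) / 80, 1e-5)
})

test_that("likelihoods are converged in the inversion grid", {
    pan <- makeBlockPanel(10, 10, rho = 0.6, seed = 1)
    set.seed(3)
    z <- rnorm(100, 0, 1.3)
    prm <- uniParams(pi = 0.01, sb = 1e-3)
    llA <- univariateLoglik(prm, z, pan, 1e4, mixerOptions())
    llB <- univariateLoglik(prm, z, pan, 1e4, mixerOptions(uniNt = 1024))
    expect_lt(abs(llA - llB) / 100, 1e-4)

    pair <- pairFromZ(pan, z, rev(z), n = 1e4)
    bp <- bivParams(pi1 = 0.01, pi2 = 0.01, pi12 = 0.01, rho12 = 0.5, rho0 = 0.1)
    llC <- bivariateLoglik(bp, pair, pan)
    llD <- bivariateLoglik(bp, pair, pan, mixerOptions(bivDt = 0.0875))
    expect_lt(abs(llC - llD) / 100, 1e-4)
})

test_that("non-finite densities are reported with the offending variant", {
    pan <- makeBlockPanel(1, 3, rho = 0, seed = 1)
    expect_error(
        univariateLoglik(uniParams(pi = 1e-300, sb = 1e-6, s0 = 1), c(0, 60, 0), pan, 1e4),
        "variant index 2")
})

# ---- derived quantities --------------------------------------------------

test_that("n_explaining_90 uses the Gaussian order-statistic tail", {
    p <- uniParams(pi = 3e-3)
    # Monte-Carlo oracle: smallest top-|beta| set capturing 90% of sum beta^2
    set.seed(7)
    b2 <- sort(rnorm(1e6)^2, decreasing = TRUE)
    kk <- which(cumsum(b2) >= 0.9 * sum(b2))[1] / 1e6
    mult <- nExplaining90(p, M = 1) / p@pi
    expect_lt(abs(mult - kk) / kk, 0.005)
    expect_lt(abs(mult - 0.446), 0.005)

    # zero causal variants, exact linearity, per-component output
    expect_equal(nExplaining90(uniParams(pi = 1e-300), M = 1e5), 1e-300 * 1e5 * mult)
    expect_equal(nExplaining90(p, M = 2e5), 2 * nExplaining90(p, M = 1e5))
    bv <- bivParams(pi1 = 1e-3, pi2 = 2e-3, pi12 = 3e-3)
    counts <- nExplaining90(bv, M = 1e5)
    expect_equal(unname(counts), mult * c(1e-3, 2e-3, 3e-3) * 1e5)
    # expected-contribution alternative
    expect_equal(unname(nExplaining90(bv, M = 1e5, method = "expected")),
        0.9 * c(1e-3, 2e-3, 3e-3) * 1e5)
})

test_that("model rg follows the mixture formula and its symmetries", {
    expect_equal(modelRg(bivParams(pi1 = 1e-300, pi2 = 1e-300, pi12 = 1e-3, rho12 = 0.42)),
        0.42, tolerance = 1e-6)
    expect_equal(modelRg(bivParams(pi1 = 1e-3, pi2 = 1e-3, pi12 = 1e-3, rho12 = 0.6)), 0.3)
    p <- bivParams(pi1 = 2e-3, pi2 = 1e-3, pi12 = 1.5e-3, rho12 = 0.7)
    pneg <- bivParams(pi1 = 2e-3, pi2 = 1e-3, pi12 = 1.5e-3, rho12 = -0.7)
    expect_equal(modelRg(pneg), -modelRg(p))

    # Monte-Carlo identity: empirical correlation of simulated effect vectors
    pan <- makeBlockPanel(2000, 50, rho = 0, seed = 1)
    prm <- bivParams(pi1 = 0.1, pi2 = 0.1, pi12 = 0.1, rho12 = 0.6)
    sim <- simulatePair(pan, prm, 1e3, 1e3, seed = 31)
    empRg <- cor(sim$truth$beta1, sim$truth$beta2)
    expect_lt(abs(empRg - modelRg(prm)), 0.02)
})

test_that("concordant fraction is the arcsine orthant probability", {
    expect_equal(concordantFraction(0), 0.5)
    expect_equal(concordantFraction(1), 1.0)
    rhos <- seq(-0.9, 0.9, by = 0.3)
    expect_true(all(diff(concordantFraction(rhos)) > 0))
    # Monte-Carlo sign agreement at 1e6 bivariate-normal draws
    set.seed(12)
    x <- rnorm(1e6); y <- 0.6 * x + sqrt(1 - 0.36) * rnorm(1e6)
    expect_lt(abs(mean(x * y > 0) - concordantFraction(0.6)), 0.001)
})

test_that("dice coefficient summarizes component overlap", {
    expect_equal(diceCoefficient(bivParams(pi1 = 1e-300, pi2 = 1e-300, pi12 = 1e-3)), 1,
        tolerance = 1e-6)
    expect_equal(diceCoefficient(bivParams(pi1 = 1e-3, pi2 = 1e-3, pi12 = 0)), 0)
    expect_equal(diceCoefficient(bivParams(pi1 = 1e-3, pi2 = 1e-3, pi12 = 1e-3)), 0.5)
})

# ---- fitting -------------------------------------------------------------

test_that("univariate fits are deterministic and AIC-consistent", {
    pan <- makeBlockPanel(300, 50, rho = 0.6, seed = 1)
    sim <- simulatePair(pan, bivParams(pi12 = 3e-3, pi1 = 1e-300, pi2 = 1e-300,
        sb1 = 2e-3, rho12 = 1), 1e5, 1e5, seed = 44)
    opts <- fastFitOptions(maxVariants = 3000)
    f1 <- fitUnivariate(sim$trait1, pan, opts, seed = 5)
    f2 <- fitUnivariate(sim$trait1, pan, opts, seed = 5)
    expect_identical(as.list(fitParams(f1)), as.list(fitParams(f2)))
    expect_identical(f1@loglik, f2@loglik)
    expect_equal(f1@aic, 2 * f1@k - 2 * f1@loglik)
    # truth pi = 3e-3: recovered within a factor of 2 on one draw
    expect_gt(fitParams(f1)@pi, 1.5e-3)
    expect_lt(fitParams(f1)@pi, 6e-3)
})

test_that("pure-null data drive the causal fraction to zero and favour the null model", {
    pan <- makeBlockPanel(300, 50, rho = 0.6, seed = 1)
    sim <- simulatePair(pan, bivParams(pi1 = 1e-300, pi2 = 1e-300, pi12 = 1e-300),
        1e5, 1e5, seed = 45)
    fit <- fitUnivariate(sim$trait1, pan, fastFitOptions(maxVariants = 3000), seed = 6)
    expect_lt(fitParams(fit)@pi, 0.01)        # pi * M below 1% of M
    expect_lt(fit@details$aicNull, fit@aic)   # parsimony wins under the null
})
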