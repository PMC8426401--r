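test_that("conditional QQ strata nest and truncate correctly under perfect dependence", {
    pan <- makeBlockPanel(40, 50, rho = 0, seed = 1)
    set.seed(5)
    z <- rnorm(2000, 0, 1.4)
    pair <- pairFromZ(pan, z, z)          # p2 = p1 exactly
    qq <- suppressWarnings(conditionalQQ(pair, 1))
    expect_equal(unname(qq@nSnps), vapply(qq@curves, nrow, numeric(1)) |> unname())
    # each stratum is the left-truncation (upper tail) of the full curve
    full <- sort(-log10(sumstatsTable(pairTrait(pair, "trait1"))$P))
    for (k in seq_along(qq@curves)) {
        obs <- qq@curves[[k]]$observed
        expect_equal(obs, tail(full, length(obs)))
    }
    # deflection (median observed) increases with stringency
    meds <- vapply(qq@curves, function(d) median(d$observed), numeric(1))
    expect_true(all(diff(meds) > 0))
    # thin strata are flagged
    expect_true(any(qq@lowCount))
    expect_warning(conditionalQQ(pair, 1), "fewer than 100")
})

test_that("condFDR grid equals the hand-computed stratified cdf on a toy table", {
    # 10 SNPs, no LD, one pruning iteration, two strata (all SNPs; p2 <= 0.1)
    pan <- makeBlockPanel(10, 1, rho = 0, seed = 1)
    p1 <- c(0.001, 0.01, 0.02, 0.05, 0.2, 0.3, 0.5, 0.6, 0.8, 1.0)
    p2 <- c(0.05, 0.5, 0.01, 0.3, 0.08, 0.9, 0.02, 0.7, 0.04, 0.6)
    z1 <- qnorm(p1 / 2, lower.tail = FALSE)
    z2 <- qnorm(p2 / 2, lower.tail = FALSE)
    pair <- pairFromZ(pan, z1, z2)
    glp <- seq(0, 3, by = 0.5)
    grid <- buildFdrGrid(pair, pan, primary = 1, pruneIters = 1, seed = 1,
        exclude = NULL, strata = c(0, 1), log10p1 = glp, minStratumSize = 0)
    # brute-force stratified empirical cdf, computed independently
    oracle <- sapply(list(rep(TRUE, 10), p2 <= 0.1), function(sel)
        sapply(10^(-glp), function(x) mean(p1[sel] <= x)))
    expect_identical(dim(grid@Fhat), dim(oracle))
    expect_equal(unname(grid@Fhat), unname(oracle))
    # condFDR derivation: p1 / max(Fhat, floor), monotone in p1, clamped
    ns <- c(10, sum(p2 <= 0.1))
    raw <- sweep(1 / pmax(oracle, rep(1 / (ns + 1), each = length(glp))), 1, 10^(-glp), `*`)
    mono <- apply(raw, 2, function(col) rev(cummax(rev(col))))
    expect_equal(unname(grid@condfdr), unname(pmin(mono, 1)))
})

test_that("condFDR is ~1 under the global null and interpolation is well-behaved", {
    pan <- makeBlockPanel(200, 50, rho = 0, seed = 1)
    set.seed(6)
    pair <- pairFromZ(pan, rnorm(1e4), rnorm(1e4))
    grid <- buildFdrGrid(pair, pan, 1, pruneIters = 2, seed = 2, exclude = NULL)
    # cells backed by >= 1e3 SNPs: moderate p1, loose stratum
    for (q in list(c(0.5, 0.5), c(0.2, 0.8), c(0.1, 0.3)))
        expect_lt(abs(condFdr(grid, q[1], q[2]) - 1), 0.1)
    # exact grid nodes return the stored cell values
    i <- 6; j <- 3
    expect_equal(condFdr(grid, 10^(-grid@log10p1[i]), 10^(-grid@strata[j])),
        grid@condfdr[i, j])
    # p1 = 1 is never significant
    expect_equal(condFdr(grid, 1, 0.5), 1)
    # interior queries stay inside their surrounding cells
    set.seed(7)
    for (r in 1:50) {
        lp1 <- runif(1, 0, 5); lp2 <- runif(1, 0, 2.9)
        v <- condFdr(grid, 10^(-lp1), 10^(-lp2))
        i <- findInterval(lp1, grid@log10p1); j <- findInterval(lp2, grid@strata)
        cells <- grid@condfdr[i:(i + 1), j:(j + 1)]
        expect_gte(v, min(cells) - 1e-12)
        expect_lte(v, max(cells) + 1e-12)
    }
    expect_error(condFdr(grid, 0, 0.5), "p-values")
    expect_error(condFdr(grid, 0.5, 2), "p-values")
})

test_that("conjFDR is the maximum of the reciprocal condFDRs and trait-order invariant", {
    pan <- makeBlockPanel(100, 50, rho = 0.5, seed = 1)
    sim <- simulatePair(pan, bivParams(pi1 = 2e-3, pi2 = 2e-3, pi12 = 4e-3,
        sb1 = 2e-3, sb2 = 2e-3, rho12 = 0.8), 1e5, 1e5, seed = 13)
    pair <- pairFromSim(sim)
    grids <- buildFdrGrids(pair, pan, pruneIters = 3, seed = 4, exclude = NULL)
    t1 <- sumstatsTable(pairTrait(pair, "trait1")); t2 <- sumstatsTable(pairTrait(pair, "trait2"))
    cj <- conjFdr(grids$g1given2, grids$g2given1, t1$P, t2$P)
    c12 <- condFdr(grids$g1given2, t1$P, t2$P)
    c21 <- condFdr(grids$g2given1, t2$P, t1$P)
    expect_equal(cj, pmax(c12, c21))
    expect_true(all(cj >= c12 & cj >= c21))
    # swapping the traits swaps nothing in the conjunction
    swapped <- new("HarmonizedPair", trait1 = pairTrait(pair, "trait2"),
        trait2 = pairTrait(pair, "trait1"), log = list())
    gridsS <- buildFdrGrids(swapped, pan, pruneIters = 3, seed = 4, exclude = NULL)
    cjS <- conjFdr(gridsS$g1given2, gridsS$g2given1, t2$P, t1$P)
    expect_equal(cjS, cj)
    # the discovery set is a subset of both one-sided sets
    disc <- discover(pair, grids)
    expect_true(all(disc$CONDFDR12[disc$FLAG] < 0.05))
    expect_true(all(disc$CONDFDR21[disc$FLAG] < 0.05))
})

test_that("discovery tables behave at the threshold extremes", {
    pan <- makeBlockPanel(50, 20, rho = 0, seed = 1)
    set.seed(9)
    pair <- pairFromZ(pan, rnorm(1000), rnorm(1000))
    grids <- buildFdrGrids(pair, pan, pruneIters = 2, seed = 3, exclude = NULL)
    disc0 <- discover(pair, grids, threshold = 1e-30)
    expect_equal(sum(disc0$FLAG), 0L)
    expect_identical(names(disc0), c("SNP", "CHR", "BP", "Z1", "Z2", "P1", "P2",
        "CONDFDR12", "CONDFDR21", "CONJFDR", "FLAG"))
    disc1 <- discover(pair, grids, threshold = 1.0000001)
    expect_true(all(disc1$FLAG))
})

test_that("doubling the pruning iterations moves cells less than their spread", {
    pan <- makeBlockPanel(100, 50, rho = 0.6, seed = 1)
    sim <- simulatePair(pan, bivParams(pi12 = 3e-3, rho12 = 0.6), 1e5, 1e5, seed = 17)
    pair <- pairFromSim(sim)
    g10 <- buildFdrGrid(pair, pan, 1, pruneIters = 10, seed = 5, exclude = NULL)
    g20 <- buildFdrGrid(pair, pan, 1, pruneIters = 20, seed = 5, exclude = NULL)
    d <- abs(g10@Fhat - g20@Fhat)
    expect_true(all(d <= pmax(g20@meta$FhatSD, 1e-10)))
})

test_that("tightening the conditioning lowers condFDR when the secondary trait is enriched", {
    pan <- makeBlockPanel(200, 50, rho = 0.5, seed = 1)
    better <- 0
    for (s in 1:20) {
        sim <- simulatePair(pan, bivParams(pi1 = 5e-4, pi2 = 5e-4, pi12 = 4e-3,
            sb1 = 2e-3, sb2 = 2e-3, rho12 = 0.9), 1e5, 1e5, seed = 600 + s)
        pair <- pairFromSim(sim)
        grid <- buildFdrGrid(pair, pan, 1, pruneIters = 3, seed = s, exclude = NULL)
        cfLoose <- condFdr(grid, 1e-4, 1)
        cfTight <- condFdr(grid, 1e-4, 1e-3)
        better <- better + (cfTight < cfLoose)
    }
    # one-sided sign test at alpha = 0.05
    expect_gt(better, qbinom(0.95, 20, 0.5))
})

test_that("null discoveries are no more frequent than with unconditional FDR", {
    pan <- makeBlockPanel(200, 50, rho = 0, seed = 1)
    extra <- 0
    for (s in 1:5) {
        set.seed(700 + s)
        pair <- pairFromZ(pan, rnorm(1e4), rnorm(1e4))
        grids <- buildFdrGrids(pair, pan, pruneIters = 3, seed = s, exclude = NULL)
        nConj <- sum(discover(pair, grids)$FLAG)
        # unconditional analogue: single all-SNP stratum in both directions
        gU <- buildFdrGrids(pair, pan, pruneIters = 3, seed = s, exclude = NULL,
            strata = 0)
        nUncond <- sum(discover(pair, gU)$FLAG)
        extra <- extra + max(0, nConj - nUncond)
    }
    expect_lte(extra, 2)
})
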