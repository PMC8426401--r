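#' Conditional Q-Q curves for cross-trait enrichment
#'
#' For each secondary-trait threshold, the observed quantiles of
#' -log10 p of the primary trait among SNPs with `p2 <= threshold` are paired
#' with the expected -log10 uniform quantiles. Successive leftward (upward)
#' deflections of the observed curve as the conditioning tightens indicate
#' cross-trait enrichment; under independence every stratum lies on the
#' identity line.
#'
#' @param pair a [HarmonizedPair-class].
#' @param primary 1 or 2: which trait supplies the primary p-values.
#' @param thresholds secondary-trait p-value thresholds defining nested
#'   strata (default `c(1, 0.1, 0.01, 0.001)`).
#' @param subset optional variant indices (e.g. a pruned set).
#' @return a [QQCurves-class]; strata under 100 SNPs are flagged and warned
#'   about but still emitted.
#' @export
conditionalQQ <- function(pair, primary = 1, thresholds = c(1, 0.1, 0.01, 0.001),
                          subset = NULL) {
    stopifnot(is(pair, "HarmonizedPair"), primary %in% 1:2)
    pri <- if (primary == 1) pair@trait1 else pair@trait2
    sec <- if (primary == 1) pair@trait2 else pair@trait1
    p1 <- pri@table$P; p2 <- sec@table$P
    if (!is.null(subset)) { p1 <- p1[subset]; p2 <- p2[subset] }
    thresholds <- sort(thresholds, decreasing = TRUE)
    curves <- list()
    nS <- numeric(length(thresholds)); low <- logical(length(thresholds))
    for (k in seq_along(thresholds)) {
        sel <- p2 <= thresholds[k]
        n <- sum(sel); nS[k] <- n
        low[k] <- n < 100
        obs <- sort(-log10(p1[sel]))
        expd <- -log10((rev(seq_len(n)) - 0.5) / n)
        curves[[paste0("p2<=", format(thresholds[k]))]] <-
            data.frame(expected = expd, observed = obs)
    }
    if (any(low)) warning("stratum with fewer than 100 SNPs: ",
        paste(format(thresholds[low]), collapse = ", "))
    new("QQCurves", curves = curves, thresholds = thresholds, nSnps = nS,
        lowCount = low, primary = traitLabel(pri))
}

#' Build a stratified condFDR lookup grid
#'
#' Over `pruneIters` random prunings of the panel, accumulates the
#' stratified empirical cdf of the primary p-value within nested
#' secondary-trait strata, averages across iterations, and derives
#' \eqn{condFDR(p_1 | p_2) = p_1 / \hat{F}(p_1 | p_2)}. The condFDR surface
#' is monotone-enforced along the p1 axis (running maximum toward larger
#' p1) and clamped to (0, 1]. An empty stratum in an iteration inherits the
#' nearest coarser stratum's cdf. Complex-LD regions are excluded from grid
#' *estimation* only; queries and discovery keep all SNPs.
#'
#' @param pair a [HarmonizedPair-class] aligned to the panel.
#' @param panel an [LDPanel-class].
#' @param primary 1 or 2: the trait whose FDR is conditioned (p1).
#' @param pruneIters random-pruning iterations (default 100).
#' @param seed base seed; iteration i uses `seed + i`.
#' @param exclude regions excluded from estimation
#'   ([defaultExcludedRegions()] by default; NULL for none).
#' @param r2Threshold pruning threshold.
#' @param strata -log10 p2 stratum thresholds (0 = all SNPs).
#' @param log10p1 -log10 p1 grid (rows).
#' @param minStratumSize strata holding fewer pruned SNPs than this inherit
#'   the nearest coarser stratum's cdf (0 disables): with few SNPs the
#'   stratified cdf is too noisy to condition on and the conjFDR would lose
#'   its conservatism. Default 100, matching the conditional Q-Q warning
#'   threshold.
#' @return an [FDRGrid-class].
#' @export
buildFdrGrid <- function(pair, panel, primary = 1, pruneIters = 100, seed = 1L,
                         exclude = defaultExcludedRegions(), r2Threshold = 0.1,
                         strata = seq(0, 3, by = 0.25),
                         log10p1 = seq(0, 300, by = 0.1), minStratumSize = 100) {
    stopifnot(is(pair, "HarmonizedPair"), nVariants(pair) == nVariants(panel))
    pri <- if (primary == 1) pair@trait1 else pair@trait2
    sec <- if (primary == 1) pair@trait2 else pair@trait1
    lp1 <- -log10(pri@table$P); lp2 <- -log10(sec@table$P)
    ok <- rep(TRUE, length(lp1))
    if (!is.null(exclude)) ok <- .outsideRegions(pri@table, exclude)

    nr <- length(log10p1); nc <- length(strata)
    acc <- matrix(0, nr, nc); accSq <- matrix(0, nr, nc)
    nsAcc <- numeric(nc); floorAcc <- numeric(nc)
    for (it in seq_len(pruneIters)) {
        idx <- randomPrune(panel, r2Threshold, seed + it)
        idx <- idx[ok[idx]]
        Fit <- matrix(NA_real_, nr, nc)
        nsIt <- numeric(nc)
        for (j in seq_len(nc)) {
            # 1e-9 tolerance keeps threshold-equal p-values inclusive despite
            # floating-point round trips through z
            sel <- lp2[idx] >= strata[j] - 1e-9
            n <- sum(sel); nsIt[j] <- n
            tooSmall <- n == 0 || (j > 1L && n < minStratumSize)
            if (tooSmall) {
                if (j == 1L) { Fit[, 1L] <- 1; next }
                Fit[, j] <- Fit[, j - 1]; nsIt[j] <- nsIt[j - 1]; next
            }
            srt <- sort(lp1[idx][sel])
            # P(p1 <= 10^-g) = #( -log10 p1 >= g ) / n, inclusive
            Fit[, j] <- (n - findInterval(log10p1 - 1e-9, srt, left.open = TRUE)) / n
        }
        acc <- acc + Fit; accSq <- accSq + Fit^2
        nsAcc <- nsAcc + nsIt; floorAcc <- floorAcc + 1 / (nsIt + 1)
    }
    Fhat <- acc / pruneIters
    FhatSD <- sqrt(pmax(accSq / pruneIters - Fhat^2, 0))
    floors <- floorAcc / pruneIters
    p1val <- 10^(-log10p1)
    cf <- p1val / pmax(Fhat, rep(floors, each = nr))
    # running maximum toward larger p1 (smaller -log10 p1)
    cf <- apply(cf, 2, function(col) rev(cummax(rev(col))))
    cf <- pmin(pmax(cf, 1e-300), 1)
    new("FDRGrid", log10p1 = log10p1, strata = strata, Fhat = Fhat, condfdr = cf,
        primary = traitLabel(pri),
        meta = list(pruneIters = pruneIters, seed = seed, r2Threshold = r2Threshold,
            excluded = exclude, nSnpsPerStratum = nsAcc / pruneIters,
            FhatSD = FhatSD, floors = floors))
}

#' @rdname buildFdrGrid
#' @param ... passed to `buildFdrGrid`.
#' @return `buildFdrGrids`: list with both conditioning directions,
#'   `g1given2` and `g2given1`.
#' @export
buildFdrGrids <- function(pair, panel, ...) {
    list(g1given2 = buildFdrGrid(pair, panel, primary = 1, ...),
         g2given1 = buildFdrGrid(pair, panel, primary = 2, ...))
}

#' Conditional FDR lookup
#'
#' Bilinear interpolation of the condFDR surface in
#' (-log10 p1, -log10 p2); queries beyond the grid clamp to the edge cells
#' (conservative for p2 beyond the finest stratum).
#'
#' @param grid an [FDRGrid-class].
#' @param p1,p2 p-value vectors in (0, 1] (recycled to a common length).
#' @return condFDR values in (0, 1].
#' @export
condFdr <- function(grid, p1, p2) {
    if (any(p1 <= 0 | p1 > 1, na.rm = TRUE) || any(p2 <= 0 | p2 > 1, na.rm = TRUE))
        stop("p-values must lie in (0, 1]")
    k <- max(length(p1), length(p2))
    p1 <- rep_len(p1, k); p2 <- rep_len(p2, k)
    lx <- pmin(pmax(-log10(p1), min(grid@log10p1)), max(grid@log10p1))
    ly <- pmin(pmax(-log10(p2), min(grid@strata)), max(grid@strata))
    .bilinear(grid@condfdr, grid@log10p1, grid@strata, lx, ly)
}

.bilinear <- function(Mx, xs, ys, x, y) {
    if (length(ys) == 1L) {   # single stratum: 1-D interpolation along p1
        ix <- pmin(pmax(findInterval(x, xs), 1L), length(xs) - 1L)
        wx <- pmin(pmax((x - xs[ix]) / (xs[ix + 1L] - xs[ix]), 0), 1)
        return((1 - wx) * Mx[ix, 1L] + wx * Mx[ix + 1L, 1L])
    }
    ix <- pmin(pmax(findInterval(x, xs), 1L), length(xs) - 1L)
    iy <- pmin(pmax(findInterval(y, ys), 1L), length(ys) - 1L)
    wx <- (x - xs[ix]) / (xs[ix + 1L] - xs[ix])
    wy <- (y - ys[iy]) / (ys[iy + 1L] - ys[iy])
    wx <- pmin(pmax(wx, 0), 1); wy <- pmin(pmax(wy, 0), 1)
    f11 <- Mx[cbind(ix, iy)];     f21 <- Mx[cbind(ix + 1L, iy)]
    f12 <- Mx[cbind(ix, iy + 1L)]; f22 <- Mx[cbind(ix + 1L, iy + 1L)]
    (1 - wx) * (1 - wy) * f11 + wx * (1 - wy) * f21 +
        (1 - wx) * wy * f12 + wx * wy * f22
}

#' Conjunctional FDR
#'
#' The maximum of the two reciprocal conditional FDRs,
#' \eqn{\max\{condFDR(p_1|p_2),\ condFDR(p_2|p_1)\}}: an upper bound on the
#' FDR of association with *both* traits.
#'
#' @param grid1given2,grid2given1 [FDRGrid-class] objects built from the same
#'   harmonized pair, one per conditioning direction.
#' @param p1,p2 p-value vectors in (0, 1].
#' @return conjFDR values in (0, 1].
#' @export
conjFdr <- function(grid1given2, grid2given1, p1, p2) {
    pmax(condFdr(grid1given2, p1, p2), condFdr(grid2given1, p2, p1))
}

#' Per-SNP conjFDR discovery table
#'
#' Annotates every harmonized SNP with both conditional FDRs, the conjFDR,
#' and a significance flag at the chosen threshold.
#'
#' @param pair a [HarmonizedPair-class].
#' @param grids list with `g1given2` and `g2given1` (see [buildFdrGrids()]).
#' @param threshold conjFDR significance threshold (default 0.05).
#' @return data.frame with columns `SNP CHR BP Z1 Z2 P1 P2 CONDFDR12
#'   CONDFDR21 CONJFDR FLAG`, one row per SNP in pair order.
#' @export
discover <- function(pair, grids, threshold = 0.05) {
    t1 <- pair@trait1@table; t2 <- pair@trait2@table
    cf12 <- condFdr(grids$g1given2, t1$P, t2$P)
    cf21 <- condFdr(grids$g2given1, t2$P, t1$P)
    conj <- pmax(cf12, cf21)
    data.frame(SNP = t1$SNP, CHR = t1$CHR, BP = t1$BP, Z1 = t1$Z, Z2 = t2$Z,
        P1 = t1$P, P2 = t2$P, CONDFDR12 = cf12, CONDFDR21 = cf21,
        CONJFDR = conj, FLAG = conj < threshold)
}
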