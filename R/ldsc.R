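#' LD-score-regression genetic correlation
#'
#' Per-trait SNP heritability from the regression of \eqn{z^2} on the LD
#' score \eqn{\ell} (slope \eqn{\times M/n}), genetic covariance from the
#' regression of \eqn{z_1 z_2} on \eqn{\ell} (slope
#' \eqn{\times M/\sqrt{n_1 n_2}}), and
#' \eqn{r_g = \hat{g}_{cov}/\sqrt{\hat{h}_1^2 \hat{h}_2^2}}. Intercepts are
#' free, absorbing residual inflation and cross-trait residual correlation
#' from sample overlap. Regressions are weighted (two-step): an unweighted
#' pass estimates the slopes, then a single heteroskedasticity weight
#' \eqn{1/[\ell (1 + n_1 h_1^2 \ell / M)(1 + n_2 h_2^2 \ell / M)]} shared by
#' all three regressions is applied, down-weighting high-LD variants whose
#' statistics are both noisier and mutually correlated. The standard
#' error and p-value come from a delete-one block jackknife over contiguous
#' variant blocks with the weights held fixed.
#'
#' @param pair a [HarmonizedPair-class].
#' @param ldscores per-variant LD scores aligned to the pair (see
#'   [ldScores()]).
#' @param nBlocks jackknife blocks (reduced so each block keeps >= 200
#'   variants).
#' @param chisqMax optional hard cap: variants with \eqn{z^2} above it are
#'   removed before the regressions. Default `Inf` (no removal): with
#'   heteroskedasticity weights a cap is unnecessary and censoring strong
#'   true signals biases the slopes downward; a finite cap remains useful
#'   against genotyping artefacts in real data.
#' @return list with `rg`, `se`, `p`, per-trait `h2`, `gcov`, `intercepts`
#'   and `nBlocks`.
#' @export
fitLdscRg <- function(pair, ldscores, nBlocks = 200, chisqMax = Inf) {
    stopifnot(is(pair, "HarmonizedPair"), length(ldscores) == nVariants(pair))
    z1 <- pair@trait1@table$Z; z2 <- pair@trait2@table$Z
    n1 <- stats::median(pair@trait1@table$N); n2 <- stats::median(pair@trait2@table$N)
    M <- length(ldscores)   # reference size: all variants, pre-filter
    ok <- z1^2 <= chisqMax & z2^2 <= chisqMax
    x <- ldscores[ok]; z1 <- z1[ok]; z2 <- z2[ok]
    mUse <- length(x)
    nBlocks <- max(2L, min(nBlocks, floor(mUse / 200)))
    blk <- pmin(ceiling(seq_len(mUse) / (mUse / nBlocks)), nBlocks)

    wfit <- function(x, y, w, keep = rep(TRUE, length(x))) {
        x <- x[keep]; y <- y[keep]; w <- w[keep]
        xm <- sum(w * x) / sum(w); ym <- sum(w * y) / sum(w)
        b <- sum(w * (x - xm) * (y - ym)) / sum(w * (x - xm)^2)
        c(slope = b, intercept = ym - b * xm)
    }
    y1 <- z1^2; y2 <- z2^2; yc <- z1 * z2
    ones <- rep(1, mUse)
    # two-step: unweighted slopes, then LDSC-style weights held fixed
    h1 <- wfit(x, y1, ones)[["slope"]] * M / n1
    h2 <- wfit(x, y2, ones)[["slope"]] * M / n2
    gc0 <- wfit(x, yc, ones)[["slope"]] * M / sqrt(n1 * n2)
    # one common weight for all three regressions (the cross-trait variance
    # form); sharing it makes rg exactly 1 for a duplicated trait
    w <- ones
    for (step in 1:2) {
        w <- 1 / (x * (1 + n1 * max(h1, 0) * x / M) * (1 + n2 * max(h2, 0) * x / M))
        h1 <- wfit(x, y1, w)[["slope"]] * M / n1
        h2 <- wfit(x, y2, w)[["slope"]] * M / n2
        gc0 <- wfit(x, yc, w)[["slope"]] * M / sqrt(n1 * n2)
    }
    rgFrom <- function(keep) {
        s1 <- wfit(x, y1, w, keep); s2 <- wfit(x, y2, w, keep)
        sc <- wfit(x, yc, w, keep)
        hh1 <- s1[["slope"]] * M / n1; hh2 <- s2[["slope"]] * M / n2
        gcv <- sc[["slope"]] * M / sqrt(n1 * n2)
        list(h2 = c(hh1, hh2), gcov = gcv,
            intercepts = c(s1[["intercept"]], s2[["intercept"]], sc[["intercept"]]),
            rg = if (hh1 > 0 && hh2 > 0) gcv / sqrt(hh1 * hh2) else NA_real_)
    }
    full <- rgFrom(rep(TRUE, mUse))
    if (!is.finite(full$rg))
        stop("non-positive heritability estimate; genetic correlation undefined")
    jack <- vapply(seq_len(nBlocks), function(b) rgFrom(blk != b)$rg, numeric(1))
    jack <- jack[is.finite(jack)]
    B <- length(jack)
    se <- sqrt((B - 1) / B * sum((jack - mean(jack))^2))
    # duplicate-trait degenerate case: rg identically 1, zero spread
    p <- if (se == 0) as.numeric(full$rg == 0) else 2 * pnorm(-abs(full$rg / se))
    list(rg = full$rg, se = se, p = p, h2 = full$h2, gcov = full$gcov,
        intercepts = full$intercepts, nBlocks = nBlocks)
}
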